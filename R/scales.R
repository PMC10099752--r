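#' Define an instrument subscale
#'
#' @param name Scale name (e.g. `"smfq"`).
#' @param wave One of `"6m"`, `"18m"`, `"3y"`, `"5y"`, `"8y"`.
#' @param n_items Number of items.
#' @param likert_min,likert_max Integer response bounds.
#' @param reverse_items Indices of reverse-coded items.
#' @return An object of class `scale_definition`.
#' @export
scale_definition <- function(name, wave, n_items, likert_min, likert_max,
                             reverse_items = integer()) {
  wave <- match.arg(wave, c("6m", "18m", "3y", "5y", "8y"))
  stopifnot(n_items >= 1, likert_min < likert_max,
            all(reverse_items %in% seq_len(n_items)))
  structure(list(name = name, wave = wave, n_items = as.integer(n_items),
                 likert_min = as.integer(likert_min),
                 likert_max = as.integer(likert_max),
                 reverse_items = as.integer(reverse_items)),
            class = "scale_definition")
}

#' Default scale registry
#'
#' The instrument subscales of the emulated measurement design: ICQ
#' fussy/difficult (7 items) and positive emotionality (2 items) on 7-point
#' scales at 6 months; EAS emotionality, shyness, sociability and activity
#' (3 items each) at 18 months, 3 and 5 years; NHiPIC-30 neuroticism
#' (6 items) at 8 years; SMFQ depressive symptoms (13 items), SCARED anxiety
#' short form (5 items) and the RS-DBD conduct (8), oppositional-defiant
#' (8), hyperactivity (9) and inattention (9) subscales at 8 years.
#'
#' @return Named list of [scale_definition()] objects.
#' @export
default_scale_registry <- function() {
  defs <- list(
    scale_definition("icq_neg", "6m", 7, 1, 7),
    scale_definition("icq_pos", "6m", 2, 1, 7),
    scale_definition("eas_emo", "18m", 3, 1, 5),
    scale_definition("eas_shy", "18m", 3, 1, 5),
    scale_definition("eas_soc", "18m", 3, 1, 5),
    scale_definition("eas_act", "18m", 3, 1, 5),
    scale_definition("eas_emo", "3y", 3, 1, 5),
    scale_definition("eas_shy", "3y", 3, 1, 5),
    scale_definition("eas_soc", "3y", 3, 1, 5),
    scale_definition("eas_act", "3y", 3, 1, 5),
    scale_definition("eas_emo", "5y", 3, 1, 5),
    scale_definition("eas_shy", "5y", 3, 1, 5),
    scale_definition("eas_soc", "5y", 3, 1, 5),
    scale_definition("eas_act", "5y", 3, 1, 5),
    scale_definition("nhipic_neur", "8y", 6, 1, 5),
    scale_definition("smfq", "8y", 13, 0, 2),
    scale_definition("scared", "8y", 5, 0, 2),
    scale_definition("rsdbd_cd", "8y", 8, 1, 4),
    scale_definition("rsdbd_odd", "8y", 8, 1, 4),
    scale_definition("rsdbd_hyp", "8y", 9, 1, 4),
    scale_definition("rsdbd_inat", "8y", 9, 1, 4))
  stats::setNames(defs, vapply(defs, function(d)
    paste0(d$name, "_", d$wave), character(1)))
}

#' Score a subscale from item responses
#'
#' The score is the mean of the available items (reverse-coded where
#' flagged), prorated: a child must answer at least `min_items_fraction` of
#' the items, otherwise the score is missing.
#'
#' @param items Data frame or matrix of item responses, one column per item
#'   in definition order (a `child_id` column, if present, is ignored).
#' @param definition A [scale_definition()].
#' @param min_items_fraction Minimum fraction of answered items (default 0.5).
#' @return Numeric vector of per-child scores.
#' @export
score_scale <- function(items, definition, min_items_fraction = 0.5) {
  stopifnot(inherits(definition, "scale_definition"))
  items <- as.data.frame(items)
  items$child_id <- NULL
  if (ncol(items) != definition$n_items)
    stop("expected ", definition$n_items, " item columns, got ", ncol(items))
  X <- as.matrix(items)
  bad <- which(!is.na(X) & (X < definition$likert_min |
                              X > definition$likert_max), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("response out of Likert range [%d, %d] for child row %d, item %d",
                 definition$likert_min, definition$likert_max,
                 bad[1, 1], bad[1, 2]))
  if (length(definition$reverse_items))
    X[, definition$reverse_items] <-
      definition$likert_min + definition$likert_max -
      X[, definition$reverse_items]
  n_obs <- rowSums(!is.na(X))
  score <- rowMeans(X, na.rm = TRUE)
  score[n_obs < min_items_fraction * definition$n_items] <- NA_real_
  score[n_obs == 0] <- NA_real_
  score
}

#' Standardize a score vector to mean 0, SD 1
#'
#' Centering and scaling use the non-missing entries (the analysis sample);
#' missing values propagate.
#'
#' @param scores Numeric vector.
#' @return Standardized vector.
#' @export
standardize <- function(scores) {
  obs <- scores[!is.na(scores)]
  if (length(obs) < 2)
    stop("standardize() needs at least 2 non-missing values")
  s <- stats::sd(obs)
  if (s == 0 || !is.finite(s))
    stop("cannot standardize a constant (zero-variance) vector")
  (scores - mean(obs)) / s
}

## Two-step polychoric correlation: thresholds from the marginal cumulative
## proportions, correlation by maximizing the bivariate-normal likelihood of
## the contingency table over rho (bounded scalar optimization).
polychoric_corr <- function(x, y, tol = 1e-6) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(x, y)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("polychoric correlation needs >= 2 observed categories per item")
  thr <- function(margin) {
    p <- cumsum(margin) / sum(margin)
    stats::qnorm(p[-length(p)])
  }
  a <- c(-Inf, thr(rowSums(tab)), Inf)
  b <- c(-Inf, thr(colSums(tab)), Inf)
  cell_probs <- function(rho) {
    P <- matrix(NA_real_, nrow(tab), ncol(tab))
    corr <- matrix(c(1, rho, rho, 1), 2)
    F <- matrix(0, nrow(tab) + 1L, ncol(tab) + 1L)
    for (i in seq_len(nrow(tab) + 1L))
      for (j in seq_len(ncol(tab) + 1L)) {
        F[i, j] <- if (i == 1L || j == 1L) 0 else
          mvtnorm::pmvnorm(upper = c(a[i], b[j]), corr = corr)
      }
    for (i in seq_len(nrow(tab)))
      for (j in seq_len(ncol(tab)))
        P[i, j] <- F[i + 1, j + 1] - F[i, j + 1] - F[i + 1, j] + F[i, j]
    pmax(P, 1e-12)
  }
  nll <- function(rho) -sum(tab * log(cell_probs(rho)))
  opt <- stats::optimize(nll, interval = c(-0.999, 0.999), tol = tol)
  opt$minimum
}

## Standardized (Spearman-Brown style) alpha from a correlation matrix:
## k * rbar / (1 + (k - 1) * rbar), rbar = mean off-diagonal correlation.
alpha_from_corr <- function(R) {
  k <- nrow(R)
  rbar <- mean(R[upper.tri(R)])
  k * rbar / (1 + (k - 1) * rbar)
}

#' Ordinal Cronbach's alpha
#'
#' Internal consistency for ordinal items: the standardized-alpha formula
#' applied to the matrix of pairwise polychoric correlations, each estimated
#' by the two-step maximum-likelihood method (thresholds from the margins,
#' correlation by a bivariate-normal likelihood).
#'
#' @param items Data frame or matrix of ordinal item responses (a `child_id`
#'   column, if present, is ignored).
#' @return Alpha in (-Inf, 1].
#' @export
ordinal_alpha <- function(items) {
  items <- as.data.frame(items)
  items$child_id <- NULL
  if (ncol(items) < 2) stop("ordinal_alpha() needs at least 2 items")
  for (j in seq_len(ncol(items)))
    if (length(unique(stats::na.omit(items[[j]]))) < 2)
      stop("item ", names(items)[j] %||% j,
           " has fewer than 2 observed categories")
  k <- ncol(items)
  R <- diag(k)
  for (i in seq_len(k - 1))
    for (j in (i + 1):k)
      R[i, j] <- R[j, i] <- polychoric_corr(items[[i]], items[[j]])
  alpha_from_corr(R)
}
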