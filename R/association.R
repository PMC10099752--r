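#' Fit a logistic regression by maximum likelihood
#'
#' Thin wrapper around iteratively reweighted least squares
#' (`stats::glm.fit`) with explicit rank, convergence and separation
#' diagnostics, returning the coefficient vector and the model-based
#' (inverse-information) covariance along with the pieces the cluster-robust
#' sandwich needs.
#'
#' @param y Binary response (0/1 or logical).
#' @param X Design matrix including the intercept column.
#' @param weights Optional case weights (e.g. aggregated 2x2 counts).
#' @return An object of class `logit_fit` with elements `coefficients`,
#'   `vcov`, `fitted`, `X`, `y`, `weights`, `n`, `deviance`.
#' @export
fit_logistic <- function(y, X, weights = NULL) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("`y` must be binary (0/1)")
  if (length(unique(y)) < 2) stop("`y` is constant; no variation to model")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(dropped, collapse = ", "))
  }
  w <- weights %||% rep(1, length(y))
  fit <- suppressWarnings(stats::glm.fit(
    X, y, weights = w, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  beta <- fit$coefficients
  if (!fit$converged || any(abs(beta) > 20))
    stop("separation suspected: coefficients diverged (max |beta| = ",
         format(max(abs(beta)), digits = 3), ")")
  mu <- fit$fitted.values
  info <- crossprod(X, X * (w * mu * (1 - mu)))
  vc <- solve(info)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 vcov = vc, fitted = mu, X = X, y = y, weights = w,
                 n = length(y), deviance = fit$deviance),
            class = "logit_fit")
}

#' @export
coef.logit_fit <- function(object, ...) object$coefficients

#' @export
vcov.logit_fit <- function(object, ...) object$vcov

#' @export
print.logit_fit <- function(x, ...) {
  cat("Logistic regression (ML),", x$n, "observations\n")
  print(round(cbind(estimate = x$coefficients,
                    se = sqrt(diag(x$vcov))), 4))
  invisible(x)
}

#' Huber-White cluster-robust covariance
#'
#' Sandwich estimator `A^-1 B A^-1` for a fitted logistic model, with `A`
#' the observed information and `B` the outer-product sum of cluster-summed
#' score vectors, optionally scaled by the finite-sample factor
#' `G / (G - 1)` (`G` clusters). With every observation its own cluster and
#' the correction disabled this is the HC0 heteroskedasticity-robust
#' covariance.
#'
#' @param fit A `logit_fit`.
#' @param cluster_ids Cluster membership, aligned with the rows of the
#'   design matrix (e.g. maternal identity).
#' @param cadjust Apply the `G/(G-1)` correction (default `TRUE`).
#' @return Covariance matrix of the coefficients.
#' @export
cluster_robust_vcov <- function(fit, cluster_ids, cadjust = TRUE) {
  stopifnot(inherits(fit, "logit_fit"))
  if (length(cluster_ids) != fit$n)
    stop("`cluster_ids` must align with the model rows")
  G <- length(unique(cluster_ids))
  if (G < 2) stop("need at least 2 clusters")
  scores <- fit$X * (fit$weights * (fit$y - fit$fitted))
  S <- rowsum(scores, group = cluster_ids)
  B <- crossprod(S)
  if (cadjust) B <- B * G / (G - 1)
  fit$vcov %*% B %*% fit$vcov
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, capped at 1.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Screen traits for association with a binary outcome
#'
#' One logistic regression per trait: outcome on the standardized trait plus
#' sex and birth year (linear), with case-wise deletion per model,
#' mother-clustered Huber-White standard errors, Wald 95% confidence
#' intervals, and Benjamini-Hochberg FDR correction across the whole family
#' of traits in the screen.
#'
#' @param cohort A `cohort` or a children data frame.
#' @param traits Character vector of trait column names (standardized
#'   internally per analysis sample).
#' @param outcome Name of the binary outcome column
#'   (default `"emotional_disorder"`).
#' @param stratify Optional column to stratify by (e.g. `"sex"`); the screen
#'   is run within each stratum with FDR applied within stratum.
#' @param covariates Covariate columns (default sex and birth year).
#' @return Data frame of class `assoc_screen`: one row per trait (and
#'   stratum), with `beta` (log-odds per SD), `robust_se`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `p_fdr`, `n_used`, `n_clusters`.
#' @export
run_screen <- function(cohort, traits, outcome = "emotional_disorder",
                       stratify = NULL, covariates = c("sex", "birth_year")) {
  df <- if (inherits(cohort, "cohort")) cohort$children else cohort
  stopifnot(all(traits %in% names(df)), outcome %in% names(df))
  strata <- if (is.null(stratify)) list(all = df) else {
    if (!stratify %in% names(df)) stop("unknown stratification column")
    split(df, df[[stratify]])
  }
  res <- list()
  for (s in names(strata)) {
    dat <- strata[[s]]
    if (!nrow(dat)) stop("empty stratum: ", s)
    rows <- lapply(traits, function(tr) {
      cols <- c(tr, outcome, covariates, "mother_id")
      use <- stats::complete.cases(dat[, cols, drop = FALSE])
      d <- dat[use, , drop = FALSE]
      x <- standardize(d[[tr]])
      X <- cbind(`(Intercept)` = 1, trait = x)
      for (cv in covariates) {
        v <- d[[cv]]
        ## numeric covariates are centered so the intercept stays on the
        ## outcome's logit scale (the separation check assumes that)
        X <- cbind(X, if (is.numeric(v)) v - mean(v) else
          as.numeric(factor(v)) - 1)
        colnames(X)[ncol(X)] <- cv
      }
      keep <- colnames(X)[c(TRUE, TRUE, apply(X[, -(1:2), drop = FALSE], 2,
                                              function(col) stats::var(col) > 0))]
      X <- X[, keep, drop = FALSE]
      fit <- fit_logistic(d[[outcome]], X)
      vc <- cluster_robust_vcov(fit, d$mother_id)
      b <- fit$coefficients["trait"]
      se <- sqrt(vc["trait", "trait"])
      z <- b / se
      data.frame(trait = tr, stratum = s, beta = unname(b), robust_se = se,
                 odds_ratio = exp(unname(b)),
                 ci_low = exp(unname(b) - 1.96 * se),
                 ci_high = exp(unname(b) + 1.96 * se),
                 p_value = 2 * stats::pnorm(-abs(unname(z))),
                 n_used = nrow(d),
                 n_clusters = length(unique(d$mother_id)))
    })
    tab <- do.call(rbind, rows)
    tab$p_fdr <- bh_fdr(tab$p_value)
    res[[s]] <- tab
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("assoc_screen", "data.frame")
  out
}
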