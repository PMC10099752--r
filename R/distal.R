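#' Classification-error table from a posterior matrix
#'
#' Step 2 of the manual 3-step approach: the K x K table
#' `q_jk = P(modal class j | true class k)` estimated as
#' `sum_i p_ik 1[W_i = j] / sum_i p_ik`, with `W` the modal assignments.
#' Columns sum to 1.
#'
#' @param posterior n x K posterior matrix or an `lpa_mixture`.
#' @param modal Optional modal assignments; defaults to the row-wise argmax
#'   (ties to the first class).
#' @return K x K matrix of class `classification_table`.
#' @export
classification_table <- function(posterior, modal = NULL) {
  if (inherits(posterior, "lpa_mixture")) {
    modal <- modal %||% posterior$modal
    posterior <- posterior$posterior
  }
  P <- as.matrix(posterior)
  K <- ncol(P)
  W <- modal %||% max.col(P, ties.method = "first")
  colmass <- colSums(P)
  if (any(colmass <= 0))
    stop("empty class (zero posterior mass) in column ",
         which(colmass <= 0)[1])
  Q <- matrix(0, K, K)
  for (j in seq_len(K))
    Q[j, ] <- colSums(P[W == j, , drop = FALSE]) / colmass
  dimnames(Q) <- list(modal = paste0("class", 1:K),
                      true = paste0("class", 1:K))
  structure(Q, class = c("classification_table", "matrix"))
}

## Build an OR table (all ordered pairs plus versus-reference rows) from
## theta and its covariance via the delta method on contrasts.
or_table_from_theta <- function(theta, vtheta, reference) {
  K <- length(theta)
  pairs <- expand.grid(j = seq_len(K), k = seq_len(K))
  pairs <- pairs[pairs$j != pairs$k, ]
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    j <- pairs$j[r]; k <- pairs$k[r]
    lor <- theta[j] - theta[k]
    se <- if (is.null(vtheta)) NA_real_ else
      sqrt(vtheta[j, j] + vtheta[k, k] - 2 * vtheta[j, k])
    data.frame(class = j, versus = k, odds_ratio = exp(lor),
               ci_low = exp(lor - 1.96 * se),
               ci_high = exp(lor + 1.96 * se),
               p_value = 2 * stats::pnorm(-abs(lor / se)))
  })
  out <- do.call(rbind, rows)
  out$comparison <- paste0("class", out$class, " vs class", out$versus)
  out[, c("comparison", "class", "versus", "odds_ratio", "ci_low",
          "ci_high", "p_value")]
}

#' Construct a distal-outcome result from class logits
#'
#' Builds the class-specific outcome object directly from a vector of
#' log-odds (e.g. for re-expressing published versus-reference odds ratios
#' as pairwise comparisons).
#'
#' @param theta K-vector of class-specific outcome logits.
#' @param vcov Optional K x K covariance of `theta`.
#' @param reference Reference class index (default the first).
#' @param pi Optional mixing proportions (metadata only).
#' @return Object of class `distal_fit`.
#' @export
distal_result <- function(theta, vcov = NULL, reference = 1L, pi = NULL) {
  K <- length(theta)
  stopifnot(reference >= 1, reference <= K)
  structure(list(theta = theta, vcov_theta = vcov, pi = pi,
                 reference = as.integer(reference), K = K,
                 or_table = or_table_from_theta(theta, vcov, reference)),
            class = "distal_fit")
}

#' 3-step ML estimation of a distal binary outcome given latent profiles
#'
#' Step 3 of the manual 3-step approach: with the classification-error table
#' `Q` fixed from step 2, maximize
#' `sum_i log sum_k pi*_k q_{W_i|k} Bernoulli(y_i; plogis(theta_k + x_i b))`
#' over the re-estimated mixing proportions `pi*`, the class-specific
#' outcome logits `theta`, and optional class-invariant covariate slopes.
#' Standard errors come from the observed information; a mother-clustered
#' sandwich can be applied on top.
#'
#' @param modal Modal class assignments `W` (integers 1..K).
#' @param Q K x K [classification_table()] from the same mixture.
#' @param y Binary outcome aligned with `modal`.
#' @param covariates Optional numeric matrix of covariates (class-invariant
#'   slopes).
#' @param cluster_ids Optional cluster ids (e.g. mother); if given, the
#'   reported covariance is the cluster-robust sandwich with the `G/(G-1)`
#'   correction.
#' @param reference Reference class for the odds-ratio table (default:
#'   largest class by `pi*`).
#' @param logq_clip Clip for `log q` when `Q` has zero cells (default 15).
#' @return Object of class `distal_fit`: `theta`, `vcov_theta`, `pi`,
#'   `or_table` over all ordered class pairs with delta-method 95% CIs,
#'   `reference`, `Q`, `loglik`.
#' @export
fit_distal <- function(modal, Q, y, covariates = NULL, cluster_ids = NULL,
                       reference = NULL, logq_clip = 15) {
  W <- as.integer(modal)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), length(W) == length(y))
  K <- ncol(Q)
  counts <- tabulate(W, K)
  if (any(counts == 0))
    stop("class(es) ", paste(which(counts == 0), collapse = ", "),
         " have no modal members; consider a smaller K")
  logQ <- pmax(log(unclass(Q)), -abs(logq_clip))
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  p_cov <- if (is.null(X)) 0L else ncol(X)
  n <- length(y)

  ## parameters: gamma (K-1, softmax for pi*), theta (K), beta (p_cov)
  unpack <- function(par) {
    gamma <- c(par[seq_len(K - 1)], 0)
    list(pi = softmax(gamma), theta = par[(K - 1) + seq_len(K)],
         beta = if (p_cov) par[(2 * K - 1) + seq_len(p_cov)] else NULL)
  }
  ## per-observation pieces reused by loglik and scores
  parts <- function(par) {
    p <- unpack(par)
    eta <- matrix(p$theta, n, K, byrow = TRUE)
    if (p_cov) eta <- eta + drop(X %*% p$beta)
    mu <- stats::plogis(eta)
    logp_y <- y * log(mu) + (1 - y) * log1p(-mu)   # y recycles down columns
    la <- matrix(log(p$pi), n, K, byrow = TRUE) + logQ[W, ] + logp_y
    lse <- log_sum_exp_rows(la)
    list(p = p, mu = mu, r = exp(la - lse), loglik = sum(lse))
  }
  nll <- function(par) -parts(par)$loglik
  scores <- function(par) {
    pt <- parts(par)
    s_theta <- pt$r * (y - pt$mu)
    s_gamma <- pt$r[, seq_len(K - 1), drop = FALSE] -
      matrix(pt$p$pi[seq_len(K - 1)], n, K - 1, byrow = TRUE)
    out <- cbind(s_gamma, s_theta)
    if (p_cov) out <- cbind(out, X * rowSums(s_theta))
    out
  }
  ngr <- function(par) -colSums(scores(par))

  ## start from the naive per-modal-class logistic rates
  rate <- vapply(seq_len(K), function(k) {
    r <- mean(y[W == k])
    min(max(r, 0.5 / max(counts[k], 1)), 1 - 0.5 / max(counts[k], 1))
  }, numeric(1))
  par0 <- c(log(pmax(counts[-K] / counts[K], 1e-6)),
            stats::qlogis(rate), rep(0, p_cov))
  ## class logits and mixing logits are boxed at +/-15: a class with no
  ## observed cases has an infinite ML logit, reported as the boundary
  lower <- c(rep(-15, K - 1 + K), rep(-Inf, p_cov))
  upper <- c(rep(15, K - 1 + K), rep(Inf, p_cov))
  opt <- stats::optim(par0, nll, ngr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 1000, factr = 1e4))
  opt <- stats::optim(opt$par, nll, ngr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 1000, factr = 1e4))
  p <- unpack(opt$par)

  H <- stats::optimHess(opt$par, nll, ngr)
  Vpar <- tryCatch(solve(H), error = function(e) {
    warning("observed information is singular; SEs unavailable")
    matrix(NA_real_, length(opt$par), length(opt$par))
  })
  if (!is.null(cluster_ids)) {
    S <- rowsum(scores(opt$par), group = cluster_ids)
    G <- nrow(S)
    B <- crossprod(S) * G / (G - 1)
    Vpar <- Vpar %*% B %*% Vpar
  }
  idx_theta <- (K - 1) + seq_len(K)
  vtheta <- Vpar[idx_theta, idx_theta, drop = FALSE]
  reference <- reference %||% which.max(p$pi)

  res <- distal_result(p$theta, vtheta, reference = reference, pi = p$pi)
  res$Q <- Q
  res$beta <- p$beta
  res$loglik <- -opt$value
  res$n <- n
  res
}

#' Re-express a distal result against a new reference class
#'
#' All odds ratios are ratios of class odds, so re-referencing is exact:
#' `OR(j, k) = exp(theta_j - theta_k)` regardless of the reference, and the
#' pairwise table is unchanged apart from which rows are flagged as
#' versus-reference.
#'
#' @param result A `distal_fit`.
#' @param new_reference Class index.
#' @return A `distal_fit` with the new reference.
#' @export
re_reference <- function(result, new_reference) {
  stopifnot(inherits(result, "distal_fit"))
  if (new_reference < 1 || new_reference > result$K)
    stop("reference class out of range 1..", result$K)
  out <- result
  out$reference <- as.integer(new_reference)
  out$or_table <- or_table_from_theta(result$theta, result$vcov_theta,
                                      new_reference)
  out
}

#' Versus-reference odds ratios of a distal result
#'
#' @param result A `distal_fit`.
#' @return Data frame of the rows of the OR table comparing each class to
#'   the reference.
#' @export
versus_reference <- function(result) {
  stopifnot(inherits(result, "distal_fit"))
  tab <- result$or_table
  tab[tab$versus == result$reference, , drop = FALSE]
}

#' @export
print.distal_fit <- function(x, ...) {
  cat("3-step distal outcome model: K =", x$K,
      ", reference = class", x$reference, "\n")
  if (!is.null(x$pi))
    cat("Re-estimated mixing proportions:", paste(round(x$pi, 4),
                                                  collapse = " "), "\n")
  cat("Class-specific outcome logits:\n")
  print(round(x$theta, 4))
  cat("\nOdds ratios versus reference:\n")
  vr <- versus_reference(x)
  print(format(vr[, c("comparison", "odds_ratio", "ci_low", "ci_high")],
               digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.distal_fit <- function(object, ...) object$theta

#' @export
vcov.distal_fit <- function(object, ...) object$vcov_theta

#' @export
summary.distal_fit <- function(object, ...) {
  print(object)
  cat("\nAll pairwise comparisons:\n")
  print(format(object$or_table, digits = 3), row.names = FALSE)
  invisible(object)
}
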