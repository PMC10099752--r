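#' Parallel-process linear growth specification
#'
#' Two processes (emotional and behavioral problems) measured at 18 months,
#' 3 and 5 years load on a latent intercept (loading 1) and a latent slope
#' with fixed time scores `lambda` in years since the first wave, so slopes
#' are per-year change. The loading matrix is 6x4 over the factor order
#' (emotional intercept, emotional slope, behavioral intercept, behavioral
#' slope), with measurement rows ordered emotional 18m/3y/5y then behavioral
#' 18m/3y/5y.
#'
#' @param wave_ages Measurement ages in years.
#' @param lambda Time scores per wave (default `wave_ages - wave_ages[1]`).
#' @return An object of class `growth_spec` with elements `processes`,
#'   `wave_ages`, `lambda` and the fixed `loading` matrix.
#' @export
growth_spec <- function(wave_ages = c(1.5, 3, 5), lambda = NULL) {
  lambda <- lambda %||% (wave_ages - wave_ages[1])
  stopifnot(length(wave_ages) == length(lambda))
  nt <- length(lambda)
  one <- cbind(1, lambda)
  L <- rbind(cbind(one, matrix(0, nt, 2)), cbind(matrix(0, nt, 2), one))
  colnames(L) <- c("emo_int", "emo_slope", "beh_int", "beh_slope")
  rownames(L) <- c(paste0("emo_", seq_len(nt)), paste0("beh_", seq_len(nt)))
  structure(list(processes = c("emotional", "behavioral"),
                 wave_ages = wave_ages, lambda = lambda, loading = L),
            class = "growth_spec")
}

#' Model-implied moments of a growth model
#'
#' @param spec A [growth_spec()].
#' @param params List with `alpha` (factor means, length 4), `psi` (4x4
#'   factor covariance, positive semidefinite) and `theta` (6 positive
#'   residual variances, wave- and process-specific).
#' @return List with `mean` (length 6) and `cov` (6x6), via
#'   `mu = Lambda alpha`, `Sigma = Lambda Psi Lambda' + Theta`.
#' @export
implied_moments <- function(spec, params) {
  stopifnot(inherits(spec, "growth_spec"))
  L <- spec$loading
  alpha <- params$alpha; psi <- params$psi; theta <- params$theta
  stopifnot(length(alpha) == ncol(L), nrow(psi) == ncol(L),
            length(theta) == nrow(L))
  ev <- eigen((psi + t(psi)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("`psi` must be positive semidefinite")
  if (any(theta < 0)) stop("`theta` residual variances must be nonnegative")
  mu <- drop(L %*% alpha)
  Sigma <- L %*% psi %*% t(L) + diag(theta)
  list(mean = mu, cov = (Sigma + t(Sigma)) / 2)
}

## ---- FIML machinery ------------------------------------------------------
## Sufficient statistics per missingness pattern (optionally class-weighted):
## counts N, sums m, crossproducts S over observed coordinates.

pattern_suffstats <- function(X, weights = NULL, pats = NULL) {
  pats <- pats %||% missing_patterns(X)
  lapply(pats, function(p) {
    Xo <- X[p$rows, p$obs, drop = FALSE]
    if (is.null(weights)) {
      list(obs = p$obs, rows = p$rows, N = length(p$rows),
           m = colSums(Xo), S = crossprod(Xo))
    } else {
      w <- weights[p$rows, , drop = FALSE]           # rows x K
      K <- ncol(w)
      list(obs = p$obs, rows = p$rows,
           N = colSums(w),
           m = crossprod(w, Xo),                      # K x d_p
           S = lapply(seq_len(K), function(k)
             crossprod(Xo * sqrt(w[, k]), Xo * sqrt(w[, k]))))
    }
  })
}

## Log-likelihood (and gradient pieces) of the growth block for K classes
## sharing Sigma = L Psi L' + Theta, class means mu_k = L alpha_k, from
## class-weighted pattern suffstats. Returns loglik and gradients wrt
## alpha (K x 4), Psi (4x4 symmetric), theta (length 6 diagonal).
growth_block_obj <- function(alphas, psi, theta, L, stats_list,
                             gradient = TRUE) {
  d <- nrow(L)
  Sigma <- L %*% psi %*% t(L) + diag(theta)
  Mu <- alphas %*% t(L)                               # K x d
  K <- nrow(Mu)
  ll <- 0
  Gmu <- matrix(0, K, d)
  GS <- matrix(0, d, d)
  for (st in stats_list) {
    o <- st$obs; dp <- length(o)
    So <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(list(loglik = -Inf))
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    ## all classes at once: M holds class sums, U class means (K x dp)
    if (is.matrix(st$m)) { N <- st$N; M <- st$m
      Stot <- Reduce(`+`, st$S)
    } else { N <- st$N; M <- matrix(st$m, 1); Stot <- st$S }
    U <- Mu[, o, drop = FALSE]
    MS <- M %*% Sinv                                  # rows: Sinv m_k
    US <- U %*% Sinv                                  # rows: Sinv mu_k
    ## tr(Sinv C_k) summed over k, with
    ## C_k = S_k - m_k mu_k' - mu_k m_k' + N_k mu_k mu_k'
    quad <- rowSums(MS * U)                           # m_k' Sinv mu_k
    umu <- rowSums(US * U)                            # mu_k' Sinv mu_k
    ll <- ll - 0.5 * (sum(N) * (dp * log(2 * pi) + logdet) +
                        sum(Sinv * Stot) - 2 * sum(quad) + sum(N * umu))
    if (gradient) {
      Gmu[, o] <- Gmu[, o] + MS - N * US
      SCS <- Sinv %*% Stot %*% Sinv - crossprod(MS, US) -
        crossprod(US, MS) + crossprod(US * N, US)
      GS[o, o] <- GS[o, o] - 0.5 * (sum(N) * Sinv - SCS)
    }
  }
  if (!gradient) return(list(loglik = ll))
  list(loglik = ll,
       g_alpha = Gmu %*% L,
       g_psi = t(L) %*% GS %*% L,
       g_theta = diag(GS))
}

## Pack / unpack the unconstrained parameterization: per-class alpha (4K),
## log-Cholesky of Psi (10), log residual variances (6).
pack_growth_par <- function(alphas, psi, theta)
  c(t(alphas), spd_to_par(psi), log(theta))

unpack_growth_par <- function(par, K) {
  q <- 4L
  alphas <- matrix(par[seq_len(K * q)], K, q, byrow = TRUE)
  psi <- par_to_spd(par[K * q + seq_len(spd_npar(q))], q)
  theta <- exp(par[(K * q + spd_npar(q)) + seq_len(6L)])
  list(alphas = alphas, psi = psi, theta = theta)
}

growth_negloglik_fn <- function(stats_list, L, K) {
  q <- 4L
  function(par) {
    p <- unpack_growth_par(par, K)
    -growth_block_obj(p$alphas, p$psi, p$theta, L, stats_list,
                      gradient = FALSE)$loglik
  }
}

growth_neggrad_fn <- function(stats_list, L, K) {
  q <- 4L
  function(par) {
    p <- unpack_growth_par(par, K)
    ob <- growth_block_obj(p$alphas, p$psi, p$theta, L, stats_list)
    lpar <- par[K * q + seq_len(spd_npar(q))]
    g_chol <- chol_chain_grad(ob$g_psi, lpar, q)
    g_theta <- ob$g_theta * p$theta
    -c(t(ob$g_alpha), g_chol, g_theta)
  }
}

#' FIML log-likelihood of growth data with missing entries
#'
#' Each row contributes the multivariate-normal log-density of its observed
#' subvector under the model-implied moments restricted to the observed
#' coordinates. Rows with no observed value are excluded (with a message
#' reporting how many).
#'
#' @param data Matrix or data frame of the 6 repeated scores (columns in
#'   loading-matrix order), `NA` for missing.
#' @param spec A [growth_spec()].
#' @param params Parameter list as for [implied_moments()].
#' @return The log-likelihood (a scalar).
#' @export
fiml_loglik <- function(data, spec, params) {
  X <- as.matrix(data)
  stopifnot(ncol(X) == nrow(spec$loading))
  empty <- rowSums(!is.na(X)) == 0
  if (any(empty)) {
    message("excluding ", sum(empty), " row(s) with no observed values")
    X <- X[!empty, , drop = FALSE]
  }
  mom <- implied_moments(spec, params)   # validates params
  st <- pattern_suffstats(X)
  growth_block_obj(matrix(params$alpha, 1), params$psi, params$theta,
                   spec$loading, st, gradient = FALSE)$loglik
}

#' Fit a parallel-process latent growth model by FIML
#'
#' Maximizes the full-information maximum-likelihood over an unconstrained
#' parameterization (log-Cholesky factor covariance, log residual variances)
#' by quasi-Newton (BFGS) with analytic gradients. Standard errors come from
#' the inverse of the observed information (numerical Hessian at the
#' optimum).
#'
#' @param data Matrix or data frame of the 6 repeated scores, `NA` allowed.
#' @param spec A [growth_spec()].
#' @param control List: `maxit` (default 500), `grad_tol` for the
#'   gradient max-norm at convergence (default 1e-6).
#' @return Object of class `growth_fit` with `alpha`, `psi`, `theta`, their
#'   standard errors (`se_alpha`), `loglik`, `n`, and the spec.
#' @export
fit_growth <- function(data, spec = growth_spec(), control = list()) {
  X <- as.matrix(data)
  empty <- rowSums(!is.na(X)) == 0
  if (any(empty)) X <- X[!empty, , drop = FALSE]
  n <- nrow(X)
  if (n < 50) warning("n < 50; growth model estimates may be unstable")
  maxit <- control$maxit %||% 500L
  grad_tol <- control$grad_tol %||% 1e-6

  st <- pattern_suffstats(X)
  L <- spec$loading
  ## moment-based start: regress wave means on the loadings, modest Psi
  mu0 <- colMeans(X, na.rm = TRUE)
  a0 <- drop(solve(crossprod(L), crossprod(L, mu0)))
  v0 <- apply(X, 2, stats::var, na.rm = TRUE)
  psi0 <- diag(c(0.5, 0.05, 0.5, 0.05) * mean(v0))
  th0 <- pmax(v0 / 2, 1e-3)
  par0 <- pack_growth_par(matrix(a0, 1), psi0, th0)

  nll <- growth_negloglik_fn(st, L, 1L)
  ngr <- growth_neggrad_fn(st, L, 1L)
  opt <- stats::optim(par0, nll, ngr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  g <- ngr(opt$par)
  if (max(abs(g)) > grad_tol * max(1, n / 100)) {
    opt2 <- stats::optim(opt$par, nll, ngr, method = "BFGS",
                         control = list(maxit = maxit, reltol = 1e-14))
    if (opt2$value <= opt$value) opt <- opt2
    g <- ngr(opt$par)
  }
  if (max(abs(g)) / max(1, n / 100) > 100 * grad_tol)
    stop("growth model did not converge: gradient max-norm ",
         format(max(abs(g)), digits = 3))
  p <- unpack_growth_par(opt$par, 1L)
  H <- stats::optimHess(opt$par, nll, ngr)
  Vpar <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, length(opt$par), length(opt$par)))
  se_alpha <- sqrt(pmax(diag(Vpar)[1:4], 0))
  structure(list(alpha = stats::setNames(drop(p$alphas), colnames(L)),
                 psi = p$psi, theta = stats::setNames(p$theta, rownames(L)),
                 se_alpha = stats::setNames(se_alpha, colnames(L)),
                 vcov_par = Vpar, par = opt$par,
                 loglik = -opt$value, n = n, spec = spec),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Parallel-process latent growth model (FIML), n =", x$n, "\n")
  cat("log-likelihood:", format(x$loglik, digits = 8), "\n\n")
  cat("Growth factor means (SE):\n")
  print(round(cbind(estimate = x$alpha, se = x$se_alpha), 4))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$alpha

#' @export
logLik.growth_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$par), nobs = object$n,
            class = "logLik")
}

#' @export
summary.growth_fit <- function(object, ...) {
  cat("Factor covariance (Psi):\n"); print(round(object$psi, 4))
  cat("\nResidual variances (Theta):\n"); print(round(object$theta, 4))
  print(object)
  invisible(object)
}
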