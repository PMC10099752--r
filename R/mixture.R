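## Latent profile analysis embedding the parallel growth processes.
##
## Class-conditional model for the 12 indicators: the 6 repeated CBCL scores
## follow the growth-structured moments (Lambda alpha_k, Lambda Psi Lambda' +
## Theta) and the 6 eight-year symptom scales are normal with class means
## nu_k and shared diagonal variances; the two blocks are independent given
## class (local independence). Covariance components are shared across
## classes; only means differ. Estimation is generalized EM: the E-step uses
## observed-coordinate marginals (FIML), the M-step updates the mixing
## proportions and eight-year parameters in closed form and takes a few
## quasi-Newton steps on the growth block's expected complete-data
## log-likelihood.

## E-step: per-row class log-densities over observed coordinates.
## Returns list(loglik, post) given parameters.
mixture_estep <- function(X, pats, L, prior, alphas, psi, theta, nu, sig8) {
  n <- nrow(X); K <- length(prior)
  d_g <- nrow(L)
  Sigma <- L %*% psi %*% t(L) + diag(theta)
  Mu_g <- alphas %*% t(L)                       # K x 6
  sd8 <- sqrt(sig8)
  logw <- matrix(rep(log(prior), each = n), n, K)
  for (p in pats) {
    og <- p$obs[p$obs <= d_g]
    o8 <- p$obs[p$obs > d_g] - d_g
    rows <- p$rows
    if (length(og)) {
      So <- Sigma[og, og, drop = FALSE]
      ch <- chol(So)
      logdet <- 2 * sum(log(diag(ch)))
      Xg <- t(X[rows, og, drop = FALSE])        # d x n_p
      base <- -0.5 * (length(og) * log(2 * pi) + logdet)
      for (k in seq_len(K)) {
        z <- backsolve(ch, Xg - Mu_g[k, og], transpose = TRUE)
        logw[rows, k] <- logw[rows, k] + base - 0.5 * colSums(z * z)
      }
    }
    if (length(o8)) {
      X8 <- X[rows, d_g + o8, drop = FALSE]
      for (k in seq_len(K)) {
        acc <- 0
        for (jj in seq_along(o8)) {
          j <- o8[jj]
          acc <- acc + stats::dnorm(X8[, jj], nu[k, j], sd8[j], log = TRUE)
        }
        logw[rows, k] <- logw[rows, k] + acc
      }
    }
  }
  lse <- log_sum_exp_rows(logw)
  list(loglik = sum(lse), post = exp(logw - lse))
}

## Initial partition for one EM start: fine-grained k-means on mean-imputed
## rows, agglomerated (Ward) down to K classes, so small classes in the
## tails are not swallowed when one class dominates. Granularity varies
## across starts for basin diversity, plus a random reassignment
## perturbation.
mixture_init <- function(X, K, L, start_id) {
  Ximp <- X
  for (j in seq_len(ncol(X)))
    Ximp[is.na(Ximp[, j]), j] <- mean(X[, j], na.rm = TRUE)
  cells <- min(max((2L + 2L * ((start_id - 1L) %% 4L)) * K, 8L),
               nrow(X) %/% 2L)
  cl <- tryCatch({
    km <- suppressWarnings(
      stats::kmeans(Ximp, centers = cells, nstart = 1, iter.max = 50))
    grp <- stats::cutree(stats::hclust(stats::dist(km$centers)^2,
                                       method = "ward.D2"), K)
    grp[km$cluster]
  }, error = function(e) sample.int(K, nrow(X), replace = TRUE))
  if (start_id > 1) {
    ## perturb: reassign a random 10% of rows
    flip <- sample(nrow(X), ceiling(0.1 * nrow(X)))
    cl[flip] <- sample.int(K, length(flip), replace = TRUE)
  }
  pi0 <- pmax(tabulate(cl, K), 1) / nrow(X)
  pi0 <- pi0 / sum(pi0)
  d_g <- nrow(L)
  centers <- t(vapply(seq_len(K), function(k)
    colMeans(Ximp[cl == k, , drop = FALSE]), numeric(ncol(X))))
  alphas0 <- centers[, seq_len(d_g), drop = FALSE] %*%
    L %*% solve(crossprod(L))
  nu0 <- centers[, d_g + seq_len(ncol(X) - d_g), drop = FALSE]
  ## within-partition (not marginal) variances: marginal variances carry the
  ## between-class separation and would blur the classes from the start
  v <- apply(X - centers[cl, , drop = FALSE], 2, stats::var, na.rm = TRUE)
  v <- pmax(v, 1e-3)
  list(pi = pi0, alphas = alphas0,
       psi = diag(c(0.4, 0.04, 0.4, 0.04) * mean(v[seq_len(d_g)])),
       theta = pmax(v[seq_len(d_g)] / 2, 1e-3),
       nu = nu0, sig8 = v[d_g + seq_len(ncol(X) - d_g)])
}

#' Fit a growth-structured latent profile model
#'
#' EM over a K-class multivariate-normal mixture on the 6 repeated CBCL
#' scores (growth-structured moments) and the 6 eight-year symptom scales
#' (class means, shared diagonal variances, independent of the growth block
#' given class). Missing entries are handled by observed-coordinate
#' marginals (FIML). The best of `n_starts` initializations is kept, and
#' classes are relabeled in decreasing mixing-proportion order (ties broken
#' by the first mean coordinate).
#'
#' @param data Matrix or data frame with the 6 CBCL columns followed by the
#'   6 eight-year columns; `NA` allowed, rows with no observed value are
#'   dropped.
#' @param K Number of classes (>= 1).
#' @param n_starts Number of random initializations (default 20).
#' @param seed Integer seed for the starts.
#' @param spec A [growth_spec()].
#' @param control List: `max_iter` (default 500), `tol` relative
#'   log-likelihood change (default 1e-8), `mstep_iter` quasi-Newton steps
#'   per M-step (default 8; with K = 1 the M-step runs to convergence),
#'   `start_iter` EM iterations per short multistart run (default 30),
#'   `subsample` rows used for the short runs on large samples (default
#'   4000), `n_final` candidates polished to convergence on the full data
#'   (default 4).
#' @return Object of class `lpa_mixture`: mixing proportions `pi`, per-class
#'   growth means `alphas` (K x 4) and 8-year means `nu` (K x 6), shared
#'   `psi`, `theta`, `sig8`, the `posterior` matrix with modal assignments,
#'   `loglik`, `loglik_trace`, `n`, `K`, `npar`, and convergence metadata.
#' @export
fit_mixture <- function(data, K, n_starts = 20L, seed = 1L,
                        spec = growth_spec(), control = list()) {
  X <- as.matrix(data)
  d_g <- nrow(spec$loading)
  stopifnot(K >= 1, ncol(X) == d_g + 6L)
  empty <- rowSums(!is.na(X)) == 0
  if (any(empty)) {
    message("excluding ", sum(empty), " row(s) with no observed values")
    X <- X[!empty, , drop = FALSE]
  }
  n <- nrow(X)
  if (n < 10 * K) stop("need n >= 10 K observations")
  max_iter <- control$max_iter %||% 500L
  tol <- control$tol %||% 1e-8
  ## with one class the "expected" complete-data likelihood IS the observed
  ## likelihood, so the M-step is run to convergence rather than partially
  mstep_iter <- control$mstep_iter %||% (if (K == 1L) 200L else 8L)
  L <- spec$loading

  ## an EM "engine" bound to one data matrix: precomputed missingness
  ## patterns plus a run() method executing generalized-EM iterations
  make_engine <- function(Xe) {
    pats_e <- missing_patterns(Xe)
    Xg <- Xe[, seq_len(d_g), drop = FALSE]
    keep_g <- rowSums(!is.na(Xg)) > 0
    Xg <- Xg[keep_g, , drop = FALSE]
    pats_g <- Filter(function(p) length(p$obs) > 0, missing_patterns(Xg))
    X8 <- Xe[, d_g + seq_len(6L), drop = FALSE]
    obs8 <- !is.na(X8)
    estep <- function(par)
      mixture_estep(Xe, pats_e, L, par$pi, par$alphas, par$psi,
                    par$theta, par$nu, par$sig8)
    run <- function(par, iter_budget, trace = numeric(0)) {
      ll_old <- if (length(trace)) trace[length(trace)] else -Inf
      for (it in seq_len(iter_budget)) {
        es <- estep(par)
        w <- es$post
        trace <- c(trace, es$loglik)
        if (min(colSums(w)) < 1) return(list(degenerate = TRUE))
        if (is.finite(ll_old) &&
            abs(es$loglik - ll_old) < tol * abs(ll_old)) {
          return(list(degenerate = FALSE, par = par, loglik = es$loglik,
                      post = w, trace = trace, iterations = length(trace),
                      converged = TRUE))
        }
        ll_old <- es$loglik
        ## M-step: closed forms for the mixing weights and 8-year block
        par$pi <- colMeans(w)
        for (j in seq_len(6L)) {
          oj <- obs8[, j]
          wj <- w[oj, , drop = FALSE]
          xj <- X8[oj, j]
          par$nu[, j] <- crossprod(wj, xj) / colSums(wj)
          resid2 <- (outer(xj, rep(1, K)) -
                       matrix(par$nu[, j], nrow = sum(oj), ncol = K,
                              byrow = TRUE))^2
          par$sig8[j] <- sum(wj * resid2) / sum(wj)
        }
        ## M-step: growth block, a few quasi-Newton steps on Q
        stw <- pattern_suffstats(Xg, weights = w[keep_g, , drop = FALSE],
                                 pats = pats_g)
        p0 <- pack_growth_par(par$alphas, par$psi, par$theta)
        nll <- growth_negloglik_fn(stw, L, K)
        ngr <- growth_neggrad_fn(stw, L, K)
        opt <- stats::optim(p0, nll, ngr, method = "BFGS",
                            control = list(maxit = mstep_iter))
        if (opt$value <= nll(p0)) {
          up <- unpack_growth_par(opt$par, K)
          par$alphas <- up$alphas; par$psi <- up$psi; par$theta <- up$theta
        }
      }
      es <- estep(par)
      list(degenerate = FALSE, par = par, loglik = es$loglik, post = es$post,
           trace = c(trace, es$loglik), iterations = length(trace) + 1L,
           converged = FALSE)
    }
    list(estep = estep, run = run, X = Xe)
  }

  engine <- make_engine(X)

  ## multistart: short EM runs from perturbed k-means partitions — on a
  ## random subsample when n is large, so many basins can be probed cheaply.
  ## Candidates are ranked by their full-data log-likelihood and the most
  ## promising ones are iterated to convergence on the full data.
  start_iter <- control$start_iter %||% min(30L, max_iter)
  n_final <- control$n_final %||% 4L
  sub_n <- control$subsample %||% 4000L
  seeds <- derive_seeds(seed, n_starts)
  use_sub <- K > 1L && n > 1.5 * sub_n
  cands <- list(); n_degenerate <- 0L
  for (s in seq_len(n_starts)) {
    set.seed(seeds[s])
    ## each start probes its own random subsample (when n is large) so the
    ## short runs explore different realizations of the landscape
    stage1 <- if (use_sub)
      make_engine(X[sample(n, sub_n), , drop = FALSE]) else engine
    par0 <- mixture_init(stage1$X, K, L, s)
    res <- stage1$run(par0, start_iter)
    if (isTRUE(res$degenerate)) { n_degenerate <- n_degenerate + 1L; next }
    res$seed <- seeds[s]
    ## rank candidates on the full data
    res$loglik_full <- if (use_sub) engine$estep(res$par)$loglik else
      res$loglik
    cands[[length(cands) + 1L]] <- res
  }
  if (!length(cands))
    stop("all ", n_starts, " starts collapsed to a degenerate class")
  ord <- order(-vapply(cands, `[[`, numeric(1), "loglik_full"))
  best <- NULL; best_seed <- NA_integer_
  for (i in utils::head(ord, n_final)) {
    cand <- cands[[i]]
    if (use_sub || !cand$converged) {
      trace0 <- if (use_sub) numeric(0) else cand$trace
      cont <- engine$run(cand$par, max_iter - length(trace0), trace0)
      if (!isTRUE(cont$degenerate)) { cont$seed <- cand$seed; cand <- cont }
      else next
    }
    if (is.null(best) || cand$loglik > best$loglik) { best <- cand
      best_seed <- cand$seed }
  }
  if (is.null(best))
    stop("all retained starts collapsed to a degenerate class")

  ## canonical labels: decreasing pi, tie-break by first implied mean
  par <- best$par
  first_mean <- (par$alphas %*% t(L))[, 1]
  ord <- order(-par$pi, first_mean)
  par$pi <- par$pi[ord]
  par$alphas <- par$alphas[ord, , drop = FALSE]
  par$nu <- par$nu[ord, , drop = FALSE]
  post <- best$post[, ord, drop = FALSE]
  colnames(post) <- paste0("class", seq_len(K))
  rownames(par$alphas) <- rownames(par$nu) <- paste0("class", seq_len(K))
  colnames(par$alphas) <- colnames(L)
  if (!is.null(colnames(X))) colnames(par$nu) <- colnames(X)[d_g + 1:6]

  structure(list(K = K, pi = par$pi, alphas = par$alphas, psi = par$psi,
                 theta = par$theta, nu = par$nu, sig8 = par$sig8,
                 posterior = post,
                 modal = max.col(post, ties.method = "first"),
                 loglik = best$loglik, loglik_trace = best$trace,
                 iterations = best$iterations, converged = best$converged,
                 n = n, npar = (K - 1) + 4 * K + spd_npar(4) + 6 + 6 * K + 6,
                 best_start_seed = best_seed,
                 n_degenerate_starts = n_degenerate, spec = spec),
            class = "lpa_mixture")
}

#' Classification entropy of a posterior matrix
#'
#' Normalized classification certainty
#' `E = 1 - sum(-p log p) / (n log K)`: 0 for uniform (uninformative)
#' posteriors, 1 for degenerate (perfect) classification.
#'
#' @param posterior An n x K posterior probability matrix (or an
#'   `lpa_mixture`).
#' @return A scalar in `[0, 1]`.
#' @export
entropy <- function(posterior) {
  if (inherits(posterior, "lpa_mixture")) posterior <- posterior$posterior
  P <- as.matrix(posterior)
  K <- ncol(P)
  if (K < 2) stop("entropy is undefined for K = 1")
  if (any(P < -1e-12) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("posterior rows must be probabilities summing to 1")
  plogp <- ifelse(P > 0, P * log(P), 0)
  1 - sum(-plogp) / (nrow(P) * log(K))
}

#' Enumerate latent profile models over a range of K
#'
#' Fits each candidate class count and reports log-likelihood, parameter
#' count, BIC (`-2 ll + p log n`), sample-size-adjusted BIC (using
#' `(n + 2) / 24` in place of `n`), AIC, entropy, the fraction of
#' individuals modally assigned to the smallest profile, and whether the
#' model passes the smallest-profile rule (> 1%).
#'
#' @param data As for [fit_mixture()].
#' @param K_range Integer vector of class counts.
#' @param n_starts,seed,spec,control Passed to [fit_mixture()].
#' @return Data frame of class `enumeration_report`, one row per K, sorted
#'   by K; non-convergent fits are flagged, not fatal. The fitted models are
#'   attached as attribute `"fits"`.
#' @export
enumerate_classes <- function(data, K_range, n_starts = 20L, seed = 1L,
                              spec = growth_spec(), control = list()) {
  stopifnot(length(K_range) >= 1)
  K_range <- sort(unique(as.integer(K_range)))
  fits <- list()
  rows <- lapply(K_range, function(K) {
    fit <- tryCatch(
      fit_mixture(data, K, n_starts = n_starts, seed = seed, spec = spec,
                  control = control),
      error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(K = K, loglik = NA_real_, npar = NA_integer_,
                        bic = NA_real_, abic = NA_real_, aic = NA_real_,
                        entropy = NA_real_, smallest_class = NA_real_,
                        accepted = FALSE, converged = FALSE,
                        error = conditionMessage(fit)))
    fits[[as.character(K)]] <<- fit
    n <- fit$n
    frac <- min(tabulate(fit$modal, K)) / n
    data.frame(K = K, loglik = fit$loglik, npar = fit$npar,
               bic = -2 * fit$loglik + fit$npar * log(n),
               abic = -2 * fit$loglik + fit$npar * log((n + 2) / 24),
               aic = -2 * fit$loglik + 2 * fit$npar,
               entropy = if (K >= 2) entropy(fit$posterior) else NA_real_,
               smallest_class = frac, accepted = frac > 0.01,
               converged = fit$converged, error = NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("enumeration_report", "data.frame")
  out
}

#' @export
print.lpa_mixture <- function(x, ...) {
  cat("Growth-structured latent profile model: K =", x$K, ", n =", x$n, "\n")
  cat("log-likelihood:", format(x$loglik, digits = 8),
      "(", x$iterations, "EM iterations,",
      if (x$converged) "converged" else "NOT converged", ")\n")
  cat("Mixing proportions:\n")
  print(round(stats::setNames(x$pi, rownames(x$alphas)), 4))
  if (x$K >= 2) cat("Entropy:", round(entropy(x$posterior), 3), "\n")
  invisible(x)
}

#' @export
summary.lpa_mixture <- function(object, ...) {
  print(object)
  cat("\nGrowth factor means by class:\n"); print(round(object$alphas, 3))
  cat("\n8-year scale means by class:\n"); print(round(object$nu, 3))
  invisible(object)
}

#' @export
logLik.lpa_mixture <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' @export
coef.lpa_mixture <- function(object, ...) {
  list(pi = object$pi, alphas = object$alphas, nu = object$nu,
       psi = object$psi, theta = object$theta, sig8 = object$sig8)
}

#' Posterior class probabilities for new data
#'
#' @param object An `lpa_mixture`.
#' @param newdata Matrix or data frame with the same 12 columns the model
#'   was fitted to; defaults to the training posterior.
#' @param ... Unused.
#' @return n x K posterior probability matrix.
#' @export
predict.lpa_mixture <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$posterior)
  X <- as.matrix(newdata)
  pats <- missing_patterns(X)
  es <- mixture_estep(X, pats, object$spec$loading, object$pi,
                      object$alphas, object$psi, object$theta, object$nu,
                      object$sig8)
  colnames(es$post) <- colnames(object$posterior)
  es$post
}

#' Simulate indicator data from a fitted profile model
#'
#' @param object An `lpa_mixture`.
#' @param nsim Number of children to simulate.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame of 12 indicator columns with a `class_true` attribute
#'   column.
#' @export
simulate.lpa_mixture <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  K <- object$K
  L <- object$spec$loading
  cls <- sample.int(K, nsim, replace = TRUE, prob = object$pi)
  eta <- matrix(stats::rnorm(nsim * 4), nsim, 4) %*% chol(object$psi) +
    object$alphas[cls, , drop = FALSE]
  Xg <- eta %*% t(L) + matrix(stats::rnorm(nsim * 6), nsim, 6) %*%
    diag(sqrt(object$theta))
  X8 <- object$nu[cls, , drop = FALSE] +
    matrix(stats::rnorm(nsim * 6), nsim, 6) %*% diag(sqrt(object$sig8))
  out <- as.data.frame(cbind(Xg, X8))
  names(out) <- c(rownames(L), colnames(object$nu))
  out$class_true <- cls
  out
}

#' Serialize a fitted mixture to JSON
#'
#' @param fit An `lpa_mixture`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_mixture_json <- function(fit, path) {
  stopifnot(inherits(fit, "lpa_mixture"))
  obj <- list(K = fit$K, n = fit$n, pi = fit$pi, alphas = fit$alphas,
              nu = fit$nu, psi = fit$psi, theta = fit$theta,
              sig8 = fit$sig8, loglik = fit$loglik,
              iterations = fit$iterations, converged = fit$converged,
              best_start_seed = fit$best_start_seed,
              loglik_trace_head = utils::head(fit$loglik_trace, 5),
              loglik_trace_tail = utils::tail(fit$loglik_trace, 5))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
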