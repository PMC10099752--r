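# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
log_sum_exp_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

## Log-Cholesky parameterization of a symmetric positive-definite matrix:
## theta holds the lower triangle column-wise with log-transformed diagonal.
spd_npar <- function(d) d * (d + 1L) / 2L

par_to_chol <- function(theta, d) {
  L <- matrix(0, d, d)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  L
}

par_to_spd <- function(theta, d) {
  L <- par_to_chol(theta, d)
  tcrossprod(L)
}

spd_to_par <- function(S) {
  L <- t(chol(S))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

## Gradient chain rule: given dQ/dPsi (symmetric G) and the log-Cholesky
## parameter vector, return dQ/dtheta.
chol_chain_grad <- function(G, theta, d) {
  L <- par_to_chol(theta, d)
  GL <- 2 * G %*% L
  GL <- GL * lower.tri(GL, diag = TRUE)
  diag(GL) <- diag(GL) * diag(L)
  GL[lower.tri(GL, diag = TRUE)]
}

is_spd <- function(S, tol = 1e-10) {
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) return(FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev), 1))
}

## Central-difference gradient and Hessian (used for observed-information
## standard errors where analytic second derivatives are not worth the code).
num_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    h <- eps * max(1, abs(x[j]))
    xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

num_jacobian <- function(f, x, eps = 1e-5) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xm <- x
    h <- eps * max(1, abs(x[j]))
    xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

## Group rows of a matrix by missingness pattern. Returns a list with, per
## pattern, the observed-coordinate index set and the row indices.
missing_patterns <- function(X) {
  obs <- !is.na(X)
  key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  idx <- split(seq_len(nrow(X)), key)
  lapply(idx, function(rows) {
    list(obs = which(obs[rows[1L], ]), rows = rows)
  })
}

## Deterministic child seeds derived from one user seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 104729L * seq_len(n)) %% 2147483629L
}

## Upper-triangular-style square root of a positive semidefinite matrix
## (chol when PD, eigen fallback so zero matrices are valid).
psd_sqrt <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors))
}
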