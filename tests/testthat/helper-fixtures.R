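# Shared fixture builders: everything is generated in code at test time.

## Growth data simulated from known parameters, optional MCAR missingness.
sim_growth_data <- function(n, alpha, psi, theta, miss = 0, seed = 1) {
  set.seed(seed)
  L <- growth_spec()$loading
  eta <- matrix(rnorm(n * 4), n, 4) %*% chol(psi + diag(1e-10, 4)) +
    matrix(alpha, n, 4, byrow = TRUE)
  X <- eta %*% t(L) + matrix(rnorm(n * 6), n, 6) %*% diag(sqrt(theta))
  if (miss > 0) X[sample(length(X), round(miss * length(X)))] <- NA
  X
}

## Two-block indicator data (6 growth + 6 eight-year) from a K-class design.
sim_mixture_data <- function(n, prior, alphas, nu, psi, theta, sig8,
                             miss = 0, seed = 1) {
  set.seed(seed)
  L <- growth_spec()$loading
  K <- length(prior)
  cls <- sample.int(K, n, TRUE, prior)
  eta <- matrix(rnorm(n * 4), n, 4) %*% chol(psi + diag(1e-10, 4)) +
    alphas[cls, , drop = FALSE]
  Xg <- eta %*% t(L) + matrix(rnorm(n * 6), n, 6) %*% diag(sqrt(theta))
  X8 <- nu[cls, , drop = FALSE] +
    matrix(rnorm(n * 6), n, 6) %*% diag(sqrt(sig8))
  X <- cbind(Xg, X8)
  if (miss > 0) {
    X[sample(length(X), round(miss * length(X)))] <- NA
    drop_rows <- rowSums(!is.na(X)) == 0
    X <- X[!drop_rows, , drop = FALSE]
    cls <- cls[!drop_rows]
  }
  list(X = X, cls = cls)
}

## Adjusted Rand index (independent implementation for recovery checks).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

## Brute-force Benjamini-Hochberg step-up (oracle, independent of p.adjust).
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (r in m:1) {
    prev <- min(prev, p[o[r]] * m / r)
    adj[o[r]] <- prev
  }
  pmin(adj, 1)
}

## Default-design truth helpers.
design_props <- function() {
  vapply(default_class_specs(), `[[`, numeric(1), "proportion")
}
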