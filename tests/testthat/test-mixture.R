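# Shared two-class fixture: well separated in both blocks.
two_class_design <- function() {
  list(prior = c(0.6, 0.4),
       alphas = rbind(c(0, 0, 0, 0), c(1.5, 0.3, 1.5, 0.3)),
       nu = rbind(rep(0, 6), rep(1.5, 6)),
       psi = diag(c(0.2, 0.02, 0.2, 0.02)),
       theta = rep(0.2, 6), sig8 = rep(0.25, 6))
}

test_that("entropy hits its boundary values and the hand-computed case", {
  expect_equal(entropy(matrix(1 / 3, 50, 3)), 0)
  hard <- diag(4)[sample(1:4, 30, TRUE), ]
  expect_equal(entropy(hard), 1)
  P <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  expected <- 1 - (-(0.9 * log(0.9) + 0.1 * log(0.1)) + log(2)) /
    (2 * log(2))
  expect_equal(entropy(P), expected, tolerance = 1e-12)
  expect_error(entropy(matrix(1, 10, 1)), "K = 1")
})

test_that("a K = 1 mixture reproduces the FIML growth fit", {
  d <- two_class_design()
  sim <- sim_mixture_data(400, 1, d$alphas[1, , drop = FALSE],
                          d$nu[1, , drop = FALSE], d$psi, d$theta, d$sig8,
                          miss = 0.15, seed = 51)
  fit1 <- fit_mixture(sim$X, K = 1, n_starts = 1, seed = 1,
                      control = list(max_iter = 200))
  lgm <- fit_growth(sim$X[, 1:6])
  expect_equal(unname(drop(fit1$alphas)), unname(lgm$alpha),
               tolerance = 1e-4)
  expect_equal(fit1$psi, lgm$psi, tolerance = 1e-3)
  ## 8-year block reduces to observed-sample means and variances
  for (j in 1:6) {
    xj <- sim$X[, 6 + j]
    expect_equal(unname(fit1$nu[1, j]), mean(xj, na.rm = TRUE),
                 tolerance = 1e-6)
    n_obs <- sum(!is.na(xj))
    expect_equal(unname(fit1$sig8[j]),
                 var(xj, na.rm = TRUE) * (n_obs - 1) / n_obs,
                 tolerance = 1e-5)
  }
  expect_equal(fit1$pi, 1)
})

test_that("well-separated classes are recovered almost perfectly", {
  d <- two_class_design()
  sim <- sim_mixture_data(500, d$prior, d$alphas, d$nu, d$psi, d$theta,
                          d$sig8, miss = 0.1, seed = 52)
  fit <- fit_mixture(sim$X, K = 2, n_starts = 3, seed = 5)
  expect_gt(adjusted_rand_index(fit$modal, sim$cls), 0.95)
  ## EM invariants on the same fixture
  expect_true(all(diff(fit$loglik_trace) > -1e-6 * abs(fit$loglik)))
  expect_equal(rowSums(fit$posterior), rep(1, fit$n), tolerance = 1e-10)
  expect_equal(unname(colMeans(fit$posterior)), unname(fit$pi),
               tolerance = 1e-3)
  ## canonical label order: descending mixing proportion
  expect_true(all(diff(fit$pi) <= 0))
})

test_that("the class-conditional likelihood is label-permutation symmetric", {
  d <- two_class_design()
  sim <- sim_mixture_data(300, d$prior, d$alphas, d$nu, d$psi, d$theta,
                          d$sig8, seed = 53)
  pats <- trajprofile:::missing_patterns(sim$X)
  L <- growth_spec()$loading
  e1 <- trajprofile:::mixture_estep(sim$X, pats, L, d$prior, d$alphas,
                                    d$psi, d$theta, d$nu, d$sig8)
  perm <- c(2, 1)
  e2 <- trajprofile:::mixture_estep(sim$X, pats, L, d$prior[perm],
                                    d$alphas[perm, ], d$psi, d$theta,
                                    d$nu[perm, ], d$sig8)
  expect_equal(e1$loglik, e2$loglik, tolerance = 1e-10)
  expect_equal(e1$post, e2$post[, perm], tolerance = 1e-12)
})

test_that("log-likelihood is non-decreasing in K on a shared fixture", {
  d <- two_class_design()
  sim <- sim_mixture_data(350, d$prior, d$alphas, d$nu, d$psi, d$theta,
                          d$sig8, seed = 54)
  lls <- vapply(1:3, function(K)
    fit_mixture(sim$X, K, n_starts = 2, seed = 7,
                control = list(max_iter = 300))$loglik, numeric(1))
  expect_true(all(diff(lls) > -1e-6 * abs(lls[1])))
})

test_that("class enumeration identifies a clear 3-class structure by BIC", {
  prior <- c(0.5, 0.3, 0.2)
  alphas <- rbind(c(0, 0, 0, 0), c(1.8, 0.3, 0, 0), c(0, 0, 1.8, 0.3))
  nu <- rbind(rep(0, 6), rep(1.6, 6), rep(-1.6, 6))
  psi <- diag(c(0.2, 0.02, 0.2, 0.02))
  hits <- 0L
  for (r in 1:20) {
    sim <- sim_mixture_data(500, prior, alphas, nu, psi, rep(0.2, 6),
                            rep(0.25, 6), seed = 500 + r)
    rep_tab <- enumerate_classes(sim$X, K_range = 2:4, n_starts = 2,
                                 seed = r, control = list(max_iter = 150))
    if (rep_tab$K[which.min(rep_tab$bic)] == 3) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("the enumeration report applies the smallest-profile rule", {
  ## a 0.5%-of-sample class must flip the accepted flag off
  prior <- c(0.995, 0.005)
  alphas <- rbind(rep(0, 4), c(4, 0.5, 4, 0.5))
  nu <- rbind(rep(0, 6), rep(4, 6))
  sim <- sim_mixture_data(3000, prior, alphas,
                          nu, diag(c(0.1, 0.01, 0.1, 0.01)), rep(0.15, 6),
                          rep(0.2, 6), seed = 56)
  tab <- enumerate_classes(sim$X, K_range = 1:2, n_starts = 2, seed = 3,
                           control = list(max_iter = 200))
  expect_true(is.na(tab$entropy[tab$K == 1]))   # no entropy entry at K = 1
  expect_true(tab$accepted[tab$K == 1])
  k2 <- tab[tab$K == 2, ]
  expect_lt(k2$smallest_class, 0.01)
  expect_false(k2$accepted)
  ## BIC/aBIC arithmetic is consistent with the stored loglik
  n <- sum(rowSums(!is.na(sim$X)) > 0)
  expect_equal(k2$bic, -2 * k2$loglik + k2$npar * log(n))
  expect_equal(k2$abic, -2 * k2$loglik + k2$npar * log((n + 2) / 24))
})

test_that("posterior prediction matches training posteriors", {
  d <- two_class_design()
  sim <- sim_mixture_data(250, d$prior, d$alphas, d$nu, d$psi, d$theta,
                          d$sig8, seed = 57)
  fit <- fit_mixture(sim$X, K = 2, n_starts = 2, seed = 9)
  pred <- predict(fit, sim$X)
  expect_equal(unname(pred), unname(fit$posterior), tolerance = 1e-10)
})

test_that("degenerate inputs are rejected", {
  d <- two_class_design()
  sim <- sim_mixture_data(15, d$prior, d$alphas, d$nu, d$psi, d$theta,
                          d$sig8, seed = 58)
  expect_error(fit_mixture(sim$X, K = 2), "n >= 10")
})
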