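test_that("implied moments follow the growth algebra", {
  sp <- growth_spec()
  ## noise-only
  m0 <- implied_moments(sp, list(alpha = rep(0, 4), psi = matrix(0, 4, 4),
                                 theta = rep(1, 6)))
  expect_equal(m0$mean, rep(0, 6), ignore_attr = TRUE)
  expect_equal(m0$cov, diag(6), ignore_attr = TRUE)
  ## deterministic line 1 + 0.5 * lambda at lambda = (0, 1.5, 3.5)
  m1 <- implied_moments(sp, list(alpha = c(1, 0.5, 0, 0),
                                 psi = matrix(0, 4, 4), theta = rep(0, 6)))
  expect_equal(m1$mean[1:3], c(1, 1.75, 2.75), ignore_attr = TRUE)
  expect_equal(m1$mean[4:6], rep(0, 3), ignore_attr = TRUE)
  ## linearity: shifting both intercepts shifts the matching process means
  base <- implied_moments(sp, list(alpha = c(0.3, 0.1, -0.2, 0.05),
                                   psi = diag(0.1, 4), theta = rep(0.2, 6)))
  shft <- implied_moments(sp, list(alpha = c(0.3 + 2, 0.1, -0.2 + 2, 0.05),
                                   psi = diag(0.1, 4), theta = rep(0.2, 6)))
  expect_equal(shft$mean, base$mean + 2)
  expect_equal(shft$cov, base$cov)
  ## invalid parameters
  badpsi <- diag(4); badpsi[1, 1] <- -1
  expect_error(implied_moments(sp, list(alpha = rep(0, 4), psi = badpsi,
                                        theta = rep(1, 6))), "semidefinite")
})

test_that("FIML equals the complete-data likelihood when nothing is missing", {
  sp <- growth_spec()
  params <- list(alpha = c(0.2, 0.1, -0.3, 0.05),
                 psi = diag(c(0.3, 0.02, 0.3, 0.02)), theta = rep(0.25, 6))
  X <- sim_growth_data(150, params$alpha, params$psi, params$theta, seed = 41)
  mom <- implied_moments(sp, params)
  oracle <- sum(mvtnorm::dmvnorm(X, mom$mean, mom$cov, log = TRUE))
  expect_equal(fiml_loglik(X, sp, params), oracle, tolerance = 1e-10)
})

test_that("a row observed at a single wave contributes a univariate density", {
  sp <- growth_spec()
  params <- list(alpha = c(0.2, 0.1, -0.3, 0.05),
                 psi = diag(c(0.3, 0.02, 0.3, 0.02)), theta = rep(0.25, 6))
  mom <- implied_moments(sp, params)
  X <- matrix(NA_real_, 1, 6)
  X[1, 1] <- 0.7
  expect_equal(fiml_loglik(X, sp, params),
               dnorm(0.7, mom$mean[1], sqrt(mom$cov[1, 1]), log = TRUE),
               tolerance = 1e-12)
})

test_that("masking independent coordinates drops exactly their densities", {
  sp <- growth_spec()
  ## psi = 0 and diagonal theta make all six coordinates independent
  params <- list(alpha = c(0.5, 0.1, -0.2, 0), psi = matrix(0, 4, 4),
                 theta = c(0.2, 0.3, 0.4, 0.2, 0.3, 0.4))
  X <- sim_growth_data(40, params$alpha, params$psi, params$theta, seed = 42)
  mom <- implied_moments(sp, params)
  Xmask <- X
  Xmask[, c(2, 5)] <- NA
  dropped <- sum(dnorm(X[, 2], mom$mean[2], sqrt(mom$cov[2, 2]), log = TRUE)) +
    sum(dnorm(X[, 5], mom$mean[5], sqrt(mom$cov[5, 5]), log = TRUE))
  expect_equal(fiml_loglik(X, sp, params) - fiml_loglik(Xmask, sp, params),
               dropped, tolerance = 1e-8)
})

test_that("rows with no observed values are excluded with a message", {
  sp <- growth_spec()
  params <- list(alpha = rep(0, 4), psi = diag(0.1, 4), theta = rep(0.3, 6))
  X <- sim_growth_data(10, params$alpha, params$psi, params$theta, seed = 43)
  Xplus <- rbind(X, NA)
  expect_message(ll <- fiml_loglik(Xplus, sp, params), "1 row")
  expect_equal(ll, fiml_loglik(X, sp, params))
})

test_that("the FIML fit recovers generating parameters", {
  alpha <- c(0.3, 0.15, -0.2, 0.08)
  psi <- trajprofile:::default_growth_factor_cov()
  theta <- rep(0.2, 6)
  X <- sim_growth_data(5000, alpha, psi, theta, seed = 44)
  fit <- fit_growth(X)
  expect_true(all(abs(fit$alpha - alpha) < 3 * fit$se_alpha))
  expect_lt(max(abs(fit$psi - psi)), 0.1 * max(diag(psi)))
  expect_lt(max(abs(fit$theta - theta)), 0.03)
})

test_that("FIML under 30% MCAR agrees with the complete-data fit", {
  alpha <- c(0.3, 0.15, -0.2, 0.08)
  psi <- trajprofile:::default_growth_factor_cov()
  theta <- rep(0.2, 6)
  X <- sim_growth_data(3000, alpha, psi, theta, seed = 45)
  fit_full <- fit_growth(X)
  Xm <- X
  set.seed(46)
  Xm[sample(length(Xm), 0.3 * length(Xm))] <- NA
  fit_miss <- fit_growth(Xm)
  comb_se <- sqrt(fit_full$se_alpha^2 + fit_miss$se_alpha^2)
  expect_true(all(abs(fit_full$alpha - fit_miss$alpha) < 3 * comb_se))
})

test_that("the optimum satisfies the GLS stationarity identity for the means", {
  ## with complete data, the ML factor means solve generalized least squares
  ## against the sample column means under the fitted implied covariance
  alpha <- c(0.2, 0.1, 0.4, -0.05)
  X <- sim_growth_data(1500, alpha, diag(c(0.2, 0.01, 0.2, 0.01)),
                       rep(0.3, 6), seed = 47)
  fit <- fit_growth(X)
  sp <- growth_spec()
  Sig <- implied_moments(sp, list(alpha = fit$alpha, psi = fit$psi,
                                  theta = fit$theta))$cov
  L <- sp$loading
  xbar <- colMeans(X)
  W <- solve(Sig)
  gls <- solve(t(L) %*% W %*% L, t(L) %*% W %*% xbar)
  expect_equal(unname(fit$alpha), unname(drop(gls)), tolerance = 1e-4)
})

test_that("the fitted solution is a local maximum of the FIML likelihood", {
  alpha <- c(0.1, 0.05, 0.2, 0)
  psi <- diag(c(0.2, 0.02, 0.2, 0.02))
  theta <- rep(0.25, 6)
  X <- sim_growth_data(800, alpha, psi, theta, miss = 0.2, seed = 48)
  fit <- fit_growth(X)
  sp <- growth_spec()
  ll_hat <- fiml_loglik(X, sp, list(alpha = fit$alpha, psi = fit$psi,
                                    theta = fit$theta))
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-6)
  set.seed(49)
  for (r in 1:10) {
    pert <- list(alpha = fit$alpha + rnorm(4, sd = 0.02),
                 psi = fit$psi + crossprod(matrix(rnorm(16, sd = 0.01), 4)),
                 theta = fit$theta * exp(rnorm(6, sd = 0.05)))
    expect_lt(fiml_loglik(X, sp, pert), ll_hat + 1e-6)
  }
})

test_that("small samples warn", {
  X <- sim_growth_data(30, rep(0, 4), diag(0.1, 4), rep(0.3, 6), seed = 50)
  expect_warning(fit_growth(X), "n < 50")
})
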