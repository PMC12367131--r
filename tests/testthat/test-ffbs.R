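test_that("forward filter matches the dense-Gaussian oracle on a toy chain", {
  set.seed(431)
  pars <- subject_params(1, a = 0.8, sigma2 = 0.3, mu_x = 0.4)
  y <- c(1, 0, 1, 1, 0)
  psi_u <- rnorm(5)
  omega <- rpg(5, rnorm(5))
  for (init in c("innovation", "stationary")) {
    ff <- forward_filter(y, omega, psi_u, pars, init = init)
    oracle <- dense_filter(y, omega, psi_u, pars, init = init)
    expect_equal(ff$means, oracle$means, tolerance = 1e-10)
    expect_equal(ff$variances, oracle$variances, tolerance = 1e-10)
  }
})

test_that("filter degenerates correctly in the limiting regimes", {
  # deterministic state: sigma2 -> 0, a = 0 collapses onto b at every trial
  pars <- subject_params(1, a = 0, sigma2 = 0, mu_x = 0.6)
  y <- rep(c(0L, 1L), 5)
  ff <- forward_filter(y, rpg(10, 0), rep(0, 10), pars)
  expect_equal(ff$means, rep(0.6, 10), tolerance = 1e-4)
  expect_true(all(ff$variances <= 1e-12))
  expect_equal(backward_sample(ff, pars), rep(0.6, 10), tolerance = 1e-4)

  # omega = 0 trials: the quadratic pseudo-observation term vanishes, so
  # the filtering variances revert to the AR(1) prior marginals while the
  # means keep the linear exp(kappa x) tilt of the augmented likelihood
  pars2 <- subject_params(1, a = 0.9, sigma2 = 0.25, mu_x = -0.3)
  T_i <- 8
  y2 <- rep(0L, T_i)
  ff2 <- forward_filter(y2, rep(0, T_i), rep(0, T_i), pars2)
  v_prior <- numeric(T_i)
  v_prior[1] <- pars2$sigma2
  for (t in 2:T_i) v_prior[t] <- pars2$a^2 * v_prior[t - 1] + pars2$sigma2
  expect_equal(ff2$variances, v_prior, tolerance = 1e-10)
  oracle2 <- dense_filter(y2, rep(0, T_i), rep(0, T_i), pars2)
  expect_equal(ff2$means, oracle2$means, tolerance = 1e-10)

  expect_error(forward_filter(y, rep(-1, 10), rep(0, 10), pars2), "omega")
})

test_that("filtering variances are bounded by the first-state prior scale
           when every observation is informative", {
  set.seed(432)
  pars <- subject_params(1, a = 0.95, sigma2 = 0.2, mu_x = 0)
  T_i <- 60
  omega <- rpg(T_i, rnorm(T_i))
  ff <- forward_filter(rbinom(T_i, 1, 0.5), omega, rnorm(T_i), pars,
                       init = "stationary")
  expect_true(all(ff$variances <= pars$sigma2 / (1 - pars$a^2) + 1e-12))
})

test_that("FFBS joint draws reproduce the dense-Gaussian smoothing law", {
  set.seed(433)
  T_i <- 6
  pars <- subject_params(1, a = 0.85, sigma2 = 0.4, mu_x = 0.3)
  y <- rbinom(T_i, 1, 0.5)
  psi_u <- rnorm(T_i)
  omega <- rpg(T_i, rnorm(T_i))
  oracle <- dense_smoother(y, omega, psi_u, pars)
  ff <- forward_filter(y, omega, psi_u, pars)
  n <- 4e4
  draws <- matrix(NA_real_, n, T_i)
  for (k in seq_len(n)) draws[k, ] <- backward_sample(ff, pars)
  # per-trial smoothing marginals within Monte-Carlo error
  mc_se <- sqrt(diag(oracle$cov) / n)
  expect_true(all(abs(colMeans(draws) - oracle$mean) < 4 * mc_se))
  expect_equal(apply(draws, 2, var), diag(oracle$cov), tolerance = 0.05)
  # lag-1 joint covariance
  lag1 <- vapply(1:(T_i - 1), function(t) cov(draws[, t], draws[, t + 1]),
                 numeric(1))
  expect_equal(lag1, oracle$cov[cbind(1:(T_i - 1), 2:T_i)], tolerance = 0.06)
  expect_error(backward_sample(list(means = 1:3, variances = 1:2), pars),
               "mismatch")
})
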