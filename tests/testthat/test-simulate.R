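test_that("AR(1) simulation matches its closed-form moments", {
  set.seed(411)
  # noise-free, memory-free: constant at b = mu_x
  p0 <- subject_params(1, a = 0, sigma2 = 0, mu_x = 0.7)
  expect_equal(simulate_ar1(p0, 50), rep(0.7, 50))

  # stationary variance sigma2 / (1 - a^2) at a = 0.98, sigma2 = 0.2
  p1 <- subject_params(1, a = 0.98, sigma2 = 0.2, mu_x = 0)
  x <- simulate_ar1(p1, 1e5, init = "stationary")
  expect_equal(var(x), 0.2 / (1 - 0.98^2), tolerance = 0.05)

  # lag-1 autocorrelation approximates a
  p2 <- subject_params(1, a = 0.9, sigma2 = 0.3, mu_x = 0.2)
  x2 <- simulate_ar1(p2, 1e5)
  expect_equal(cor(x2[-1], x2[-length(x2)]), 0.9, tolerance = 0.02)

  # long-run mean converges to mu_x (within 3 Monte-Carlo s.e. of the
  # AR(1) mean, whose variance is approx. var(x) (1+a)/(1-a) / T)
  se <- sqrt(var(x2) * (1 + 0.9) / (1 - 0.9) / length(x2))
  expect_lt(abs(mean(x2) - 0.2), 3 * se)

  expect_error(simulate_ar1(subject_params(1, 1, 0.1), 10,
                            init = "stationary"), "a < 1")
})

test_that("subject simulation follows the Bernoulli observation model", {
  set.seed(412)
  # fair coin when all log-odds are zero
  p0 <- subject_params(0, a = 0, sigma2 = 0, mu_x = 0)
  s0 <- simulate_subject(p0, matrix(rnorm(1e4)))
  expect_lt(abs(mean(s0$data$responses) - 0.5), 3 * 0.5 / sqrt(1e4))

  # single signed evidence level: P(y = 1 | u = +1) = sigmoid(1.25)
  p1 <- subject_params(1.25, a = 0, sigma2 = 0, mu_x = 0)
  u <- matrix(sample(c(-1, 1), 2e4, replace = TRUE))
  s1 <- simulate_subject(p1, u)
  pos <- u[, 1] > 0
  expect_equal(mean(s1$data$responses[pos]), sigmoid(1.25), tolerance = 0.02)
  expect_equal(mean(s1$data$responses[!pos]), sigmoid(-1.25),
               tolerance = 0.02)

  # saturated criterion
  p2 <- subject_params(0.3, a = 1, sigma2 = 0, mu_x = 5)
  s2 <- simulate_subject(p2, matrix(rnorm(2000)))
  expect_gt(mean(s2$data$responses), 0.95)

  expect_error(simulate_subject(p1, matrix(rnorm(20), 10, 2)), "columns")

  # response probabilities always strictly inside (0, 1): responses vary
  # even under strong criterion excursions
  expect_true(all(s1$data$responses %in% c(0L, 1L)))
})

test_that("truncated-normal persistence draws match the closed-form mean", {
  set.seed(413)
  draws <- rtnorm(1e5, 0.98, 0.03, 0, 1)
  expect_true(all(draws >= 0 & draws <= 1))
  expect_equal(mean(draws), tnorm_mean(0.98, 0.03), tolerance = 0.005)
})

test_that("hierarchical simulation honors the group-level distributions", {
  eta <- default_hyper_params()
  sim <- simulate_dataset(eta, n_subjects = 30, n_trials = 40, seed = 414)
  expect_length(sim$data, 30)
  expect_true(all(vapply(sim$data, `[[`, integer(1), "n_trials") == 40))
  # derived intercept identity holds for every simulated subject
  for (pr in sim$params) expect_equal(pr$b, pr$mu_x * (1 - pr$a))
  a_vals <- vapply(sim$params, `[[`, numeric(1), "a")
  expect_true(all(a_vals >= 0 & a_vals <= 1))
  expect_true(all(vapply(sim$params, `[[`, numeric(1), "sigma2") > 0))

  # degenerate hierarchy: all subjects collapse onto the group means
  eta0 <- hyper_params(c(0.5, -0.2), c(1e-12, 1e-12), 0.9, 1e-12,
                       0.1, 1e4, 1e-12)
  sim0 <- simulate_dataset(eta0, 5, 10, seed = 415)
  for (pr in sim0$params) {
    expect_equal(pr$w, c(0.5, -0.2), tolerance = 1e-4)
    expect_equal(pr$mu_x, 0, tolerance = 1e-4)
  }
})

test_that("simulation is reproducible and subject streams are independent", {
  eta <- default_hyper_params()
  s1 <- simulate_dataset(eta, 6, 25, seed = 416)
  s2 <- simulate_dataset(eta, 6, 25, seed = 416)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$trajectories, s2$trajectories)
  # growing the dataset leaves earlier subjects' draws untouched
  s3 <- simulate_dataset(eta, 9, 25, seed = 416)
  expect_identical(s1$data[[3]], s3$data[[3]])
  # caller's RNG state is restored
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_dataset(eta, 2, 10, seed = 417))
  expect_identical(rnorm(1), before)
})
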