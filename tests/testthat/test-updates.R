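test_that("weight update reduces to the prior with no trials and respects
           the criterion offset", {
  set.seed(441)
  # T = 0: draws follow N(mu_w, diag(sigma2_w))
  draws <- t(replicate(4000, update_weights(
    integer(0), matrix(numeric(0), 0, 2), numeric(0), numeric(0),
    mu_w = c(1, -2), sigma2_w = c(0.5, 2))))
  expect_equal(colMeans(draws), c(1, -2), tolerance = 0.06)
  expect_equal(apply(draws, 2, var), c(0.5, 2), tolerance = 0.1)

  # the conditional depends on the trajectory only through kappa - omega x:
  # a criterion shift is absorbed, not attributed to the weights
  T_i <- 50
  u <- matrix(rnorm(T_i))
  y <- rbinom(T_i, 1, 0.5)
  om <- rpg(T_i, 0.3)
  x <- rnorm(T_i)
  set.seed(442); w1 <- update_weights(y, u, x, om, 0, 1)
  # same RNG, shifted trajectory with compensating pseudo-observations:
  # shifting x by delta changes the conditional mean by -delta * S_ux / prec
  delta <- 0.7
  set.seed(442); w2 <- update_weights(y, u, x + delta, om, 0, 1)
  prec <- 1 + sum(om * u[, 1]^2)
  expect_equal(w2 - w1, -delta * sum(om * u[, 1]) / prec, tolerance = 1e-10)

  expect_error(update_weights(y, u, x, om, 0, -1), "positive")
})

test_that("PG-augmented Gibbs for the weights targets the exact Bernoulli
           posterior (dense-grid oracle)", {
  set.seed(443)
  T_i <- 200
  u <- matrix(rnorm(T_i))
  x <- simulate_ar1(subject_params(1, 0.9, 0.1, 0), T_i)
  y <- rbinom(T_i, 1, sigmoid(0.8 * u[, 1] + x))
  mu0 <- 0; v0 <- 4
  n_keep <- 5000; thin <- 5
  w <- 0
  draws <- numeric(n_keep)
  for (k in seq_len(n_keep * thin)) {
    om <- rpg(T_i, u[, 1] * w + x)
    w <- update_weights(y, u, x, om, mu0, v0)
    if (k %% thin == 0) draws[k / thin] <- w
  }
  grid <- seq(-1, 3, length.out = 2000)
  logpost <- vapply(grid, function(wg) {
    eta <- wg * u[, 1] + x
    dnorm(wg, mu0, sqrt(v0), log = TRUE) +
      sum(y * eta - log1p(exp(eta)))
  }, numeric(1))
  expect_lt(grid_ks(draws, grid, logpost), 0.05)
})

test_that("persistence conditional matches a grid oracle and is consistent", {
  set.seed(444)
  T_i <- 200
  a0 <- 0.9; s20 <- 0.25; mux0 <- 0.3
  x <- simulate_ar1(subject_params(1, a0, s20, mux0), T_i)
  mu_a <- 0.85; s2_a <- 0.05^2
  draws <- replicate(5000, update_a(x, a0, s20, mux0, mu_a, s2_a))
  grid <- seq(1e-4, 1 - 1e-4, length.out = 3000)
  xc <- x - mux0
  logpost <- vapply(grid, function(a) {
    dtnorm(a, mu_a, sqrt(s2_a), 0, 1, log = TRUE) -
      sum((xc[-1] - a * xc[-T_i])^2) / (2 * s20)
  }, numeric(1))
  expect_lt(grid_ks(draws, grid, logpost), 0.05)

  # dogmatic prior pins the draw at mu_a
  pin <- replicate(50, update_a(x, a0, s20, mux0, 0.5, 1e-12))
  expect_equal(pin, rep(0.5, 50), tolerance = 1e-4)

  # near-asymptotic consistency
  xl <- simulate_ar1(subject_params(1, 0.95, 0.3, 0), 1e5)
  est <- mean(replicate(300, update_a(xl, 0.95, 0.3, 0, 0.8, 0.1)))
  expect_equal(est, 0.95, tolerance = 0.01)
})

test_that("innovation-variance conditional matches its grid oracle and is
           consistent", {
  set.seed(445)
  T_i <- 200
  a0 <- 0.9; s20 <- 0.25; mux0 <- -0.2
  x <- simulate_ar1(subject_params(1, a0, s20, mux0), T_i)
  al <- 3.5; be <- 0.5
  draws <- replicate(5000, update_sigma2(x, a0, mux0, al, be))
  grid <- exp(seq(log(0.05), log(1.5), length.out = 3000))
  xc <- x - mux0
  logpost <- vapply(grid, function(s2) {
    dinvgamma(s2, al, be, log = TRUE) - (T_i - 1) / 2 * log(s2) -
      sum((xc[-1] - a0 * xc[-T_i])^2) / (2 * s2) -
      0.5 * log(s2) - xc[1]^2 / (2 * s2)
  }, numeric(1))
  # grid is log-spaced: weight by the grid cell widths via the jacobian
  expect_lt(grid_ks(draws, grid, logpost + log(grid)), 0.05)

  xl <- simulate_ar1(subject_params(1, 0.9, 0.2, 0), 1e5)
  est <- mean(replicate(300, update_sigma2(xl, 0.9, 0, al, be)))
  expect_equal(est, 0.2, tolerance = 0.004)  # within 2%

  # zero-residual trajectory: posterior is the prior updated in shape only
  xz <- rep(0.4, 100)  # a = 1, mu_x = 0.4 gives zero residuals
  dz <- replicate(4000, update_sigma2(xz, 1, 0.4, al, be, init = "fixed"))
  expect_equal(mean(dz), be / (al + 99 / 2 - 1), tolerance = 0.02)
})

test_that("trajectory-mean conditional matches its grid oracle", {
  set.seed(446)
  T_i <- 200
  a0 <- 0.9; s20 <- 0.25; mux0 <- 0.5
  x <- simulate_ar1(subject_params(1, a0, s20, mux0), T_i)
  v_mux <- 0.25
  draws <- replicate(5000, update_mux(x, a0, s20, v_mux))
  grid <- seq(-2, 3, length.out = 3000)
  logpost <- vapply(grid, function(m) {
    xc <- x - m
    -m^2 / (2 * v_mux) - sum((xc[-1] - a0 * xc[-T_i])^2) / (2 * s20) -
      xc[1]^2 / (2 * s20)
  }, numeric(1))
  expect_lt(grid_ks(draws, grid, logpost), 0.05)

  # dogmatic prior pins mu_x at zero
  expect_equal(update_mux(x, a0, s20, 1e-14), 0, tolerance = 1e-5)

  # constant trajectory with a = 0 centers near that constant
  xc <- rep(1.2, 400)
  dc <- replicate(2000, update_mux(xc, 0, 0.1, 100))
  expect_equal(mean(dc), 1.2, tolerance = 0.01)
})

test_that("closed-form group-level updates are conjugate-correct", {
  set.seed(447)
  hp <- hyperprior_config()
  eta <- hyper_params(0, 1, 0.9, 0.01, 0.2, 0.5, 0.3)

  # single subject: posterior mean of mu_w sits between hyperprior mean
  # and the subject's weight, at the conjugate ratio
  w1 <- matrix(2.5, 1, 1)
  draws <- replicate(4000, update_global_normals(w1, 0.3, eta, hp)$mu_w)
  exp_mean <- (hp$m0_w / hp$v0_w + 2.5 / 1) / (1 / hp$v0_w + 1)
  expect_equal(mean(draws), exp_mean, tolerance = 0.05)

  # many subjects: concentration at the empirical mean
  wN <- matrix(rnorm(2000, 1.4, 0.3))
  dN <- replicate(500, update_global_normals(wN, rnorm(2000), eta, hp)$mu_w)
  expect_equal(mean(dN), mean(wN), tolerance = 0.01)

  # grid oracle for p = 1, N = 5: mu_w | w, sigma2_w
  w5 <- matrix(c(0.2, 1.1, -0.4, 0.8, 0.5))
  d5 <- replicate(5000,
                  update_global_normals(w5, rnorm(5), eta, hp)$mu_w)
  grid <- seq(-2, 3, length.out = 2000)
  logpost <- vapply(grid, function(m) {
    dnorm(m, hp$m0_w, sqrt(hp$v0_w), log = TRUE) +
      sum(dnorm(w5[, 1], m, sqrt(eta$sigma2_w), log = TRUE))
  }, numeric(1))
  expect_lt(grid_ks(d5, grid, logpost), 0.05)
})

test_that("random-walk Metropolis on the persistence hyperparameters is
           consistent and logs acceptances", {
  set.seed(448)
  hp <- geweke_hyperpriors()
  a_vec <- rtnorm(500, 0.9, 0.05, 0, 1)
  s2_vec <- rinvgamma(500, 3.5, 0.5)
  eta <- hyper_params(0, 1, 0.8, 0.02, 0.3, 0.7, 0.3)
  n <- 4000
  out <- matrix(NA_real_, n, 2)
  acc <- logical(n)
  for (k in seq_len(n)) {
    r <- update_global_mh(a_vec, s2_vec, eta, hp,
                          steps = c(mu_a = 0.02, sigma2_a = 0.002,
                                    mu_sigma2 = 0.05, beta_sigma2 = 0.15))
    eta <- r$eta
    out[k, ] <- c(eta$mu_a, eta$mu_sigma2)
    acc[k] <- r$accept[["mu_a"]]
  }
  keep <- seq(500, n)
  expect_equal(mean(out[keep, 1]), 0.9, tolerance = 0.01)
  expect_equal(mean(out[keep, 2]), 0.2, tolerance = 0.05)
  expect_true(mean(acc) > 0.05 && mean(acc) < 0.95)

  # near-zero-width proposals: the chain essentially never moves
  eta2 <- hyper_params(0, 1, 0.8, 0.02, 0.3, 0.7, 0.3)
  r2 <- update_global_mh(a_vec, s2_vec, eta2, hp,
                         steps = c(mu_a = 1e-14, sigma2_a = 1e-14,
                                   mu_sigma2 = 1e-14, beta_sigma2 = 1e-14))
  expect_equal(r2$eta$mu_a, 0.8, tolerance = 1e-10)
  expect_equal(r2$eta$beta_sigma2, 0.7, tolerance = 1e-10)
})
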