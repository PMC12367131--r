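make_small_sim <- function(seed = 451, n_subjects = 4, n_trials = 60) {
  simulate_dataset(default_hyper_params(), n_subjects, n_trials, seed = seed)
}

test_that("sampler configuration validates its fields", {
  expect_error(sampler_config(iterations = 100, burn_in = 100))
  expect_error(sampler_config(mh_steps = c(mu_a = -1, sigma2_a = 1,
                                           mu_sigma2 = 1, beta_sigma2 = 1)))
  expect_error(sampler_config(fixed_a = 1.2))
  cfg <- sampler_config(iterations = 10, burn_in = 2)
  expect_s3_class(cfg, "sampler_config")
})

test_that("fits are bit-reproducible given a seed", {
  sim <- make_small_sim()
  cfg <- sampler_config(iterations = 30, burn_in = 5)
  f1 <- fit_hmfc(sim, cfg, seed = 452)
  f2 <- fit_hmfc(sim, cfg, seed = 452)
  expect_identical(f1$eta, f2$eta)
  expect_identical(f1$w, f2$w)
  expect_identical(f1$trajectory_mean, f2$trajectory_mean)
})

test_that("stored draws respect the parameter domains and derived
           identities at every iteration", {
  sim <- make_small_sim(453)
  fit <- fit_hmfc(sim, sampler_config(iterations = 60, burn_in = 10),
                  seed = 454)
  expect_true(all(fit$a >= 0 & fit$a <= 1))
  expect_true(all(fit$sigma2 > 0))
  expect_true(all(fit$eta[, c("sigma2_w_1", "sigma2_w_2", "sigma2_w_3",
                              "sigma2_a", "mu_sigma2", "beta_sigma2",
                              "sigma2_mux")] > 0))
  # derived inverse-gamma shape is consistent with its formula everywhere
  alpha <- fit$eta[, "beta_sigma2"] / fit$eta[, "mu_sigma2"] + 1
  expect_true(all(alpha > 1))
  expect_equal(nrow(fit$eta), 60)
})

test_that("clamping the persistence reproduces the fixed-a variant", {
  sim <- make_small_sim(455)
  cfg <- sampler_config(iterations = 25, burn_in = 5, fixed_a = 0.9995)
  fit <- fit_hmfc(sim, cfg, seed = 456)
  expect_true(all(fit$a == 0.9995))
  # group-level persistence parameters are frozen
  expect_equal(length(unique(fit$eta[, "mu_a"])), 1L)
})

test_that("disabling fluctuation estimation reduces to a hierarchical
           random-intercept logistic model", {
  sim <- make_small_sim(457)
  cfg <- sampler_config(iterations = 25, burn_in = 5,
                        estimate_fluctuations = FALSE)
  fit <- fit_hmfc(sim, cfg, seed = 458)
  # trajectories are flat at the per-subject intercept
  ts <- trajectory_summary(fit)
  for (id in unique(ts$subject)) {
    expect_equal(sd(ts$mean[ts$subject == id]), 0, tolerance = 1e-12)
  }
})

test_that("reduced model matches the exact posterior of a logistic
           regression with a random intercept (grid oracle)", {
  set.seed(459)
  T_i <- 200
  u <- matrix(rnorm(T_i), dimnames = list(NULL, "stim"))
  mux_true <- 0.6
  y <- rbinom(T_i, 1, sigmoid(1.1 * u[, 1] + mux_true))
  data <- list(subject_data(1, y, u))
  # freeze the hierarchy at known values so the oracle is two-dimensional
  hp <- hyperprior_config()
  cfg <- sampler_config(iterations = 20000, burn_in = 1000,
                        estimate_fluctuations = FALSE,
                        update_globals = FALSE, save_trajectories = FALSE)
  fit <- fit_hmfc(data, cfg, seed = 460)
  # init_state sets eta from the data; recover the frozen values used
  v_w <- fit$eta[1, "sigma2_w_1"]
  m_w <- fit$eta[1, "mu_w_1"]
  v_m <- fit$eta[1, "sigma2_mux"]
  # thin to near-independence so the KS comparison is calibrated
  idx <- seq(1001, 20000, by = 8)
  wg <- seq(-1, 3, length.out = 120)
  mg <- seq(-2, 3, length.out = 120)
  lp <- outer(wg, mg, Vectorize(function(w, m) {
    eta_t <- w * u[, 1] + m
    dnorm(w, m_w, sqrt(v_w), log = TRUE) + dnorm(m, 0, sqrt(v_m), log = TRUE) +
      sum(y * eta_t - log1p(exp(eta_t)))
  }))
  pw <- rowSums(exp(lp - max(lp)))
  expect_lt(grid_ks(fit$w[idx, 1, 1], wg, log(pw)), 0.05)
  pm <- colSums(exp(lp - max(lp)))
  expect_lt(grid_ks(fit$mu_x[idx, 1], mg, log(pm)), 0.05)
})

test_that("degenerate state-space settings flatten the trajectories", {
  set.seed(461)
  # generative fluctuations are negligible; clamp a low so the posterior
  # cannot attribute residual response noise to slow drift
  eta <- hyper_params(c(0.5), 0.5, 0.9, 0.01, 1e-6, 1e-4, 0.25)
  sim <- simulate_dataset(eta, 3, 200, seed = 462)
  cfg <- sampler_config(iterations = 60, burn_in = 20, fixed_a = 0.2)
  fit <- fit_hmfc(sim, cfg, seed = 463)
  pm <- posterior_means(fit)
  for (i in 1:3) {
    # trajectory posterior mean is essentially flat at mu_x
    expect_lt(sd(fit$trajectory_mean[[i]]), 0.2)
    expect_equal(mean(fit$trajectory_mean[[i]]), pm$mu_x[i],
                 tolerance = 0.2)
  }
})

test_that("errors in a subject update carry iteration and subject context", {
  sim <- make_small_sim(464)
  # corrupt a response after construction: the failure surfaces inside the
  # per-subject update blocks, not in input validation
  sim$data[[2]]$responses[5] <- NA_integer_
  expect_error(fit_hmfc(sim$data, sampler_config(iterations = 5, burn_in = 1),
                        seed = 465),
               "iteration 1.*subject 2")
})

test_that("posterior summaries have the documented shapes", {
  sim <- make_small_sim(466)
  fit <- fit_hmfc(sim, sampler_config(iterations = 40, burn_in = 10),
                  seed = 467)
  pm <- posterior_means(fit)
  expect_equal(dim(pm$w), c(4, 3))
  expect_length(pm$a, 4)
  expect_named(pm$eta)
  ts <- trajectory_summary(fit, level = 0.9)
  expect_equal(nrow(ts), 4 * 60)
  expect_true(all(ts$lower <= ts$mean & ts$mean <= ts$upper))
})
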