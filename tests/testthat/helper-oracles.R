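# Shared oracles and fixtures, all built in code at test time.

# Dense joint-Gaussian oracle for the PG-augmented criterion chain:
# builds the tridiagonal AR(1) prior precision plus the diagonal
# pseudo-observation precision, and returns the exact posterior mean
# vector and covariance matrix of x_{1:T}.
dense_smoother <- function(responses, omega, psi_u, params,
                           init = "innovation") {
  T_i <- length(responses)
  a <- params$a
  s2 <- params$sigma2
  b <- params$b
  P0 <- switch(init,
               innovation = s2,
               stationary = s2 / (1 - a^2),
               stop("unsupported init"))
  Q <- matrix(0, T_i, T_i)
  h <- numeric(T_i)
  Q[1, 1] <- 1 / P0
  h[1] <- params$mu_x / P0
  if (T_i > 1) {
    for (t in 2:T_i) {
      Q[t, t] <- Q[t, t] + 1 / s2
      Q[t - 1, t - 1] <- Q[t - 1, t - 1] + a^2 / s2
      Q[t - 1, t] <- Q[t - 1, t] - a / s2
      Q[t, t - 1] <- Q[t, t - 1] - a / s2
      h[t] <- h[t] + b / s2
      h[t - 1] <- h[t - 1] - a * b / s2
    }
  }
  kappa <- responses - 0.5
  Qp <- Q + diag(omega, T_i)
  hp <- h + kappa - omega * psi_u
  S <- solve(Qp)
  list(mean = drop(S %*% hp), cov = S)
}

# Filtered (not smoothed) oracle: exact marginals of p(x_t | y_{1:t})
# obtained by running the dense oracle on the first t trials only.
dense_filter <- function(responses, omega, psi_u, params,
                         init = "innovation") {
  T_i <- length(responses)
  means <- vars <- numeric(T_i)
  for (t in seq_len(T_i)) {
    sm <- dense_smoother(responses[1:t], omega[1:t], psi_u[1:t], params,
                         init)
    means[t] <- sm$mean[t]
    vars[t] <- sm$cov[t, t]
  }
  list(means = means, variances = vars)
}

# Kolmogorov-Smirnov distance between draws and a discretized density on a
# grid (density given as unnormalized log values at grid points).
grid_ks <- function(draws, grid, log_density) {
  d <- exp(log_density - max(log_density))
  d <- d / sum(d)
  # midpoint-corrected CDF: the probability mass of a cell is split around
  # its grid point, so the comparison is calibrated even on coarse grids
  max(abs(stats::ecdf(draws)(grid) - (cumsum(d) - d / 2)))
}

# Mean of a normal truncated to [lower, upper]
tnorm_mean <- function(mean, sd, lower = 0, upper = 1) {
  za <- (lower - mean) / sd
  zb <- (upper - mean) / sd
  mean + sd * (dnorm(za) - dnorm(zb)) / (pnorm(zb) - pnorm(za))
}

# Moderate-scale hyperprior constants used for joint-distribution
# (Geweke-style) sampler validation: tight enough that prior draws produce
# numerically tame datasets, while exercising every update.
geweke_hyperpriors <- function() {
  hyperprior_config(v0_w = 1, a0_w = 3, b0_w = 1, m0_a = 0.7, v0_a = 0.09,
                    a0_sa = 3, b0_sa = 0.04, a0_ms = 3, b0_ms = 0.4,
                    a0_bs = 3, b0_bs = 1, a0_mux = 3, b0_mux = 0.5)
}

# One joint prior draw of (eta, subject params, trajectories)
geweke_prior_state <- function(n_subjects, n_trials, p, hp) {
  eta <- draw_hyper_prior(p, hp)
  subjects <- lapply(seq_len(n_subjects), function(i) {
    w <- rnorm(p, eta$mu_w, sqrt(eta$sigma2_w))
    a <- rtnorm(1, eta$mu_a, sqrt(eta$sigma2_a), 0, 1)
    s2 <- rinvgamma(1, eta$alpha_sigma2, eta$beta_sigma2)
    mux <- rnorm(1, 0, sqrt(eta$sigma2_mux))
    list(w = w, a = a, sigma2 = s2, mu_x = mux,
         x = simulate_ar1(subject_params(w, a, s2, mux), n_trials))
  })
  list(subjects = subjects, eta = eta)
}

# scalar summaries tracked by the joint-distribution test
geweke_grab <- function(state) {
  st <- state$subjects[[1]]
  c(mu_w = unname(state$eta$mu_w[1]), sigma2_w = unname(state$eta$sigma2_w[1]),
    mu_a = state$eta$mu_a, sigma2_a = state$eta$sigma2_a,
    mu_sigma2 = state$eta$mu_sigma2, beta_sigma2 = state$eta$beta_sigma2,
    sigma2_mux = state$eta$sigma2_mux,
    w_subj = unname(st$w[1]), a_subj = st$a, sigma2_subj = st$sigma2,
    mux_subj = st$mu_x, x_first = st$x[1], x_last = st$x[length(st$x)])
}
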