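#' Sampler configuration
#'
#' @param iterations total Gibbs iterations recorded.
#' @param burn_in iterations discarded when forming posterior summaries
#'   (must be < `iterations`).
#' @param thin keep every `thin`-th post-burn-in sample in summaries.
#' @param mh_steps named random-walk proposal SDs for the four
#'   Metropolis-updated group parameters.
#' @param adapt adapt `mh_steps` during burn-in toward `adapt_target`
#'   acceptance (frozen afterwards, preserving detailed balance).
#' @param adapt_target target acceptance rate for the adaptation.
#' @param hyperpriors constants from [hyperprior_config()].
#' @param init initial-state convention for the latent chain (shared with
#'   the simulator; see [simulate_ar1()]).
#' @param fixed_a optional value in \[0, 1\]: clamp every subject's `a_i`
#'   (its update and the group-level `mu_a`/`sigma2_a` updates are skipped).
#' @param estimate_fluctuations when `FALSE`, the criterion is held fixed at
#'   `mu_x_i` (no trajectory, `a_i`, or `sigma2_i` updates): the model
#'   reduces to logistic regression with a hierarchical random intercept.
#' @param update_globals when `FALSE` the group-level parameters are frozen
#'   at their initial values (useful for conditional-distribution checks).
#' @param save_trajectories store thinned post-burn-in trajectory draws (at
#'   most `traj_max_draws`) for credible bands; the running posterior mean
#'   is always kept.
#' @param traj_max_draws cap on stored trajectory draws.
#' @param verbose print progress every 100 iterations.
#' @return a list of class `sampler_config`.
#' @export
sampler_config <- function(iterations = 1000, burn_in = 250, thin = 1,
                           mh_steps = c(mu_a = 0.01, sigma2_a = 0.005,
                                        mu_sigma2 = 0.05, beta_sigma2 = 0.1),
                           adapt = TRUE, adapt_target = 0.3,
                           hyperpriors = hyperprior_config(),
                           init = c("innovation", "stationary", "fixed"),
                           fixed_a = NULL, estimate_fluctuations = TRUE,
                           update_globals = TRUE,
                           save_trajectories = TRUE, traj_max_draws = 200,
                           verbose = FALSE) {
  init <- match.arg(init)
  stopifnot(iterations >= 1, burn_in >= 0, burn_in < iterations, thin >= 1,
            all(mh_steps > 0), adapt_target > 0, adapt_target < 1)
  if (!is.null(fixed_a)) {
    stopifnot(length(fixed_a) == 1, fixed_a >= 0, fixed_a <= 1)
  }
  structure(
    list(iterations = as.integer(iterations), burn_in = as.integer(burn_in),
         thin = as.integer(thin), mh_steps = mh_steps, adapt = adapt,
         adapt_target = adapt_target, hyperpriors = hyperpriors,
         init = init, fixed_a = fixed_a,
         estimate_fluctuations = estimate_fluctuations,
         update_globals = update_globals,
         save_trajectories = save_trajectories,
         traj_max_draws = as.integer(traj_max_draws), verbose = verbose),
    class = "sampler_config"
  )
}

# Starting state: per-subject logistic fits for w, logit of the response
# mean (clipped to +-2) for mu_x, a = 0.9, sigma2 = 0.1, flat trajectories.
# Cheap and overdispersion is handled by burn-in.
init_state <- function(data, config) {
  p <- ncol(data[[1]]$covariates)
  subjects <- lapply(data, function(s) {
    w <- tryCatch({
      fit <- suppressWarnings(
        glm(s$responses ~ s$covariates, family = binomial()))
      co <- coef(fit)[-1]
      co[!is.finite(co)] <- 0
      pmin(pmax(unname(co), -5), 5)
    }, error = function(e) numeric(p))
    if (length(w) != p) w <- numeric(p)
    mux <- min(max(qlogis(mean(c(s$responses, 0.5))), -2), 2)
    a <- if (is.null(config$fixed_a)) 0.9 else config$fixed_a
    list(w = w, a = a, sigma2 = 0.1, mu_x = mux,
         x = rep(mux, s$n_trials))
  })
  w_mat <- do.call(rbind, lapply(subjects, `[[`, "w"))
  mux <- vapply(subjects, `[[`, numeric(1), "mu_x")
  v_w <- apply(w_mat, 2, var)
  v_w[!is.finite(v_w)] <- 0.5
  v_m <- var(mux)
  if (!is.finite(v_m)) v_m <- 0.5
  eta <- hyper_params(
    mu_w = colMeans(w_mat),
    sigma2_w = pmax(v_w, 0.1),
    mu_a = 0.9, sigma2_a = 0.01, mu_sigma2 = 0.2, beta_sigma2 = 0.5,
    sigma2_mux = max(v_m, 0.1)
  )
  list(subjects = subjects, eta = eta)
}

#' One blocked Gibbs sweep
#'
#' Runs one full sweep over a sampler state: per subject, draw the
#' Polya-gamma auxiliaries, the latent trajectory (FFBS), then the
#' conditionals of `w`, `a`, `sigma2`, and `mu_x`; finally the group-level
#' closed-form and Metropolis updates. Exposed as a building block so that
#' joint-distribution (Geweke-style) correctness checks can drive the exact
#' transition kernel used by [fit_hmfc()].
#'
#' @param state list with elements `subjects` (each a list `w`, `a`,
#'   `sigma2`, `mu_x`, `x`) and `eta` (a [hyper_params]).
#' @param data list of [subject_data] objects.
#' @param config a [sampler_config()].
#' @param mh_steps proposal SDs to use this sweep (defaults to the config's).
#' @return the updated state, with an `accept` attribute-like element
#'   recording the Metropolis acceptances.
#' @export
gibbs_sweep <- function(state, data, config = sampler_config(),
                        mh_steps = config$mh_steps) {
  eta <- state$eta
  est_fluct <- config$estimate_fluctuations
  for (i in seq_along(data)) {
    s <- data[[i]]
    st <- state$subjects[[i]]
    res <- tryCatch({
      psi_u <- drop(s$covariates %*% st$w)
      omega <- rpg(s$n_trials, psi_u + st$x)
      if (est_fluct) {
        pars <- subject_params(st$w, st$a, st$sigma2, st$mu_x)
        flt <- forward_filter(s$responses, omega, psi_u, pars,
                              init = config$init, x1 = st$mu_x)
        st$x <- backward_sample(flt, pars)
      }
      st$w <- update_weights(s$responses, s$covariates, st$x, omega,
                             eta$mu_w, eta$sigma2_w)
      if (est_fluct) {
        if (is.null(config$fixed_a)) {
          st$a <- update_a(st$x, st$a, st$sigma2, st$mu_x,
                           eta$mu_a, eta$sigma2_a, init = config$init)
        }
        st$sigma2 <- update_sigma2(st$x, st$a, st$mu_x,
                                   eta$alpha_sigma2, eta$beta_sigma2,
                                   init = config$init)
        st$mu_x <- update_mux(st$x, st$a, st$sigma2, eta$sigma2_mux,
                              init = config$init)
      } else {
        psi_u <- drop(s$covariates %*% st$w)
        st$mu_x <- update_mux_static(s$responses, omega, psi_u,
                                     eta$sigma2_mux)
        st$x <- rep(st$mu_x, s$n_trials)
      }
      st
    }, error = function(e) {
      stop("Gibbs update failed for subject ", s$subject_id, ": ",
           conditionMessage(e), call. = FALSE)
    })
    state$subjects[[i]] <- res
  }

  accept <- c(mu_a = NA, sigma2_a = NA, mu_sigma2 = NA, beta_sigma2 = NA)
  if (config$update_globals) {
    w_mat <- do.call(rbind, lapply(state$subjects, `[[`, "w"))
    mux <- vapply(state$subjects, `[[`, numeric(1), "mu_x")
    eta <- update_global_normals(w_mat, mux, eta, config$hyperpriors)
    if (est_fluct) {
      a_vec <- vapply(state$subjects, `[[`, numeric(1), "a")
      s2_vec <- vapply(state$subjects, `[[`, numeric(1), "sigma2")
      mh <- update_global_mh(a_vec, s2_vec, eta, config$hyperpriors,
                             steps = mh_steps)
      if (!is.null(config$fixed_a)) {
        # a_i clamped: keep mu_a / sigma2_a untouched
        eta <- hyper_params(mh$eta$mu_w, mh$eta$sigma2_w,
                            eta$mu_a, eta$sigma2_a,
                            mh$eta$mu_sigma2, mh$eta$beta_sigma2,
                            mh$eta$sigma2_mux)
        mh$accept[c("mu_a", "sigma2_a")] <- NA
      } else {
        eta <- mh$eta
      }
      accept <- mh$accept
    }
    state$eta <- eta
  }
  state$accept <- accept
  state
}

#' Fit the hierarchical criterion-fluctuation model
#'
#' Runs the augmented, blocked Gibbs sampler over a multi-subject dataset
#' and records the full posterior chain: per-subject weights, AR(1)
#' parameters, trajectory means, group-level parameters, and (optionally)
#' latent criterion trajectories.
#'
#' @param data list of [subject_data] objects (or an `hmfc_sim`, whose
#'   `$data` is used).
#' @param config a [sampler_config()].
#' @param seed integer seed; every source of randomness in the fit flows
#'   from it, so runs are exactly reproducible.
#' @return an object of class `hmfc_fit`.
#' @export
fit_hmfc <- function(data, config = sampler_config(), seed = NULL) {
  if (inherits(data, "hmfc_sim")) data <- data$data
  validate_dataset(data)
  if (!is.null(seed)) set.seed(seed)
  n <- length(data)
  p <- ncol(data[[1]]$covariates)
  iters <- config$iterations

  state <- init_state(data, config)
  mh_steps <- config$mh_steps
  acc_batch <- c(mu_a = 0, sigma2_a = 0, mu_sigma2 = 0, beta_sigma2 = 0)
  batch_n <- 0

  w_draws <- array(NA_real_, c(iters, n, p))
  a_draws <- matrix(NA_real_, iters, n)
  s2_draws <- matrix(NA_real_, iters, n)
  mux_draws <- matrix(NA_real_, iters, n)
  eta_names <- c(paste0("mu_w_", seq_len(p)), paste0("sigma2_w_", seq_len(p)),
                 "mu_a", "sigma2_a", "mu_sigma2", "beta_sigma2",
                 "sigma2_mux")
  eta_draws <- matrix(NA_real_, iters, length(eta_names),
                      dimnames = list(NULL, eta_names))
  accept_log <- matrix(NA, iters, 4,
                       dimnames = list(NULL, names(acc_batch)))

  n_post <- iters - config$burn_in
  traj_sum <- lapply(data, function(s) numeric(s$n_trials))
  traj_keep_every <- max(1L, ceiling(n_post / config$traj_max_draws))
  traj_draws <- if (config$save_trajectories) {
    lapply(data, function(s)
      matrix(NA_real_, ceiling(n_post / traj_keep_every), s$n_trials))
  }
  kept <- 0

  for (it in seq_len(iters)) {
    state <- tryCatch(
      gibbs_sweep(state, data, config, mh_steps = mh_steps),
      error = function(e) {
        stop("iteration ", it, ": ", conditionMessage(e), call. = FALSE)
      })

    if (config$adapt && it <= config$burn_in &&
        config$update_globals && config$estimate_fluctuations) {
      ok <- !is.na(state$accept)
      acc_batch[ok] <- acc_batch[ok] + state$accept[ok]
      batch_n <- batch_n + 1
      if (batch_n == 25) {
        rate <- acc_batch / 25
        mh_steps <- mh_steps * exp(rate - config$adapt_target)
        acc_batch[] <- 0
        batch_n <- 0
      }
    }

    for (i in seq_len(n)) {
      st <- state$subjects[[i]]
      w_draws[it, i, ] <- st$w
      a_draws[it, i] <- st$a
      s2_draws[it, i] <- st$sigma2
      mux_draws[it, i] <- st$mu_x
    }
    e <- state$eta
    eta_draws[it, ] <- c(e$mu_w, e$sigma2_w, e$mu_a, e$sigma2_a,
                         e$mu_sigma2, e$beta_sigma2, e$sigma2_mux)
    accept_log[it, ] <- state$accept

    if (it > config$burn_in) {
      j <- it - config$burn_in
      for (i in seq_len(n)) {
        traj_sum[[i]] <- traj_sum[[i]] + state$subjects[[i]]$x
      }
      if (config$save_trajectories && (j - 1) %% traj_keep_every == 0) {
        kept <- kept + 1
        for (i in seq_len(n)) {
          traj_draws[[i]][kept, ] <- state$subjects[[i]]$x
        }
      }
    }
    if (config$verbose && it %% 100 == 0) {
      message("iteration ", it, "/", iters)
    }
  }
  if (config$save_trajectories) {
    traj_draws <- lapply(traj_draws, function(m) m[seq_len(kept), , drop = FALSE])
  }

  structure(
    list(w = w_draws, a = a_draws, sigma2 = s2_draws, mu_x = mux_draws,
         eta = eta_draws, accept = accept_log,
         trajectory_mean = lapply(traj_sum, function(v) v / n_post),
         trajectory_draws = traj_draws,
         subject_ids = vapply(data, function(s) as.character(s$subject_id),
                              character(1)),
         n_trials = vapply(data, `[[`, integer(1), "n_trials"),
         config = config, mh_steps_final = mh_steps, seed = seed),
    class = "hmfc_fit"
  )
}

#' @export
print.hmfc_fit <- function(x, ...) {
  n <- ncol(x$a)
  cat("Hierarchical criterion-fluctuation fit\n")
  cat("  subjects:   ", n, "\n")
  cat("  iterations: ", nrow(x$eta), " (burn-in ", x$config$burn_in, ")\n",
      sep = "")
  post <- posterior_means(x)
  cat("  posterior mean group-level parameters:\n")
  print(signif(post$eta, 3))
  acc <- colMeans(x$accept[-seq_len(x$config$burn_in), , drop = FALSE])
  if (!all(is.na(acc))) {
    cat("  MH acceptance (post burn-in):",
        paste(names(acc), signif(acc, 2), collapse = ", "), "\n")
  }
  invisible(x)
}

# post-burn-in, thinned iteration indices
post_idx <- function(fit) {
  idx <- seq(fit$config$burn_in + 1, nrow(fit$eta))
  idx[seq(1, length(idx), by = fit$config$thin)]
}

#' Posterior means of all parameters
#'
#' Point estimates are posterior means over post-burn-in (thinned) samples.
#'
#' @param fit an `hmfc_fit`.
#' @return list with `w` (`N x p` matrix), vectors `a`, `sigma2`, `mu_x`,
#'   and the named group-level vector `eta`.
#' @export
posterior_means <- function(fit) {
  stopifnot(inherits(fit, "hmfc_fit"))
  idx <- post_idx(fit)
  list(w = apply(fit$w[idx, , , drop = FALSE], c(2, 3), mean),
       a = colMeans(fit$a[idx, , drop = FALSE]),
       sigma2 = colMeans(fit$sigma2[idx, , drop = FALSE]),
       mu_x = colMeans(fit$mu_x[idx, , drop = FALSE]),
       eta = colMeans(fit$eta[idx, , drop = FALSE]))
}

#' Per-trial posterior summary of the criterion trajectories
#'
#' @param fit an `hmfc_fit` run with `save_trajectories = TRUE`.
#' @param level credible level for the equal-tailed band.
#' @return a data.frame with columns `subject`, `trial`, `mean`, `lower`,
#'   `upper`.
#' @export
trajectory_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "hmfc_fit"))
  if (is.null(fit$trajectory_draws)) {
    stop("fit was run with save_trajectories = FALSE", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  out <- lapply(seq_along(fit$trajectory_mean), function(i) {
    qs <- apply(fit$trajectory_draws[[i]], 2, quantile,
                probs = c(alpha, 1 - alpha))
    data.frame(subject = fit$subject_ids[i],
               trial = seq_len(fit$n_trials[i]),
               mean = fit$trajectory_mean[[i]],
               lower = qs[1, ], upper = qs[2, ])
  })
  do.call(rbind, out)
}
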