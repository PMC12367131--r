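#' Pearson recovery correlation
#'
#' Correlation between true (generative) values and their estimates, the
#' standard recovery metric for simulation-based validation.
#'
#' @param truth,estimate equal-length numeric vectors (length >= 3).
#' @return the Pearson correlation.
#' @export
recovery_correlation <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate), length(truth) >= 3)
  if (sd(truth) == 0 || sd(estimate) == 0) {
    stop("correlation undefined: zero variance input", call. = FALSE)
  }
  cor(truth, estimate)
}

#' Root-mean-square error between trajectories
#'
#' @param truth,estimate equal-length numeric vectors.
#' @return non-negative RMSE.
#' @export
trajectory_rmse <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("trajectory length mismatch", call. = FALSE)
  }
  sqrt(mean((truth - estimate)^2))
}

#' Equal-tailed credible interval
#'
#' @param samples numeric vector of posterior draws (>= 100).
#' @param level credible level in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(samples, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (length(samples) < 100) {
    stop("need at least 100 samples for a stable interval", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  q <- quantile(samples, c(alpha, 1 - alpha), names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Count datasets whose credible interval covers the truth
#'
#' For each group-level parameter, counts in how many replicate fits the
#' generative value lies inside the equal-tailed credible interval.
#'
#' @param fits list of `hmfc_fit` objects over replicate datasets.
#' @param truth named vector of generative group-level values (names
#'   matching the fit's `eta` columns).
#' @param level credible level.
#' @return named integer vector of coverage counts (max = `length(fits)`).
#' @export
coverage_count <- function(fits, truth, level = 0.95) {
  stopifnot(length(fits) >= 1)
  pars <- names(truth)
  counts <- stats::setNames(integer(length(pars)), pars)
  for (fit in fits) {
    idx <- post_idx(fit)
    for (par in pars) {
      ci <- credible_interval(fit$eta[idx, par], level)
      if (truth[[par]] >= ci["lower"] && truth[[par]] <= ci["upper"]) {
        counts[par] <- counts[par] + 1L
      }
    }
  }
  counts
}

#' Sample autocorrelation of a chain
#'
#' @param samples numeric chain (length > `max_lag`).
#' @param max_lag largest lag.
#' @return autocorrelations at lags `1..max_lag`.
#' @export
chain_autocorrelation <- function(samples, max_lag = 20) {
  stopifnot(length(samples) > max_lag)
  if (sd(samples) == 0) {
    stop("autocorrelation undefined: constant chain", call. = FALSE)
  }
  drop(acf(samples, lag.max = max_lag, plot = FALSE)$acf)[-1]
}

#' Recovery report for a fitted simulation
#'
#' Compares a fit against the ground truth of the simulated dataset it was
#' run on: Pearson recovery correlations for each per-subject parameter,
#' per-subject trajectory correlations and RMSEs, and credible-interval
#' coverage indicators for the group-level parameters.
#'
#' @param fit an `hmfc_fit`.
#' @param sim the `hmfc_sim` the fit was run on.
#' @param level credible level for the coverage indicators.
#' @return list of class `recovery_report` with elements
#'   `parameter_correlations`, `trajectory` (per-subject data.frame),
#'   `trajectory_correlation_mean`, `trajectory_rmse_mean`, and
#'   `global_coverage` (named logical).
#' @export
recovery_report <- function(fit, sim, level = 0.95) {
  stopifnot(inherits(fit, "hmfc_fit"), inherits(sim, "hmfc_sim"))
  post <- posterior_means(fit)
  true_w <- do.call(rbind, lapply(sim$params, `[[`, "w"))
  p <- ncol(true_w)
  par_cor <- c(
    stats::setNames(
      vapply(seq_len(p),
             function(j) recovery_correlation(true_w[, j], post$w[, j]),
             numeric(1)),
      paste0("w_", seq_len(p))),
    a = recovery_correlation(vapply(sim$params, `[[`, numeric(1), "a"),
                             post$a),
    sigma2 = recovery_correlation(
      vapply(sim$params, `[[`, numeric(1), "sigma2"), post$sigma2),
    mu_x = recovery_correlation(
      vapply(sim$params, `[[`, numeric(1), "mu_x"), post$mu_x)
  )
  traj <- data.frame(
    subject = fit$subject_ids,
    correlation = vapply(seq_along(sim$trajectories), function(i) {
      cor(sim$trajectories[[i]], fit$trajectory_mean[[i]])
    }, numeric(1)),
    rmse = vapply(seq_along(sim$trajectories), function(i) {
      trajectory_rmse(sim$trajectories[[i]], fit$trajectory_mean[[i]])
    }, numeric(1))
  )
  # for the weight hyperparameters, "truth" is the within-dataset mean and
  # variance of the realized per-subject weights: the posterior concentrates
  # on the population actually drawn, which at finite N can sit away from
  # the generative values
  truth_eta <- c(stats::setNames(colMeans(true_w), paste0("mu_w_", seq_len(p))),
                 stats::setNames(apply(true_w, 2, var),
                                 paste0("sigma2_w_", seq_len(p))),
                 mu_a = sim$eta$mu_a, sigma2_a = sim$eta$sigma2_a,
                 mu_sigma2 = sim$eta$mu_sigma2,
                 beta_sigma2 = sim$eta$beta_sigma2,
                 sigma2_mux = sim$eta$sigma2_mux)
  cover <- coverage_count(list(fit), truth_eta, level) == 1L
  structure(
    list(parameter_correlations = par_cor, trajectory = traj,
         trajectory_correlation_mean = mean(traj$correlation),
         trajectory_rmse_mean = mean(traj$rmse),
         global_coverage = cover),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery report\n")
  cat("  parameter recovery correlations:\n")
  print(signif(x$parameter_correlations, 3))
  cat("  trajectory: mean correlation",
      signif(x$trajectory_correlation_mean, 3), ", mean RMSE",
      signif(x$trajectory_rmse_mean, 3), "\n")
  cat("  group-level 95% CI covers truth:",
      sum(x$global_coverage), "/", length(x$global_coverage),
      "parameters\n")
  invisible(x)
}

#' Recovery scatterplot
#'
#' True versus posterior-mean estimates for one per-subject parameter, with
#' the identity line.
#'
#' @param truth,estimate numeric vectors.
#' @param label axis label.
#' @return a ggplot object.
#' @export
plot_recovery <- function(truth, estimate, label = "parameter") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  df <- data.frame(truth = truth, estimate = estimate)
  ggplot2::ggplot(df, ggplot2::aes(x = truth, y = estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = paste("true", label),
                  y = paste("estimated", label)) +
    ggplot2::theme_minimal()
}

#' Trajectory overlay plot
#'
#' Posterior mean and credible band of one subject's latent criterion,
#' optionally overlaid with the ground-truth trajectory.
#'
#' @param fit an `hmfc_fit`.
#' @param subject index of the subject to plot.
#' @param truth optional true trajectory.
#' @param level credible level of the band.
#' @return a ggplot object.
#' @export
plot_trajectory <- function(fit, subject = 1, truth = NULL, level = 0.95) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  ts <- trajectory_summary(fit, level)
  ts <- ts[ts$subject == fit$subject_ids[subject], ]
  g <- ggplot2::ggplot(ts, ggplot2::aes(x = trial)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = mean), colour = "steelblue") +
    ggplot2::labs(x = "trial", y = "criterion") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    g <- g + ggplot2::geom_line(
      data = data.frame(trial = seq_along(truth), truth = truth),
      ggplot2::aes(y = truth), colour = "black", linewidth = 0.3)
  }
  g
}
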