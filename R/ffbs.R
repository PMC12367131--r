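#' Forward filtering for the augmented criterion chain
#'
#' After Polya-gamma augmentation, the latent criterion chain is a scalar
#' linear-Gaussian state-space model with pseudo-observations
#' \eqn{z_t = \kappa_t / \omega_t - w^\top u_t} and noise variance
#' \eqn{1 / \omega_t}. `forward_filter()` returns the filtering means and
#' variances of \eqn{p(x_t | y_{1:t})}; the update is computed in a form
#' that stays finite as \eqn{\omega_t \to 0} (an uninformative trial, where
#' the filter falls back to the AR(1) prior marginal). Filtering variances
#' are floored at 1e-12.
#'
#' @param responses binary vector (0/1).
#' @param omega positive PG auxiliary draws, one per trial.
#' @param psi_u per-trial covariate contribution \eqn{w^\top u_t}.
#' @param params a [subject_params] object.
#' @param init initial-state convention shared with [simulate_ar1()];
#'   `"innovation"` uses \eqn{N(\mu_x, \sigma^2)}, `"stationary"`
#'   \eqn{N(\mu_x, \sigma^2 / (1 - a^2))}, `"fixed"` a point mass at `x1`.
#' @param x1 first-state value when `init = "fixed"`.
#' @return list with `means` and `variances`, each of length `T`.
#' @export
forward_filter <- function(responses, omega, psi_u, params,
                           init = c("innovation", "stationary", "fixed"),
                           x1 = 0) {
  init <- match.arg(init)
  T_i <- length(responses)
  stopifnot(length(omega) == T_i, length(psi_u) == T_i, T_i >= 1)
  if (any(omega < 0)) stop("all `omega` must be >= 0", call. = FALSE)
  a <- params$a
  s2 <- params$sigma2
  if (init == "innovation") {
    m0 <- params$mu_x
    P0 <- s2
  } else if (init == "stationary") {
    if (a >= 1) stop("stationary init requires a < 1", call. = FALSE)
    m0 <- params$mu_x
    P0 <- s2 / (1 - a^2)
  } else {
    m0 <- x1
    P0 <- 0
  }
  kappa <- responses - 0.5
  .forward_filter_cpp(kappa, omega, psi_u, a, params$b, s2, m0, P0)
}

#' Backward sampling of the criterion trajectory
#'
#' Draws the full trajectory \eqn{x_{1:T}} from its joint conditional given
#' the PG auxiliaries, weights, AR(1) parameters, and responses: the last
#' state from the final filtering distribution, then each earlier state from
#' the exact Gaussian backward kernel.
#'
#' @param filter output of [forward_filter()] run with the same `params`.
#' @param params a [subject_params] object.
#' @return numeric trajectory of length `T`.
#' @export
backward_sample <- function(filter, params) {
  m <- filter$means
  P <- filter$variances
  if (length(m) != length(P)) {
    stop("filter means/variances length mismatch", call. = FALSE)
  }
  .backward_sample_cpp(m, P, params$a, params$b, params$sigma2)
}

#' One FFBS draw of the latent criterion trajectory
#'
#' Convenience wrapper: [forward_filter()] followed by [backward_sample()].
#'
#' @inheritParams forward_filter
#' @return numeric trajectory of length `T`.
#' @export
ffbs <- function(responses, omega, psi_u, params,
                 init = c("innovation", "stationary", "fixed"), x1 = 0) {
  f <- forward_filter(responses, omega, psi_u, params, init = init, x1 = x1)
  backward_sample(f, params)
}
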