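#' Hyperprior constants for the group-level parameters
#'
#' Broad proper priors on the group-level parameters: normal on the weight
#' means `mu_w` and the truncated-normal location `mu_a`, inverse-gamma on
#' every variance-role parameter (`sigma2_w`, `sigma2_a`, `mu_sigma2`,
#' `beta_sigma2`, `sigma2_mux`). Proper priors keep every conditional
#' well-defined even with a single subject; all constants are exposed so a
#' different weakly informative choice can be dropped in verbatim.
#'
#' The prior on `mu_a` is itself truncated to \[0, 1\]: the location of the
#' persistence prior is only weakly identified when the `a_i` pile up near
#' 1 (the truncated-normal likelihood has a ridge trading location against
#' scale), and keeping it inside the support keeps it interpretable as a
#' persistence level.
#'
#' @param m0_w,v0_w normal mean/variance of the prior on each `mu_w` entry.
#' @param a0_w,b0_w inverse-gamma shape/scale of the prior on `sigma2_w`.
#' @param m0_a,v0_a location/scale^2 of the \[0, 1\]-truncated normal prior
#'   on `mu_a`.
#' @param a0_sa,b0_sa inverse-gamma prior on `sigma2_a`.
#' @param a0_ms,b0_ms inverse-gamma prior on `mu_sigma2`.
#' @param a0_bs,b0_bs inverse-gamma prior on `beta_sigma2`.
#' @param a0_mux,b0_mux inverse-gamma prior on `sigma2_mux`.
#' @return a named list of constants.
#' @export
hyperprior_config <- function(m0_w = 0, v0_w = 25,
                              a0_w = 2, b0_w = 1,
                              m0_a = 0.5, v0_a = 1,
                              a0_sa = 1, b0_sa = 0.01,
                              a0_ms = 2, b0_ms = 0.5,
                              a0_bs = 2, b0_bs = 0.5,
                              a0_mux = 2, b0_mux = 0.5) {
  hp <- list(m0_w = m0_w, v0_w = v0_w, a0_w = a0_w, b0_w = b0_w,
             m0_a = m0_a, v0_a = v0_a, a0_sa = a0_sa, b0_sa = b0_sa,
             a0_ms = a0_ms, b0_ms = b0_ms, a0_bs = a0_bs, b0_bs = b0_bs,
             a0_mux = a0_mux, b0_mux = b0_mux)
  stopifnot(all(vapply(hp, is.numeric, logical(1))))
  if (v0_w <= 0 || v0_a <= 0 ||
      any(unlist(hp[grep("^[ab]0_(w|sa|ms|bs|mux)$", names(hp))]) <= 0)) {
    stop("hyperprior scale constants must be strictly positive",
         call. = FALSE)
  }
  hp
}

#' Draw group-level parameters from their hyperprior
#'
#' Used for initialization checks and joint-distribution (Geweke-style)
#' validation of the sampler.
#'
#' @param p number of covariates.
#' @param hp constants from [hyperprior_config()].
#' @return a [hyper_params] draw.
#' @export
draw_hyper_prior <- function(p, hp = hyperprior_config()) {
  hyper_params(
    mu_w = rnorm(p, hp$m0_w, sqrt(hp$v0_w)),
    sigma2_w = rinvgamma(p, hp$a0_w, hp$b0_w),
    mu_a = rtnorm(1, hp$m0_a, sqrt(hp$v0_a), 0, 1),
    sigma2_a = rinvgamma(1, hp$a0_sa, hp$b0_sa),
    mu_sigma2 = rinvgamma(1, hp$a0_ms, hp$b0_ms),
    beta_sigma2 = rinvgamma(1, hp$a0_bs, hp$b0_bs),
    sigma2_mux = rinvgamma(1, hp$a0_mux, hp$b0_mux)
  )
}

#' Conjugate draw of the covariate weights
#'
#' Exact multivariate-normal draw from the PG-augmented conditional of `w`:
#' precision = prior precision + \eqn{\sum_t \omega_t u_t u_t^\top}, with
#' pseudo-observations \eqn{\kappa_t = y_t - 1/2} offset by the latent
#' criterion \eqn{x_t}. With zero trials the draw follows the prior.
#'
#' @param responses binary vector (0/1), length `T`.
#' @param covariates `T x p` covariate matrix.
#' @param x latent criterion trajectory, length `T`.
#' @param omega PG auxiliaries, length `T`.
#' @param mu_w,sigma2_w prior mean and variances of the weights.
#' @return a length-`p` weight draw.
#' @export
update_weights <- function(responses, covariates, x, omega, mu_w, sigma2_w) {
  U <- as.matrix(covariates)
  p <- ncol(U)
  stopifnot(length(mu_w) == p, length(sigma2_w) == p,
            nrow(U) == length(responses), length(x) == length(responses),
            length(omega) == length(responses))
  if (any(sigma2_w <= 0)) stop("`sigma2_w` must be positive", call. = FALSE)
  kappa <- responses - 0.5
  prec <- diag(1 / sigma2_w, p) + crossprod(U * omega, U)
  rhs <- mu_w / sigma2_w + drop(crossprod(U, kappa - omega * x))
  R <- tryCatch(chol(prec), error = function(e) {
    stop("singular conditional precision for `w`; check `sigma2_w`",
         call. = FALSE)
  })
  mean <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
  drop(mean + backsolve(R, rnorm(p)))
}

#' Draw the AR(1) persistence parameter
#'
#' Combines the truncated-normal prior `TruncNorm(mu_a, sigma2_a, [0, 1])`
#' with the AR(1) regression likelihood of the mean-centered states. Under
#' `init = "innovation"` or `init = "fixed"` the first state's law does not
#' depend on `a`, so the truncated-normal conditional is exact and drawn
#' directly. Under `init = "stationary"` the first state's law carries a
#' \eqn{\sqrt{1 - a^2}\exp(-(1-a^2)(x_1-\mu_x)^2/2\sigma^2)} factor; the
#' truncated-normal draw then serves as an independence-Metropolis proposal
#' accepted against that factor, so the draw still targets the exact
#' conditional (acceptance is near 1 for realistic `T`).
#'
#' @param x latent trajectory (length >= 2).
#' @param a_current current value of `a` (used by the Metropolis step).
#' @param sigma2,mu_x current innovation variance and trajectory mean.
#' @param mu_a,sigma2_a group-level prior location and scale^2.
#' @param init initial-state convention (see [forward_filter()]).
#' @return the new value of `a`.
#' @export
update_a <- function(x, a_current, sigma2, mu_x, mu_a, sigma2_a,
                     init = c("innovation", "stationary", "fixed")) {
  init <- match.arg(init)
  T_i <- length(x)
  stopifnot(T_i >= 2, sigma2 > 0, sigma2_a > 0)
  xc <- x - mu_x
  sxx <- sum(xc[-T_i]^2)
  sxy <- sum(xc[-1] * xc[-T_i])
  prec <- 1 / sigma2_a + sxx / sigma2
  if (!is.finite(prec) || prec <= 0) {
    stop("degenerate conditional variance for `a`", call. = FALSE)
  }
  v <- 1 / prec
  m <- v * (mu_a / sigma2_a + sxy / sigma2)
  # numerical guard: a = 1 exactly would make the stationary variance
  # undefined downstream
  prop <- min(rtnorm(1, m, sqrt(v), 0, 1), 1 - 1e-9)
  if (init != "stationary") return(prop)
  log_init <- function(a) {
    0.5 * log1p(-a^2) - (1 - a^2) * xc[1]^2 / (2 * sigma2)
  }
  if (accept_mh(log_init(prop), log_init(a_current))) prop else a_current
}

# Metropolis accept step robust to -Inf / NaN log densities
accept_mh <- function(lp_prop, lp_cur) {
  u <- runif(1)  # always consume one uniform for reproducible call order
  if (!is.finite(lp_prop)) return(FALSE)
  if (!is.finite(lp_cur)) return(TRUE)
  log(u) < lp_prop - lp_cur
}

#' Conjugate draw of the innovation variance
#'
#' Exact inverse-gamma draw. Under `init = "fixed"` the shape is
#' \eqn{\alpha_{\sigma^2} + (T-1)/2} and the scale
#' \eqn{\beta_{\sigma^2} + \frac12\sum_t (x_t - b - a x_{t-1})^2}. The
#' first state's law contributes a further 1/2 to the shape and
#' \eqn{(x_1-\mu_x)^2/2} (innovation init) or
#' \eqn{(1-a^2)(x_1-\mu_x)^2/2} (stationary init) to the scale, keeping
#' the conditional exactly inverse-gamma.
#'
#' @inheritParams update_a
#' @param a current persistence.
#' @param alpha_sigma2,beta_sigma2 prior shape and scale.
#' @return the new value of `sigma2`.
#' @export
update_sigma2 <- function(x, a, mu_x, alpha_sigma2, beta_sigma2,
                          init = c("innovation", "stationary", "fixed")) {
  init <- match.arg(init)
  T_i <- length(x)
  stopifnot(T_i >= 2, alpha_sigma2 > 0, beta_sigma2 > 0)
  xc <- x - mu_x
  resid <- xc[-1] - a * xc[-T_i]
  shape <- alpha_sigma2 + (T_i - 1) / 2
  scale <- beta_sigma2 + 0.5 * sum(resid^2)
  if (init == "innovation") {
    shape <- shape + 0.5
    scale <- scale + 0.5 * xc[1]^2
  } else if (init == "stationary") {
    shape <- shape + 0.5
    scale <- scale + 0.5 * (1 - a^2) * xc[1]^2
  }
  rinvgamma(1, shape, scale)
}

#' Conjugate draw of the trajectory mean
#'
#' Exact Gaussian draw. The mean enters every transition through
#' \eqn{b = \mu_x (1 - a)} and (unless the first state is fixed) the first
#' state's marginal law; the prior is the zero-mean hierarchical normal
#' `N(0, sigma2_mux)`.
#'
#' @inheritParams update_sigma2
#' @param sigma2 current innovation variance.
#' @param sigma2_mux group-level prior variance of the trajectory means.
#' @return the new value of `mu_x`.
#' @export
update_mux <- function(x, a, sigma2, sigma2_mux,
                       init = c("innovation", "stationary", "fixed")) {
  init <- match.arg(init)
  T_i <- length(x)
  stopifnot(T_i >= 1, sigma2 > 0, sigma2_mux > 0)
  prec <- 1 / sigma2_mux
  lin <- 0
  if (T_i >= 2) {
    d <- x[-1] - a * x[-T_i]
    prec <- prec + (T_i - 1) * (1 - a)^2 / sigma2
    lin <- lin + (1 - a) * sum(d) / sigma2
  }
  if (init == "innovation") {
    prec <- prec + 1 / sigma2
    lin <- lin + x[1] / sigma2
  } else if (init == "stationary") {
    prec <- prec + (1 - a^2) / sigma2
    lin <- lin + x[1] * (1 - a^2) / sigma2
  }
  rnorm(1, lin / prec, sqrt(1 / prec))
}

# Gaussian draw of the trajectory mean when no fluctuations are estimated:
# the model reduces to logistic regression with a random intercept, and the
# PG-augmented conditional of the intercept is normal.
update_mux_static <- function(responses, omega, psi_u, sigma2_mux) {
  stopifnot(sigma2_mux > 0)
  kappa <- responses - 0.5
  prec <- 1 / sigma2_mux + sum(omega)
  lin <- sum(kappa - omega * psi_u)
  rnorm(1, lin / prec, sqrt(1 / prec))
}

#' Closed-form updates of the normal group-level parameters
#'
#' Conjugate draws of `mu_w` (normal), `sigma2_w` (inverse-gamma) and
#' `sigma2_mux` (inverse-gamma) given the current per-subject weights and
#' trajectory means.
#'
#' @param w_mat `N x p` matrix of current per-subject weights.
#' @param mux_vec length-`N` vector of current trajectory means.
#' @param eta current [hyper_params].
#' @param hp constants from [hyperprior_config()].
#' @return an updated [hyper_params] object.
#' @export
update_global_normals <- function(w_mat, mux_vec, eta, hp) {
  w_mat <- as.matrix(w_mat)
  n <- nrow(w_mat)
  p <- ncol(w_mat)
  stopifnot(n >= 1, length(mux_vec) == n, length(eta$mu_w) == p)
  mu_w <- numeric(p)
  sigma2_w <- numeric(p)
  for (j in seq_len(p)) {
    prec <- 1 / hp$v0_w + n / eta$sigma2_w[j]
    m <- (hp$m0_w / hp$v0_w + sum(w_mat[, j]) / eta$sigma2_w[j]) / prec
    mu_w[j] <- rnorm(1, m, sqrt(1 / prec))
    sigma2_w[j] <- rinvgamma(1, hp$a0_w + n / 2,
                             hp$b0_w + 0.5 * sum((w_mat[, j] - mu_w[j])^2))
  }
  sigma2_mux <- rinvgamma(1, hp$a0_mux + n / 2,
                          hp$b0_mux + 0.5 * sum(mux_vec^2))
  hyper_params(mu_w, sigma2_w, eta$mu_a, eta$sigma2_a, eta$mu_sigma2,
               eta$beta_sigma2, sigma2_mux)
}

#' Random-walk Metropolis updates of the non-conjugate group parameters
#'
#' One symmetric-Gaussian random-walk step for each of `mu_a`, `sigma2_a`,
#' `mu_sigma2` and `beta_sigma2`, targeting the product of the per-subject
#' prior densities (truncated-normal for the `a_i`; inverse-gamma with the
#' derived shape \eqn{\alpha_{\sigma^2} = \beta_{\sigma^2}/\mu_{\sigma^2} +
#' 1} for the `sigma2_i`) times the weakly informative hyperprior.
#' Proposals violating positivity are rejected outright.
#'
#' @param a_vec,s2_vec current per-subject `a_i` and `sigma2_i`.
#' @param eta current [hyper_params].
#' @param hp constants from [hyperprior_config()].
#' @param steps named proposal standard deviations for
#'   `mu_a`, `sigma2_a`, `mu_sigma2`, `beta_sigma2`.
#' @return list with the updated `eta` and a named logical `accept`.
#' @export
update_global_mh <- function(a_vec, s2_vec, eta, hp,
                             steps = c(mu_a = 0.01, sigma2_a = 0.005,
                                       mu_sigma2 = 0.05, beta_sigma2 = 0.1)) {
  stopifnot(all(steps > 0))
  accept <- c(mu_a = FALSE, sigma2_a = FALSE,
              mu_sigma2 = FALSE, beta_sigma2 = FALSE)

  lp_a <- function(mu_a, sigma2_a) {
    if (sigma2_a <= 0 || mu_a < 0 || mu_a > 1) return(-Inf)
    sum(dtnorm(a_vec, mu_a, sqrt(sigma2_a), 0, 1, log = TRUE)) +
      dtnorm(mu_a, hp$m0_a, sqrt(hp$v0_a), 0, 1, log = TRUE) +
      dinvgamma(sigma2_a, hp$a0_sa, hp$b0_sa, log = TRUE)
  }
  lp_s <- function(mu_sigma2, beta_sigma2) {
    if (mu_sigma2 <= 0 || beta_sigma2 <= 0) return(-Inf)
    alpha <- derive_alpha(beta_sigma2, mu_sigma2)
    sum(dinvgamma(s2_vec, alpha, beta_sigma2, log = TRUE)) +
      dinvgamma(mu_sigma2, hp$a0_ms, hp$b0_ms, log = TRUE) +
      dinvgamma(beta_sigma2, hp$a0_bs, hp$b0_bs, log = TRUE)
  }

  mu_a <- eta$mu_a
  sigma2_a <- eta$sigma2_a
  prop <- mu_a + rnorm(1, 0, steps[["mu_a"]])
  if (accept_mh(lp_a(prop, sigma2_a), lp_a(mu_a, sigma2_a))) {
    mu_a <- prop
    accept[["mu_a"]] <- TRUE
  }
  prop <- sigma2_a + rnorm(1, 0, steps[["sigma2_a"]])
  if (accept_mh(lp_a(mu_a, prop), lp_a(mu_a, sigma2_a))) {
    sigma2_a <- prop
    accept[["sigma2_a"]] <- TRUE
  }

  mu_s <- eta$mu_sigma2
  beta_s <- eta$beta_sigma2
  prop <- mu_s + rnorm(1, 0, steps[["mu_sigma2"]])
  if (accept_mh(lp_s(prop, beta_s), lp_s(mu_s, beta_s))) {
    mu_s <- prop
    accept[["mu_sigma2"]] <- TRUE
  }
  prop <- beta_s + rnorm(1, 0, steps[["beta_sigma2"]])
  if (accept_mh(lp_s(mu_s, prop), lp_s(mu_s, beta_s))) {
    beta_s <- prop
    accept[["beta_sigma2"]] <- TRUE
  }

  list(eta = hyper_params(eta$mu_w, eta$sigma2_w, mu_a, sigma2_a,
                          mu_s, beta_s, eta$sigma2_mux),
       accept = accept)
}
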