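#' Draw Polya-gamma PG(1, c) auxiliary variables
#'
#' The Polya-gamma augmentation renders the Bernoulli likelihood
#' conditionally Gaussian: given \eqn{\omega_t \sim PG(1, \psi_t)} with
#' \eqn{\psi_t = w^\top u_t + x_t}, the pseudo-observation
#' \eqn{\kappa_t/\omega_t} (with \eqn{\kappa_t = y_t - 1/2}) has a normal
#' likelihood with precision \eqn{\omega_t}. Only the `b = 1` case (one
#' Bernoulli trial) is needed here.
#'
#' `method = "devroye"` is the exact alternating-series sampler and the
#' default. `method = "sumgamma"` is an approximate truncated
#' sum-of-gammas representation (`terms` >= 200 keeps the truncation error
#' in the mean below ~3e-4), kept as a slower, dependency-free fallback and
#' as an independent check on the exact sampler.
#'
#' @param n number of draws.
#' @param c tilt parameter(s), recycled to length `n`.
#' @param method sampler to use.
#' @param terms number of gamma terms for `method = "sumgamma"`.
#' @return `n` positive draws.
#' @export
rpg <- function(n, c = 0, method = c("devroye", "sumgamma"), terms = 200L) {
  method <- match.arg(method)
  if (anyNA(c) || any(!is.finite(c))) {
    stop("tilt parameter `c` must be finite", call. = FALSE)
  }
  if (method == "devroye") {
    .rpg_devroye(as.integer(n), as.numeric(c))
  } else {
    if (terms < 1) stop("`terms` must be >= 1", call. = FALSE)
    .rpg_sumgamma(as.integer(n), as.numeric(c), as.integer(terms))
  }
}
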