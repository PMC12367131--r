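#' Truncated normal and inverse-gamma helpers
#'
#' `rtnorm()` draws from a normal distribution truncated to
#' `[lower, upper]` by the inverse-CDF method, which stays robust when the
#' location sits near (or beyond) a boundary, where naive rejection sampling
#' stalls. `dtnorm()` is the matching density, `rinvgamma()`/`dinvgamma()`
#' the inverse-gamma draw and density in shape/scale parametrization
#' (mean = scale / (shape - 1) for shape > 1).
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the untruncated normal.
#' @param lower,upper truncation bounds.
#' @param x quantile(s).
#' @param log logical; return the log density?
#' @param shape,scale inverse-gamma shape and scale, both > 0.
#' @return draws or (log-)densities.
#' @name trunc_dists
NULL

#' @rdname trunc_dists
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = 0, upper = 1) {
  stopifnot(sd > 0, lower < upper)
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  u <- runif(n)
  x <- qnorm(plo + u * (phi - plo), mean, sd)
  pmin(pmax(x, lower), upper)
}

#' @rdname trunc_dists
#' @export
dtnorm <- function(x, mean = 0, sd = 1, lower = 0, upper = 1, log = FALSE) {
  stopifnot(sd > 0, lower < upper)
  # log(Phi(zb) - Phi(za)) computed in the better tail so it stays finite
  # even when the location sits far outside the truncation interval
  za <- (lower - mean) / sd
  zb <- (upper - mean) / sd
  lz <- if (za > 0) {
    la <- pnorm(za, lower.tail = FALSE, log.p = TRUE)
    lb <- pnorm(zb, lower.tail = FALSE, log.p = TRUE)
    la + log1p(-exp(lb - la))
  } else {
    la <- pnorm(za, log.p = TRUE)
    lb <- pnorm(zb, log.p = TRUE)
    lb + log1p(-exp(la - lb))
  }
  ld <- dnorm(x, mean, sd, log = TRUE) - lz
  ld[x < lower | x > upper] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname trunc_dists
#' @export
rinvgamma <- function(n, shape, scale) {
  stopifnot(shape > 0, scale > 0)
  1 / rgamma(n, shape = shape, rate = scale)
}

#' @rdname trunc_dists
#' @export
dinvgamma <- function(x, shape, scale, log = FALSE) {
  stopifnot(shape > 0, scale > 0)
  ld <- ifelse(x > 0,
               shape * base::log(scale) - lgamma(shape) -
                 (shape + 1) * base::log(x) - scale / x,
               -Inf)
  if (log) ld else exp(ld)
}
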