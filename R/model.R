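#' Numerically stable logistic function
#'
#' Maps log-odds to response probability, \eqn{f(z) = 1 / (1 + e^{-z})}.
#' Stable for arguments far beyond +-700 (no overflow).
#'
#' @param z numeric vector of finite log-odds.
#' @return probabilities in (0, 1).
#' @examples
#' sigmoid(0)      # 0.5
#' sigmoid(1.25)   # ~0.7773
#' @export
sigmoid <- function(z) {
  if (!is.numeric(z) || anyNA(z) || any(!is.finite(z))) {
    stop("`z` must be finite numeric log-odds", call. = FALSE)
  }
  plogis(z)
}

#' AR(1) intercept implied by the trajectory mean
#'
#' The latent criterion follows \eqn{x_t = b + a x_{t-1} + \epsilon_t}. The
#' intercept is never a free parameter: it is derived from the trajectory
#' mean \eqn{\mu_x} and the autoregressive coefficient as
#' \eqn{b = \mu_x (1 - a)}.
#'
#' @param mu_x real mean of the criterion trajectory.
#' @param a autoregressive coefficient in \[0, 1\].
#' @return the implied intercept \eqn{b}.
#' @export
derive_intercept <- function(mu_x, a) {
  if (!is.numeric(a) || anyNA(a) || any(a < 0) || any(a > 1)) {
    stop("`a` must lie in [0, 1]", call. = FALSE)
  }
  mu_x * (1 - a)
}

#' Inverse-gamma shape implied by the fluctuation-variance mean
#'
#' The population distribution of per-subject fluctuation variances is
#' inverse-gamma. Its shape is not free: the model estimates the mean
#' \eqn{\mu_{\sigma^2}} and scale \eqn{\beta_{\sigma^2}} and derives
#' \eqn{\alpha_{\sigma^2} = \beta_{\sigma^2} / \mu_{\sigma^2} + 1}, so the
#' inverse-gamma mean \eqn{\beta / (\alpha - 1)} equals
#' \eqn{\mu_{\sigma^2}} exactly. This decorrelates the shape and scale
#' estimates.
#'
#' @param beta_sigma2 positive inverse-gamma scale.
#' @param mu_sigma2 positive target mean of the fluctuation variances.
#' @return the implied shape (always > 1, so the mean exists).
#' @export
derive_alpha <- function(beta_sigma2, mu_sigma2) {
  if (!is.numeric(beta_sigma2) || !is.numeric(mu_sigma2) ||
      anyNA(beta_sigma2) || anyNA(mu_sigma2) ||
      any(beta_sigma2 <= 0) || any(mu_sigma2 <= 0)) {
    stop("`beta_sigma2` and `mu_sigma2` must be strictly positive",
         call. = FALSE)
  }
  beta_sigma2 / mu_sigma2 + 1
}

#' Per-subject generative parameters
#'
#' Bundles one subject's parameter vector: covariate weights `w`, the AR(1)
#' persistence `a` in \[0, 1\], the innovation variance `sigma2` (>= 0; zero
#' means a static criterion), and the trajectory mean `mu_x`. The AR(1)
#' intercept `b` is always derived, never set.
#'
#' @param w numeric vector of covariate weights.
#' @param a autoregressive coefficient in \[0, 1\].
#' @param sigma2 non-negative innovation variance.
#' @param mu_x real trajectory mean.
#' @return an object of class `subject_params`.
#' @export
subject_params <- function(w, a, sigma2, mu_x = 0) {
  stopifnot(is.numeric(w), length(w) >= 0)
  if (!is.numeric(a) || length(a) != 1 || is.na(a) || a < 0 || a > 1) {
    stop("`a` must be a single value in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(sigma2) || length(sigma2) != 1 || is.na(sigma2) ||
      sigma2 < 0) {
    stop("`sigma2` must be a single non-negative value", call. = FALSE)
  }
  if (!is.numeric(mu_x) || length(mu_x) != 1 || !is.finite(mu_x)) {
    stop("`mu_x` must be a single finite value", call. = FALSE)
  }
  structure(
    list(w = as.numeric(w), a = a, sigma2 = sigma2, mu_x = mu_x,
         b = derive_intercept(mu_x, a)),
    class = "subject_params"
  )
}

#' @export
print.subject_params <- function(x, ...) {
  cat("Per-subject parameters\n")
  cat("  w:      ", paste(signif(x$w, 4), collapse = ", "), "\n")
  cat("  a:      ", signif(x$a, 4), "\n")
  cat("  sigma2: ", signif(x$sigma2, 4), "\n")
  cat("  mu_x:   ", signif(x$mu_x, 4),
      " (implied b =", signif(x$b, 4), ")\n")
  invisible(x)
}

#' Group-level (hierarchical prior) parameters
#'
#' The population distributions over per-subject parameters:
#' `w_i ~ N(mu_w, diag(sigma2_w))`,
#' `a_i ~ TruncNorm(mu_a, sigma2_a, [0, 1])`,
#' `sigma2_i ~ InvGamma(alpha_sigma2, beta_sigma2)` with
#' `alpha_sigma2 = beta_sigma2 / mu_sigma2 + 1` derived, and
#' `mu_x_i ~ N(0, sigma2_mux)`.
#'
#' @param mu_w numeric vector, population mean of covariate weights.
#' @param sigma2_w positive vector, population variances of the weights.
#' @param mu_a location of the truncated-normal prior on `a_i`.
#' @param sigma2_a positive scale^2 of that prior.
#' @param mu_sigma2 positive mean of the inverse-gamma prior on `sigma2_i`.
#' @param beta_sigma2 positive scale of that prior.
#' @param sigma2_mux positive variance of the prior on `mu_x_i`.
#' @return an object of class `hyper_params` with the derived `alpha_sigma2`.
#' @export
hyper_params <- function(mu_w, sigma2_w, mu_a, sigma2_a, mu_sigma2,
                         beta_sigma2, sigma2_mux) {
  stopifnot(is.numeric(mu_w), is.numeric(sigma2_w),
            length(mu_w) == length(sigma2_w))
  pos <- c(sigma2_w, sigma2_a, mu_sigma2, beta_sigma2, sigma2_mux)
  if (anyNA(pos) || any(pos <= 0)) {
    stop("all variance-role parameters must be strictly positive",
         call. = FALSE)
  }
  if (!is.finite(mu_a)) stop("`mu_a` must be finite", call. = FALSE)
  structure(
    list(mu_w = as.numeric(mu_w), sigma2_w = as.numeric(sigma2_w),
         mu_a = mu_a, sigma2_a = sigma2_a, mu_sigma2 = mu_sigma2,
         beta_sigma2 = beta_sigma2, sigma2_mux = sigma2_mux,
         alpha_sigma2 = derive_alpha(beta_sigma2, mu_sigma2)),
    class = "hyper_params"
  )
}

#' @export
print.hyper_params <- function(x, ...) {
  cat("Group-level parameters\n")
  cat("  mu_w:       ", paste(signif(x$mu_w, 4), collapse = ", "), "\n")
  cat("  sigma2_w:   ", paste(signif(x$sigma2_w, 4), collapse = ", "), "\n")
  cat("  mu_a:       ", signif(x$mu_a, 4),
      "  sigma2_a:", signif(x$sigma2_a, 4), "\n")
  cat("  mu_sigma2:  ", signif(x$mu_sigma2, 4),
      "  beta_sigma2:", signif(x$beta_sigma2, 4),
      "  (implied alpha_sigma2 =", signif(x$alpha_sigma2, 4), ")\n")
  cat("  sigma2_mux: ", signif(x$sigma2_mux, 4), "\n")
  invisible(x)
}

#' Default group-level parameters of the reference simulation design
#'
#' Three covariate weights with population mean (0, 0.2, -0.1) and unit
#' variances; persistence `a_i` from TruncNorm(0.98, 0.03^2, \[0, 1\]);
#' fluctuation variances from an inverse-gamma with mean 0.2 and scale 0.5;
#' trajectory means with standard deviation 0.5.
#'
#' @return a [hyper_params] object.
#' @export
default_hyper_params <- function() {
  hyper_params(mu_w = c(0, 0.2, -0.1), sigma2_w = c(1, 1, 1),
               mu_a = 0.98, sigma2_a = 0.03^2,
               mu_sigma2 = 0.2, beta_sigma2 = 0.5,
               sigma2_mux = 0.5^2)
}

#' One subject's observed trials
#'
#' @param subject_id scalar identifier.
#' @param responses binary vector (0/1) of length `T`.
#' @param covariates numeric `T x p` matrix of per-trial covariates. Column
#'   names are kept if present. A constant column is rejected: the trajectory
#'   mean `mu_x` absorbs the intercept, so a constant covariate would be
#'   non-identifiable.
#' @return an object of class `subject_data` with element `n_trials`.
#' @export
subject_data <- function(subject_id, responses, covariates) {
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (!all(responses %in% c(0, 1))) {
    bad <- which(!(responses %in% c(0, 1)))
    stop("responses must be 0 or 1 (offending trials: ",
         paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
  }
  if (nrow(covariates) != length(responses)) {
    stop("covariate rows (", nrow(covariates),
         ") must match the number of responses (", length(responses), ")",
         call. = FALSE)
  }
  if (anyNA(covariates) || any(!is.finite(covariates))) {
    stop("covariates must be finite", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, responses = as.integer(responses),
         covariates = covariates, n_trials = length(responses)),
    class = "subject_data"
  )
}

#' @export
print.subject_data <- function(x, ...) {
  cat("Subject", x$subject_id, "-", x$n_trials, "trials,",
      ncol(x$covariates), "covariates, mean response",
      signif(mean(x$responses), 3), "\n")
  invisible(x)
}

#' Validate a multi-subject dataset
#'
#' Checks that every element is a [subject_data], that the covariate count is
#' shared, and that no covariate column is constant across all trials of all
#' subjects (the trajectory mean absorbs the intercept, so a constant column
#' is non-identifiable).
#'
#' @param data list of [subject_data] objects.
#' @return the validated list, invisibly.
#' @export
validate_dataset <- function(data) {
  if (!is.list(data) || length(data) == 0) {
    stop("`data` must be a non-empty list of subject_data objects",
         call. = FALSE)
  }
  ok <- vapply(data, inherits, logical(1), what = "subject_data")
  if (!all(ok)) {
    stop("elements ", paste(which(!ok), collapse = ", "),
         " are not subject_data objects", call. = FALSE)
  }
  p <- vapply(data, function(s) ncol(s$covariates), integer(1))
  if (length(unique(p)) != 1) {
    stop("all subjects must share the same covariate count; found ",
         paste(unique(p), collapse = ", "), call. = FALSE)
  }
  allu <- do.call(rbind, lapply(data, `[[`, "covariates"))
  if (anyNA(allu) || any(!is.finite(allu))) {
    stop("covariates contain missing or non-finite values", call. = FALSE)
  }
  const <- apply(allu, 2, function(col) diff(range(col)) == 0)
  if (any(const)) {
    stop("covariate column(s) ", paste(which(const), collapse = ", "),
         " are constant across all trials; the criterion mean absorbs the ",
         "intercept, so a constant covariate is non-identifiable",
         call. = FALSE)
  }
  invisible(data)
}
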