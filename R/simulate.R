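#' Simulate a latent AR(1) criterion trajectory
#'
#' Generates \eqn{x_t = b + a x_{t-1} + \epsilon_t}, \eqn{\epsilon_t \sim
#' N(0, \sigma^2)}, with \eqn{b = \mu_x (1 - a)}. Three first-state
#' conventions are supported. The default, `init = "innovation"`, draws
#' \eqn{x_1 \sim N(\mu_x, \sigma^2)}: \eqn{\mu_x} is the marginal mean at
#' every trial and \eqn{\sigma^2} sets the fluctuation scale at every
#' horizon, which stays well-behaved as \eqn{a \to 1} (the stationary
#' variance \eqn{\sigma^2/(1-a^2)} diverges there, producing saturated
#' observers whose responses never vary). `init = "stationary"` draws from
#' the stationary law \eqn{N(\mu_x, \sigma^2 / (1 - a^2))} (requires
#' `a < 1`); `init = "fixed"` sets the first state to `x1`.
#'
#' @param params a [subject_params] object.
#' @param n_trials trajectory length (>= 1).
#' @param init initial-state convention.
#' @param x1 first state when `init = "fixed"`.
#' @return numeric vector of length `n_trials`.
#' @export
simulate_ar1 <- function(params, n_trials,
                         init = c("innovation", "stationary", "fixed"),
                         x1 = 0) {
  stopifnot(inherits(params, "subject_params"), n_trials >= 1)
  init <- match.arg(init)
  a <- params$a
  s2 <- params$sigma2
  if (init == "innovation") {
    x0 <- rnorm(1, params$mu_x, sqrt(s2))
  } else if (init == "stationary") {
    if (a >= 1) {
      stop("stationary initialization requires a < 1 ",
           "(the stationary variance is undefined at a = 1)", call. = FALSE)
    }
    x0 <- rnorm(1, params$mu_x, sqrt(s2 / (1 - a^2)))
  } else {
    x0 <- x1
  }
  if (n_trials == 1) return(x0)
  eps <- rnorm(n_trials - 1, 0, sqrt(s2))
  # recursive filter on centered states: x_t - mu = a (x_{t-1} - mu) + eps
  xc <- stats::filter(eps, a, method = "recursive",
                      init = x0 - params$mu_x)
  c(x0, as.numeric(xc) + params$mu_x)
}

#' Simulate one subject's responses
#'
#' Draws a latent criterion trajectory and then responses
#' \eqn{y_t \sim Bern(f(w^\top u_t + x_t))}.
#'
#' @inheritParams simulate_ar1
#' @param covariates `T x p` matrix of covariate values; `p` must match
#'   `length(params$w)`.
#' @param subject_id identifier stored in the result.
#' @return list with elements `data` (a [subject_data]) and `trajectory`
#'   (the ground-truth latent states, for recovery testing).
#' @export
simulate_subject <- function(params, covariates, subject_id = 1L,
                             init = c("innovation", "stationary", "fixed"),
                             x1 = 0) {
  covariates <- as.matrix(covariates)
  if (ncol(covariates) != length(params$w)) {
    stop("covariates have ", ncol(covariates), " columns but `w` has length ",
         length(params$w), call. = FALSE)
  }
  x <- simulate_ar1(params, nrow(covariates), init = match.arg(init), x1 = x1)
  pr <- sigmoid(drop(covariates %*% params$w) + x)
  y <- rbinom(nrow(covariates), 1L, pr)
  list(data = subject_data(subject_id, y, covariates), trajectory = x)
}

#' Simulate a full hierarchical dataset
#'
#' Draws per-subject parameters from the group-level distributions
#' (`w_i ~ N(mu_w, diag(sigma2_w))`, `a_i ~ TruncNorm(mu_a, sigma2_a,
#' [0,1])`, `sigma2_i ~ InvGamma(alpha_sigma2, beta_sigma2)`,
#' `mu_x_i ~ N(0, sigma2_mux)`), then simulates covariates (i.i.d. standard
#' normal) and responses for each subject.
#'
#' A master seed is expanded into per-subject L'Ecuyer-CMRG substreams, so
#' changing `n_subjects` or `n_trials` does not correlate draws across
#' subjects. The caller's RNG state is restored on exit.
#'
#' @param eta a [hyper_params] object.
#' @param n_subjects number of subjects (>= 1).
#' @param n_trials trials per subject (>= 2); scalar or length-`n_subjects`.
#' @param seed master seed (integer). `NULL` draws one from the current RNG.
#' @param covariates optional list of user-supplied covariate matrices, one
#'   per subject, overriding the standard-normal default.
#' @return list of class `hmfc_sim` with elements `data` (list of
#'   [subject_data]), `params` (list of [subject_params] ground truth),
#'   `trajectories` (list of numeric vectors), and `eta`.
#' @export
simulate_dataset <- function(eta, n_subjects, n_trials, seed = NULL,
                             covariates = NULL) {
  stopifnot(inherits(eta, "hyper_params"), n_subjects >= 1,
            all(n_trials >= 2))
  n_trials <- rep_len(n_trials, n_subjects)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(seed)
  stream <- get(".Random.seed", globalenv())

  p <- length(eta$mu_w)
  data <- vector("list", n_subjects)
  params <- vector("list", n_subjects)
  traj <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    stream <- parallel::nextRNGStream(stream)
    assign(".Random.seed", stream, globalenv())
    w_i <- rnorm(p, eta$mu_w, sqrt(eta$sigma2_w))
    a_i <- rtnorm(1, eta$mu_a, sqrt(eta$sigma2_a), 0, 1)
    s2_i <- rinvgamma(1, eta$alpha_sigma2, eta$beta_sigma2)
    mux_i <- rnorm(1, 0, sqrt(eta$sigma2_mux))
    params[[i]] <- subject_params(w_i, a_i, s2_i, mux_i)
    u <- if (is.null(covariates)) {
      matrix(rnorm(n_trials[i] * p), n_trials[i], p,
             dimnames = list(NULL, paste0("cov_", seq_len(p))))
    } else {
      as.matrix(covariates[[i]])
    }
    sim <- simulate_subject(params[[i]], u, subject_id = i)
    data[[i]] <- sim$data
    traj[[i]] <- sim$trajectory
  }
  structure(list(data = data, params = params, trajectories = traj,
                 eta = eta, seed = seed),
            class = "hmfc_sim")
}

#' @export
print.hmfc_sim <- function(x, ...) {
  Ts <- vapply(x$data, `[[`, integer(1), "n_trials")
  cat("Simulated hierarchical dataset:", length(x$data), "subjects,",
      if (length(unique(Ts)) == 1) Ts[1] else paste(min(Ts), "-", max(Ts)),
      "trials,", ncol(x$data[[1]]$covariates), "covariates (seed",
      x$seed, ")\n")
  invisible(x)
}
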