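#' Read a long-format trial dataset
#'
#' Expects delimited text with header `subject,trial,response,cov_1..cov_p`
#' (any covariate column names are accepted; every column beyond the first
#' three is treated as a covariate). Trials are ordered by trial index
#' within subject. Validation rejects non-binary responses, missing or
#' non-finite covariates, duplicate (subject, trial) pairs, and constant
#' covariate columns, naming the offending rows.
#'
#' @param path CSV file path.
#' @param quiet suppress the summary message.
#' @return a validated list of [subject_data] objects.
#' @export
read_dataset <- function(path, quiet = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "trial", "response")
  if (!all(need %in% names(df))) {
    stop("dataset must have columns subject, trial, response; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  cov_cols <- setdiff(names(df), need)
  if (length(cov_cols) == 0) {
    stop("dataset has no covariate columns", call. = FALSE)
  }
  bad <- which(!(df$response %in% c(0, 1)))
  if (length(bad) > 0) {
    stop("non-binary responses at rows ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  covm <- as.matrix(df[cov_cols])
  if (anyNA(covm) || any(!is.finite(covm))) {
    bad <- which(rowSums(!is.finite(covm)) > 0)
    stop("missing or non-finite covariates at rows ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df[c("subject", "trial")])
  if (any(dup)) {
    stop("duplicate (subject, trial) pairs at rows ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  subjects <- unique(df$subject)
  data <- lapply(subjects, function(id) {
    rows <- df[df$subject == id, ]
    rows <- rows[order(rows$trial), ]
    subject_data(id, rows$response,
                 `dimnames<-`(as.matrix(rows[cov_cols]),
                              list(NULL, cov_cols)))
  })
  validate_dataset(data)
  if (!quiet) {
    Ts <- vapply(data, `[[`, integer(1), "n_trials")
    message("read ", length(data), " subjects, ",
            if (length(unique(Ts)) == 1) paste(Ts[1], "trials each")
            else paste("trials per subject in [", min(Ts), ", ", max(Ts), "]"),
            ", ", length(cov_cols), " covariates")
  }
  data
}

#' Write a dataset (and optional ground truth) to CSV
#'
#' The dataset goes to `path` in long format (one row per trial, 1-based
#' trial indices within subject). For simulated data, ground-truth
#' parameters and trajectories are written to sidecar files
#' `<path base>_params.csv` and `<path base>_trajectories.csv` for
#' recovery testing.
#'
#' @param data list of [subject_data], or an `hmfc_sim` (whose ground truth
#'   is then written too).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  sim <- NULL
  if (inherits(data, "hmfc_sim")) {
    sim <- data
    data <- data$data
  }
  rows <- lapply(data, function(s) {
    u <- s$covariates
    if (is.null(colnames(u))) {
      colnames(u) <- paste0("cov_", seq_len(ncol(u)))
    }
    cbind(data.frame(subject = s$subject_id,
                     trial = seq_len(s$n_trials),
                     response = s$responses),
          as.data.frame(u))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  if (!is.null(sim)) {
    base <- sub("\\.csv$", "", path)
    p <- length(sim$params[[1]]$w)
    par_df <- do.call(rbind, lapply(seq_along(sim$params), function(i) {
      pr <- sim$params[[i]]
      cbind(data.frame(subject = sim$data[[i]]$subject_id),
            as.data.frame(t(stats::setNames(pr$w, paste0("w_", seq_len(p))))),
            data.frame(a = pr$a, sigma2 = pr$sigma2, mu_x = pr$mu_x))
    }))
    write.csv(par_df, paste0(base, "_params.csv"), row.names = FALSE)
    traj_df <- do.call(rbind, lapply(seq_along(sim$trajectories), function(i) {
      data.frame(subject = sim$data[[i]]$subject_id,
                 trial = seq_along(sim$trajectories[[i]]),
                 x = sim$trajectories[[i]])
    }))
    write.csv(traj_df, paste0(base, "_trajectories.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Persist a fitted chain as columnar CSV files plus a manifest
#'
#' Writes one CSV per parameter group (`subject_params.csv` with the
#' per-iteration per-subject draws, `global_params.csv` with the
#' group-level draws, `trajectories.csv` with per-trial posterior means and
#' 95% credible bounds) and a JSON `manifest.json` recording the
#' configuration, seed, and package version, sufficient to re-run the job
#' bit-identically.
#'
#' @param fit an `hmfc_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "hmfc_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iters <- nrow(fit$eta)
  n <- ncol(fit$a)
  p <- dim(fit$w)[3]

  subj <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(data.frame(iteration = seq_len(iters),
                     subject = fit$subject_ids[i]),
          `colnames<-`(matrix(fit$w[, i, ], iters, p),
                       paste0("w_", seq_len(p))),
          data.frame(a = fit$a[, i], sigma2 = fit$sigma2[, i],
                     mu_x = fit$mu_x[, i]))
  }))
  write.csv(subj, file.path(dir, "subject_params.csv"), row.names = FALSE)
  write.csv(cbind(data.frame(iteration = seq_len(iters)),
                  as.data.frame(fit$eta)),
            file.path(dir, "global_params.csv"), row.names = FALSE)
  if (!is.null(fit$trajectory_draws)) {
    write.csv(trajectory_summary(fit),
              file.path(dir, "trajectories.csv"), row.names = FALSE)
  }
  manifest <- list(
    format_version = "1.0",
    package_version = as.character(utils::packageVersion("hmfc")),
    seed = fit$seed,
    config = fit$config[setdiff(names(fit$config), "hyperpriors")],
    hyperpriors = fit$config$hyperpriors,
    mh_steps_final = as.list(fit$mh_steps_final),
    n_subjects = n,
    n_trials = fit$n_trials
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}
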