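# Plain-text input/output: YAML run configs, tidy trajectory/thermo CSVs,
# rate-matrix CSVs, and JSON run summaries.

#' Read a run configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [run_config()] (`seed`,
#' `n_states`, `topology`, `rate_range`, `beta`, `amplitude`, `drive_shape`,
#' `init`, `t_equil`, `t_drive`, `t_post`, `ramp`, `dt`, `record_every`,
#' `plateau_tol`, `ness_tol`) plus an optional `stressors` list of
#' `{kind, amplitude, t_on, duration}` entries.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must contain a seed")
  stressors <- lapply(y$stressors, function(s)
    stressor_event(kind = s$kind, amplitude = s$amplitude, t_on = s$t_on,
                   duration = s$duration %||% Inf))
  y$stressors <- NULL
  args <- y[names(y) %in% names(formals(run_config))]
  args$stressors <- stressors
  if (!is.null(args$rate_range)) args$rate_range <- as.numeric(args$rate_range)
  do.call(run_config, args)
}

#' Write a run configuration to YAML
#' @param config a [run_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$landscape <- NULL
  x$plateau_window <- NULL
  x$stressors <- lapply(config$stressors, function(ev)
    list(kind = ev$kind, amplitude = ev$amplitude, t_on = ev$t_on,
         duration = if (is.finite(ev$duration)) ev$duration else NULL))
  if (!length(x$stressors)) x$stressors <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Write a trajectory as tidy CSV
#'
#' Long format, one row per (time, state): columns `t`, `state` (1-based
#' index), `p`.
#'
#' @param trajectory a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  n <- ncol(trajectory$p)
  d <- data.frame(
    t = rep(trajectory$time, each = n),
    state = rep.int(seq_len(n), length(trajectory$time)),
    p = as.vector(t(trajectory$p))
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write thermodynamic observables as CSV
#'
#' Columns `t, S_sys, dS_sys, dS_tot, dS_res, S_int_cum, S_exp_cum` (the
#' cumulative columns are added via [accumulate_thermo()] if absent).
#'
#' @param trajectory a `trajectory` or a thermo data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_thermo_csv <- function(trajectory, path) {
  th <- if (inherits(trajectory, "trajectory")) accumulate_thermo(trajectory)
        else trajectory
  utils::write.csv(th, path, row.names = FALSE)
  invisible(path)
}

#' Write a rate matrix as dense CSV
#'
#' Row/column headers are 0-based state indices.
#'
#' @param K rate matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rate_matrix_csv <- function(K, path) {
  m <- unclass(K)
  dimnames(m) <- list(seq_len(nrow(m)) - 1L, seq_len(ncol(m)) - 1L)
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' Read a rate matrix from dense CSV
#'
#' @param path CSV written by [write_rate_matrix_csv()] (first column = row
#'   labels).
#' @param topology topology attribute to attach (`"chain"`, `"ring"`, or
#'   `"custom"`).
#' @return a `rate_matrix`.
#' @export
read_rate_matrix_csv <- function(path, topology = "custom") {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  dimnames(m) <- NULL
  K <- new_rate_matrix(m, topology)
  validate_rate_matrix(K, tol = 1e-8)
  K
}

#' Write a JSON summary of a bathtub run
#'
#' Emits plateau entropy, equilibrium entropy, bathtub depth, recovery gap,
#' maximum production rate, and the Glansdorff-Prigogine fraction.
#'
#' @param run a `bathtub_run`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(run, path) {
  s <- run$summary
  x <- list(
    S_equilibrium = s$S_equilibrium, S_plateau = s$S_plateau,
    bathtub_depth = s$bathtub_depth, S_final = s$S_final,
    recovery_gap = s$recovery_gap,
    relaxation_time = s$relaxation_time,
    max_dS_tot = max(run$thermo$dS_tot),
    gp_fraction = s$gp_fraction,
    is_strict_ness = s$ness_certificate$is_strict_ness
  )
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
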