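# Experiment orchestration: bathtub life-cycle runs, stressor perturbation
# runs, NESS certification, and plateau detection.

#' Configuration for a bathtub or stressor run
#'
#' The defaults are the canonical life-cycle conditions: a chain of 30
#' potential wells, undriven base rates sampled uniformly from
#' `[0.01, 0.02]`, a uniform-random initial distribution, `beta = 1`, and a
#' unidirectional drive of amplitude 1 toward state 1. Time is dimensionless
#' (units of the inverse intrinsic jump rate). The default phase lengths
#' (equilibration 25000, drive 20000, post-drive 40000) are several multiples
#' of the undriven chain's slowest relaxation time, so the run starts within
#' 1% of the undriven stationary state, holds the driven plateau for many
#' driven relaxation times, and recovers to equilibrium afterwards.
#'
#' @param seed integer seed (mandatory; drives both the rate draw and the
#'   initial distribution).
#' @param n_states number of wells.
#' @param topology `"chain"` or `"ring"`.
#' @param rate_range bounds of the uniform base-rate draw.
#' @param landscape optional [energy_landscape()]; if given, base rates are
#'   built from it (Arrhenius path) instead of sampled.
#' @param beta inverse temperature.
#' @param amplitude main drive energy per forward edge.
#' @param drive_shape `"rectangular"` or `"trapezoidal"`.
#' @param init initial distribution: `"uniform_random"` (entries drawn
#'   uniformly, then normalized), `"uniform"`, `"stationary"` (of the base
#'   rates), or a numeric vector.
#' @param t_equil,t_drive,t_post phase durations; for a trapezoidal drive the
#'   plateau of length `t_drive` is flanked by two linear ramps of length
#'   `ramp`.
#' @param ramp trapezoid ramp duration.
#' @param dt Euler step.
#' @param record_every recording stride in steps.
#' @param plateau_tol plateau-detection tolerance (fraction of series range).
#' @param plateau_window plateau-detection window (default `0.1 * t_drive`).
#' @param ness_tol tolerance for NESS certification.
#' @param stressors list of [stressor_event()]s (used by [run_stressor()]).
#' @param drive_until_end if `TRUE` the drive stays on to the end of the run
#'   (no recovery phase); used for stressor experiments.
#' @return a `run_config` list.
#' @export
run_config <- function(seed, n_states = 30L, topology = "chain",
                       rate_range = c(0.01, 0.02), landscape = NULL,
                       beta = 1, amplitude = 1,
                       drive_shape = c("rectangular", "trapezoidal"),
                       init = "uniform_random",
                       t_equil = 25000, t_drive = 20000, t_post = 40000,
                       ramp = 5000, dt = 0.5, record_every = 20L,
                       plateau_tol = 0.01, plateau_window = NULL,
                       ness_tol = 1e-8, stressors = list(),
                       drive_until_end = FALSE) {
  if (missing(seed)) stop("a seed is mandatory")
  drive_shape <- match.arg(drive_shape)
  structure(
    list(seed = as.integer(seed), n_states = as.integer(n_states),
         topology = topology, rate_range = rate_range, landscape = landscape,
         beta = beta, amplitude = amplitude, drive_shape = drive_shape,
         init = init, t_equil = t_equil, t_drive = t_drive, t_post = t_post,
         ramp = ramp, dt = dt, record_every = as.integer(record_every),
         plateau_tol = plateau_tol,
         plateau_window = plateau_window %||% (0.1 * t_drive),
         ness_tol = ness_tol, stressors = stressors,
         drive_until_end = drive_until_end),
    class = "run_config")
}

config_base_rates <- function(config) {
  if (!is.null(config$landscape)) build_rates(config$landscape)
  else sample_base_rates(config$n_states, config$rate_range[1],
                         config$rate_range[2], config$topology, config$seed)
}

config_initial_state <- function(config, base) {
  n <- config$n_states
  p0 <- if (is.numeric(config$init)) config$init
  else switch(config$init,
    uniform_random = withr::with_seed(config$seed + 1L, stats::runif(n)),
    uniform = rep(1, n),
    stationary = stationary_distribution(base),
    stop("unknown initial-distribution spec: ", config$init))
  probability_state(p0 / sum(p0))
}

config_protocol <- function(config) {
  t_on <- config$t_equil
  if (config$drive_shape == "rectangular") {
    t_off <- if (config$drive_until_end) config$t_equil + config$t_drive +
      config$t_post + 1 else t_on + config$t_drive
    protocol_rectangular(config$amplitude, t_on, t_off)
  } else {
    protocol_trapezoidal(config$amplitude, t_on, t_on + config$ramp,
                         t_on + config$ramp + config$t_drive,
                         t_on + 2 * config$ramp + config$t_drive)
  }
}

config_t_end <- function(config) {
  extra <- if (config$drive_shape == "trapezoidal") 2 * config$ramp else 0
  config$t_equil + config$t_drive + extra + config$t_post
}

# window [t0, t1] of the constant-drive plateau of the main protocol
config_plateau_window <- function(config) {
  t_on <- config$t_equil +
    if (config$drive_shape == "trapezoidal") config$ramp else 0
  c(t_on, t_on + config$t_drive)
}

#' Detect a plateau in a time series
#'
#' Finds the earliest time from which the series stays within
#' `tol * range(series)` (plus a tiny absolute floor) over a stretch of at
#' least `window` time units, then extends that stretch for as long as the
#' values remain inside the band around its running center.
#'
#' @param t time stamps (uniformly spaced).
#' @param x series values.
#' @param window minimum plateau duration (time units).
#' @param tol band width as a fraction of the full series range.
#' @return `list(t_enter, plateau_mean, idx)` or `NULL` if no plateau.
#' @export
detect_plateau <- function(t, x, window, tol = 0.01) {
  m <- length(x)
  if (m < 2 || t[m] - t[1] < window) return(NULL)
  h <- t[2] - t[1]
  wn <- max(2L, as.integer(ceiling(window / h)))
  if (wn > m) return(NULL)
  band <- tol * diff(range(x)) + 1e-12 * max(1, max(abs(x)))
  hi <- zoo::rollapply(x, wn, max, align = "left")
  lo <- zoo::rollapply(x, wn, min, align = "left")
  ok <- which(hi - lo < band)
  if (!length(ok)) return(NULL)
  i0 <- ok[1]
  center <- stats::median(x[i0:(i0 + wn - 1L)])
  j <- i0 + wn - 1L
  while (j < m && abs(x[j + 1L] - center) < band) j <- j + 1L
  idx <- i0:j
  list(t_enter = t[i0], plateau_mean = mean(x[idx]), idx = idx)
}

#' Certify a stationary state as a (strict) NESS
#'
#' A stationary distribution is a strict non-equilibrium steady state when
#' (i) it is stationary (`||K p|| < tol`), (ii) some Kolmogorov cycle ratio
#' differs from 1, and (iii) some per-edge current is nonzero. Tree graphs
#' (chains) have no cycles, cannot sustain stationary currents, and are
#' always certified non-strict, with an explanatory note.
#'
#' @param K driven `rate_matrix` (connected edge graph).
#' @param tol certification tolerance.
#' @return a `ness_certificate` list: `p_st`, `stationarity_residual`,
#'   `max_current`, `cycle_ratios`, `currents_vanish`, `is_strict_ness`,
#'   `note`.
#' @export
certify_ness <- function(K, tol = 1e-8) {
  p_st <- stationary_distribution(K)
  resid <- max(abs(unclass(K) %*% p_st))
  J <- current_matrix(K, p_st)
  max_cur <- max(abs(J))
  ratios <- kolmogorov_cycle_ratios(K)
  cycle_broken <- length(ratios) > 0 &&
    any(vapply(ratios, function(r) abs(r$log_ratio) > tol, logical(1)))
  strict <- (resid < tol) && cycle_broken && (max_cur > tol)
  note <- if (length(ratios) == 0)
    "tree topology: no cycles, stationary currents vanish pairwise; strict NESS impossible"
  else if (!cycle_broken)
    "all cycle ratios equal 1: detailed-balance dynamics"
  else NULL
  structure(list(p_st = p_st, stationarity_residual = resid,
                 max_current = max_cur, cycle_ratios = ratios,
                 currents_vanish = max_cur < tol,
                 is_strict_ness = strict, note = note),
            class = "ness_certificate")
}

#' @export
print.ness_certificate <- function(x, ...) {
  cat("NESS certificate\n")
  cat(sprintf("  stationarity residual: %.3e\n", x$stationarity_residual))
  cat(sprintf("  max per-edge current:  %.3e\n", x$max_current))
  if (length(x$cycle_ratios))
    cat(sprintf("  cycle ratio(s): %s\n",
                paste(vapply(x$cycle_ratios, function(r)
                  sprintf("%.6g", r$ratio), character(1)), collapse = ", ")))
  cat(sprintf("  strict NESS: %s\n", x$is_strict_ness))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Run a bathtub life-cycle experiment
#'
#' Executes equilibration (no drive), the driving protocol, and post-drive
#' relaxation in a single propagation; computes the cumulative entropy
#' bookkeeping, detects the entropy plateau inside the constant-drive
#' window, and summarizes the run (equilibrium entropy, plateau entropy,
#' bathtub depth, relaxation time, NESS certificate of the driven rates, and
#' the Glansdorff-Prigogine fraction over the drive plateau).
#'
#' @param config a [run_config()].
#' @return a `bathtub_run`: `list(trajectory, thermo, summary, base)`.
#' @export
run_bathtub <- function(config) {
  base <- config_base_rates(config)
  p0 <- config_initial_state(config, base)
  protocol <- config_protocol(config)
  traj <- propagate(p0, base, protocol, t_end = config_t_end(config),
                    dt = config$dt, record_every = config$record_every,
                    beta = config$beta)
  thermo <- accumulate_thermo(traj)
  summary <- summarize_bathtub(traj, thermo, config)
  structure(list(trajectory = traj, thermo = thermo, summary = summary,
                 base = base),
            class = "bathtub_run")
}

summarize_bathtub <- function(traj, thermo, config) {
  S <- thermo$S_sys
  tt <- thermo$t
  pw <- config_plateau_window(config)

  pre <- tt < config$t_equil & tt >= 0.8 * config$t_equil
  S_equilibrium <- mean(S[pre])

  in_drive <- tt >= pw[1] & tt <= pw[2]
  pd <- detect_plateau(tt[in_drive], S[in_drive],
                       window = config$plateau_window,
                       tol = config$plateau_tol)
  S_plateau <- if (is.null(pd)) NA_real_ else pd$plateau_mean
  plateau_idx <- if (is.null(pd)) integer(0) else which(in_drive)[pd$idx]
  max_dS_sys_plateau <- if (length(plateau_idx))
    max(abs(thermo$dS_sys[plateau_idx])) else NA_real_

  tail_n <- max(5L, ceiling(0.05 * length(S)))
  S_final <- mean(S[seq.int(length(S) - tail_n + 1L, length(S))])

  # relaxation into the driven plateau: restrict the record to the drive
  # window so the post-drive recovery does not redefine the plateau
  drive_slice <- traj
  drive_slice$time <- tt[in_drive]
  drive_slice$thermo <- traj$thermo[in_drive, ]
  drive_slice$p <- traj$p[in_drive, , drop = FALSE]
  relax <- tryCatch(
    relaxation_time(drive_slice, "entropy", tol = config$plateau_tol,
                    t_min = pw[1]),
    warning = function(w) NA_real_)

  field <- uniform_driving_field(config$n_states, config$amplitude,
                                 config$topology, "forward")
  K_driven <- apply_drive_to_base(config_base_rates(config), field,
                                  config$beta)
  ness <- certify_ness(K_driven, config$ness_tol)

  margin <- 10 * config$dt * config$record_every
  gp_in <- tt >= pw[1] + margin & tt <= pw[2] - margin
  gp_fraction <- if (sum(gp_in) >= 5)
    gp_diagnostic(thermo[gp_in, ])$fraction else NA_real_

  list(S_equilibrium = S_equilibrium, S_plateau = S_plateau,
       bathtub_depth = S_equilibrium - S_plateau,
       S_final = S_final,
       recovery_gap = abs(S_final - S_equilibrium) / S_equilibrium,
       max_dS_sys_plateau = max_dS_sys_plateau,
       relaxation_time = relax,
       plateau_detected = !is.null(pd),
       plateau_idx = plateau_idx,
       ness_certificate = ness,
       gp_fraction = gp_fraction,
       max_entropy = log(config$n_states))
}

#' @export
print.bathtub_run <- function(x, ...) {
  s <- x$summary
  cat("Entropy-bathtub run\n")
  cat(sprintf("  equilibrium entropy: %.4f (max ln n = %.4f)\n",
              s$S_equilibrium, s$max_entropy))
  cat(sprintf("  plateau entropy:     %.4f (depth %.4f)\n",
              s$S_plateau, s$bathtub_depth))
  cat(sprintf("  final entropy:       %.4f (recovery gap %.2f%%)\n",
              s$S_final, 100 * s$recovery_gap))
  cat(sprintf("  relaxation time:     %.0f\n", s$relaxation_time))
  cat(sprintf("  GP fraction (drive plateau): %.3f\n", s$gp_fraction))
  invisible(x)
}

#' Run stressor perturbation experiments
#'
#' Each configured stressor event is applied in its own run on top of the
#' main drive (which here stays on to the end of the run, so the perturbed
#' and recovered steady states are visible). For a pulse the outcome records
#' the pre-pulse plateau, the mean entropy during the pulse, and the
#' post-recovery plateau; for a step it records the new plateau and the
#' total-variation distance between the final state and the stationary
#' distribution of the stressed rate matrix (independent linear-solve
#' oracle).
#'
#' @param config a [run_config()] with a non-empty `stressors` list; every
#'   event must start after the main drive has reached its plateau.
#' @return a `stressor_run`: `list(trajectories, outcomes, baseline)` where
#'   `outcomes` is a data frame with one row per event.
#' @export
run_stressor <- function(config) {
  if (!length(config$stressors)) stop("config has no stressor events")
  config$drive_until_end <- TRUE
  base <- config_base_rates(config)
  p0 <- config_initial_state(config, base)
  t_end <- config_t_end(config)
  main <- config_protocol(config)

  field_f <- uniform_driving_field(config$n_states, config$amplitude,
                                   config$topology, "forward")
  win <- config$plateau_window

  trajectories <- list()
  rows <- list()
  for (i in seq_along(config$stressors)) {
    ev <- config$stressors[[i]]
    if (ev$t_on <= config$t_equil)
      stop("stressor starts before the main drive has a plateau")
    traj <- propagate(p0, base, add_stressor(main, ev), t_end = t_end,
                      dt = config$dt, record_every = config$record_every,
                      beta = config$beta)
    tt <- traj$time; S <- traj$thermo$S_sys
    pre <- tt >= ev$t_on - win & tt < ev$t_on
    S_pre <- mean(S[pre])
    if (ev$kind == "pulse") {
      during <- tt >= ev$t_on & tt < ev$t_on + ev$duration
      post <- tt >= t_end - win
      out <- data.frame(kind = "pulse", amplitude = ev$amplitude,
                        S_pre = S_pre, S_during = mean(S[during]),
                        S_post = mean(S[post]),
                        recovery_gap = abs(mean(S[post]) - S_pre),
                        tv_to_oracle = NA_real_)
    } else {
      post <- tt >= t_end - win
      field_b <- uniform_driving_field(config$n_states, ev$amplitude,
                                       config$topology, "backward")
      K_str <- apply_drive_to_base(
        apply_drive_to_base(base, field_f, config$beta), field_b, config$beta)
      p_or <- stationary_distribution(K_str)
      tv <- 0.5 * sum(abs(traj$p[nrow(traj$p), ] - p_or))
      out <- data.frame(kind = "step", amplitude = ev$amplitude,
                        S_pre = S_pre, S_during = NA_real_,
                        S_post = mean(S[post]),
                        recovery_gap = NA_real_, tv_to_oracle = tv)
    }
    trajectories[[i]] <- traj
    rows[[i]] <- out
  }
  outcomes <- do.call(rbind, rows)
  S_eq <- shannon_entropy(stationary_distribution(base))
  structure(list(trajectories = trajectories, outcomes = outcomes,
                 S_equilibrium = S_eq, base = base),
            class = "stressor_run")
}

#' @export
print.stressor_run <- function(x, ...) {
  cat("Stressor experiment\n")
  cat(sprintf("  equilibrium entropy of undriven system: %.4f\n",
              x$S_equilibrium))
  print(x$outcomes, row.names = FALSE)
  invisible(x)
}
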