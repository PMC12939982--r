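# Master-equation dynamics: probability currents, explicit-Euler propagation
# of dp/dt = K p, stationary distributions, and detailed-balance diagnostics.

#' Probability state of the jump process
#'
#' @param p non-negative probability vector (normalized to sum 1 within
#'   `1e-10`; renormalized exactly on construction).
#' @param t time stamp (dimensionless units of the inverse intrinsic jump
#'   rate).
#' @return an object of class `probability_state`.
#' @export
probability_state <- function(p, t = 0) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("probabilities must be >= 0")
  if (abs(sum(p) - 1) > 1e-10) stop("probabilities must sum to 1")
  structure(list(p = p / sum(p), t = t), class = "probability_state")
}

as_prob_vector <- function(state) {
  if (inherits(state, "probability_state")) state$p else as.numeric(state)
}

#' @export
print.probability_state <- function(x, ...) {
  cat(sprintf("Probability state at t = %g over %d states\n", x$t,
              length(x$p)))
  print(round(x$p, 4))
  invisible(x)
}

#' Probability current matrix
#'
#' `J[x, xp] = K[x, xp] p[xp] - K[xp, x] p[x]` is the net probability flow
#' from `xp` into `x`; the matrix is antisymmetric by construction and its
#' row sums equal `dp/dt`.
#'
#' @param K rate matrix (generator).
#' @param state probability vector or `probability_state`.
#' @return antisymmetric numeric matrix of currents.
#' @export
current_matrix <- function(K, state) {
  p <- as_prob_vector(state)
  if (length(p) != nrow(K)) stop("dimension mismatch between K and p")
  Ku <- unclass(K)
  attr(Ku, "topology") <- NULL
  A <- sweep(Ku, 2, p, "*")
  diag(A) <- 0
  A - t(A)
}

#' One explicit-Euler step of the master equation
#'
#' Advances `p <- p + dt * K p`, clamps round-off negatives (down to
#' `-1e-12`) to zero, renormalizes to sum 1, and advances the clock. The
#' stability guard `dt * max|K_xx| <= guard` keeps the update a positive,
#' probability-preserving map.
#'
#' @param state a `probability_state`.
#' @param K rate matrix.
#' @param dt time step (> 0).
#' @param guard stability bound on `dt * max|diag(K)|` (default 0.1).
#' @return the advanced `probability_state`.
#' @export
euler_step <- function(state, K, dt, guard = 0.1) {
  stopifnot(dt > 0)
  if (dt * max(abs(diag(K))) > guard + 1e-12)
    stop("time step violates the stability guard dt * max|K_xx| <= ", guard)
  p <- state$p + dt * as.vector(unclass(K) %*% state$p)
  if (any(p < -1e-12))
    stop("negative probability encountered; reduce dt")
  p[p < 0] <- 0
  probability_state(p / sum(p), state$t + dt)
}

#' Propagate the master equation under a driving protocol
#'
#' Explicit-Euler integration of `dp/dt = K(t) p` where
#' `K(t) = base rates x exp(beta * delta(t))` edge-wise, with `delta(t)`
#' evaluated from the protocol (main amplitude on forward edges, stressor
#' amplitude on backward edges). Every `record_every`-th step the state is
#' recorded together with its instantaneous thermodynamic observables
#' (Shannon entropy, Schnakenberg system-entropy rate, total
#' entropy-production rate, reservoir rate). Recorded timestamps are exact
#' multiples of `dt * record_every`.
#'
#' @param initial a `probability_state` (its `t` is taken as 0).
#' @param base undriven `rate_matrix`.
#' @param protocol a `driving_protocol` (default: undriven).
#' @param t_end final time.
#' @param dt Euler step; must satisfy the stability guard for the
#'   maximally-driven rate matrix over the whole protocol.
#' @param record_every record every this many steps (default 10).
#' @param beta inverse temperature used to convert drive energies to rate
#'   factors.
#' @param guard stability bound (see [euler_step()]).
#' @return an object of class `trajectory`: recorded times, probability
#'   matrix (rows = records), drive amplitudes, and a `thermo` data frame
#'   with columns `t, S_sys, dS_sys, dS_tot, dS_res`.
#' @export
propagate <- function(initial, base, protocol = zero_protocol(), t_end, dt,
                      record_every = 10L, beta = 1, guard = 0.1) {
  stopifnot(inherits(initial, "probability_state"), t_end > 0, dt > 0)
  n <- nrow(base)
  if (length(initial$p) != n) stop("initial state does not match rate matrix")
  topology <- attr(base, "topology")
  if (!topology %in% c("chain", "ring"))
    stop("propagate needs a chain or ring rate matrix")
  idx <- edge_indices(n, topology)
  base_off <- unclass(base); diag(base_off) <- 0

  # stability pre-check at the largest drive anywhere in the protocol
  amax <- protocol_max_amplitudes(protocol)
  worst <- base_off
  worst[idx$forward] <- worst[idx$forward] * exp(beta * amax["forward"])
  worst[idx$backward] <- worst[idx$backward] * exp(beta * amax["backward"])
  if (dt * max(colSums(worst)) > guard + 1e-12)
    stop("dt violates the stability guard for the maximally driven rates")

  n_steps <- as.integer(round(t_end / dt))
  record_every <- as.integer(record_every)
  step_t <- (seq_len(n_steps) - 1L) * dt
  aa <- drive_amplitude(protocol, step_t)
  ss <- stressor_amplitude(protocol, step_t)

  rec_idx <- seq.int(0L, n_steps, by = record_every)
  if (rec_idx[length(rec_idx)] != n_steps) rec_idx <- c(rec_idx, n_steps)
  n_rec <- length(rec_idx)
  P <- matrix(NA_real_, n_rec, n)
  th <- matrix(NA_real_, n_rec, 5,
               dimnames = list(NULL, c("t", "S_sys", "dS_sys", "dS_tot",
                                       "dS_res")))
  a_rec <- numeric(n_rec); s_rec <- numeric(n_rec)

  K <- base_off
  la <- NA_real_; ls <- NA_real_
  p <- initial$p
  r <- 1L
  for (k in 0L:n_steps) {
    # amplitudes governing the step starting at t_k (and the observables there)
    if (k < n_steps) { ak <- aa[k + 1L]; sk <- ss[k + 1L] }
    else { ak <- drive_amplitude(protocol, k * dt)
           sk <- stressor_amplitude(protocol, k * dt) }
    if (!identical(ak, la) || !identical(sk, ls)) {
      K <- base_off
      if (ak != 0) K[idx$forward] <- K[idx$forward] * exp(beta * ak)
      if (sk != 0) K[idx$backward] <- K[idx$backward] * exp(beta * sk)
      diag(K) <- -colSums(K)
      la <- ak; ls <- sk
    }
    if (k == rec_idx[r]) {
      J <- current_matrix(K, p)
      P[r, ] <- p
      th[r, ] <- c(k * dt,
                   shannon_entropy(p),
                   system_entropy_rate(J, p),
                   total_entropy_production(K, p),
                   reservoir_entropy_rate(K, p))
      a_rec[r] <- ak; s_rec[r] <- sk
      r <- r + 1L
    }
    if (k < n_steps) {
      p <- p + dt * as.vector(K %*% p)
      if (any(p < -1e-12)) stop("negative probability at t = ", k * dt,
                                "; reduce dt")
      p[p < 0] <- 0
      p <- p / sum(p)
    }
  }
  structure(
    list(time = th[, "t"], p = P, drive = a_rec, stress = s_rec,
         thermo = as.data.frame(th), base = base, beta = beta,
         protocol = protocol, dt = dt, record_every = record_every,
         topology = topology),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d states, %d records over t in [0, %g] (dt = %g)\n",
    ncol(x$p), length(x$time), max(x$time), x$dt))
  cat(sprintf("  S_sys range [%.4f, %.4f]\n",
              min(x$thermo$S_sys), max(x$thermo$S_sys)))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$time, x$thermo$S_sys, type = "l", xlab = "t",
       ylab = expression(S[sys] / k[B]), ...)
  plot(x$time, x$drive, type = "l", col = "blue", xlab = "t",
       ylab = expression(delta(t)), ylim = range(c(x$drive, x$stress)))
  graphics::lines(x$time, x$stress, col = "red")
  invisible(x)
}

#' Exact propagator over a constant-rate interval
#'
#' Matrix-exponential solution `p(t) = expm(K t) p(0)` of the master
#' equation; used as an independent cross-check of the Euler integrator on
#' constant-drive segments.
#'
#' @param state a `probability_state` or probability vector.
#' @param K constant rate matrix.
#' @param t elapsed time.
#' @return the propagated probability vector.
#' @export
propagate_exact <- function(state, K, t) {
  p <- as_prob_vector(state)
  as.vector(Matrix::expm(Matrix::Matrix(unclass(K) * t)) %*% p)
}

#' Stationary distribution of a generator
#'
#' Solves `K p = 0` with the normalization `sum(p) = 1` by a dense linear
#' solve. Errors if the edge graph is disconnected (stationary state not
#' unique).
#'
#' @param K rate matrix.
#' @return stationary probability vector (entries >= 0, sum 1).
#' @export
stationary_distribution <- function(K) {
  n <- nrow(K)
  adj <- (unclass(K) > 0) | (t(unclass(K)) > 0)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (igraph::components(g)$no > 1)
    stop("edge graph is disconnected: stationary distribution is not unique")
  A <- rbind(unclass(K), rep(1, n))
  p <- qr.solve(A, c(rep(0, n), 1))
  if (any(p < -1e-10)) stop("stationary solve produced negative entries")
  p[p < 0] <- 0
  p / sum(p)
}

#' Maximum detailed-balance violation at a state
#'
#' Returns `max |K[x,xp] p[xp] - K[xp,x] p[x]|` over all pairs; zero exactly
#' when detailed balance holds at this state.
#'
#' @param K rate matrix.
#' @param state probability vector or `probability_state`.
#' @return non-negative scalar.
#' @export
detailed_balance_residual <- function(K, state) {
  max(abs(current_matrix(K, state)))
}

#' Kolmogorov cycle ratios
#'
#' For each fundamental cycle of the topology, the ratio of the product of
#' rates traversing the cycle in increasing-index orientation to the product
#' in the reverse orientation. A ratio different from 1 on some cycle is the
#' cycle condition certifying that a stationary state can be a true NESS; a
#' chain (tree graph) has no cycles and returns an empty list.
#'
#' @param K `rate_matrix` with a `"chain"` or `"ring"` topology attribute.
#' @return list of `list(cycle, ratio, log_ratio)`, empty for a chain.
#' @export
kolmogorov_cycle_ratios <- function(K) {
  topology <- attr(K, "topology")
  if (is.null(topology)) stop("K carries no topology attribute")
  if (topology == "chain") return(list())
  if (topology != "ring") stop("cycle enumeration supports chain and ring")
  n <- nrow(K)
  from <- seq_len(n)
  to <- c(seq.int(2L, n), 1L)           # orientation 1 -> 2 -> ... -> n -> 1
  fwd <- unclass(K)[cbind(to, from)]
  bwd <- unclass(K)[cbind(from, to)]
  if (any(fwd == 0) || any(bwd == 0))
    stop("zero rate on a cycle edge: cycle ratio undefined")
  lr <- sum(log(fwd)) - sum(log(bwd))
  list(list(cycle = seq_len(n), ratio = exp(lr), log_ratio = lr))
}

#' Relaxation time of a recorded trajectory
#'
#' Plateau-band entry time: the first recorded time (at or after `t_min`)
#' from which the chosen observable stays within `tol * |plateau|` of its
#' final plateau value for the remainder of the record (if the plateau value
#' is ~0, the band is `tol * range` instead). Returns `NA` with a warning if
#' no such time exists.
#'
#' @param trajectory a `trajectory`.
#' @param observable `"entropy"` (Shannon entropy series) or
#'   `"total_variation"` (TV distance to the final recorded state).
#' @param tol band width as a fraction of the plateau value (default 0.01).
#' @param t_min ignore records before this time (e.g. the drive onset).
#' @return the absolute entry time, or `NA_real_`.
#' @export
relaxation_time <- function(trajectory,
                            observable = c("entropy", "total_variation"),
                            tol = 0.01, t_min = 0) {
  observable <- match.arg(observable)
  keep <- trajectory$time >= t_min
  tt <- trajectory$time[keep]
  x <- switch(observable,
    entropy = trajectory$thermo$S_sys[keep],
    total_variation = {
      P <- trajectory$p[keep, , drop = FALSE]
      0.5 * rowSums(abs(sweep(P, 2, P[nrow(P), ])))
    })
  m <- length(x)
  tail_n <- max(5L, ceiling(0.05 * m))
  plateau <- mean(x[seq.int(m - tail_n + 1L, m)])
  rng <- diff(range(x))
  # observables that decay to ~0 (e.g. TV distance) get a range-based band
  band <- if (abs(plateau) > 1e-6 * rng) tol * abs(plateau) else tol * rng
  outside <- abs(x - plateau) > band
  last_out <- if (any(outside)) max(which(outside)) else 0L
  if (last_out >= m) {
    warning("observable never settles into the plateau band")
    return(NA_real_)
  }
  tt[last_out + 1L]
}
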