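# Entropy functionals and entropy-production bookkeeping.
#
# All entropies are in units of k_B (default k_B = 1) and all rates in units
# of the intrinsic jump frequency. Conventions for zero probabilities:
# 0*log(0) = 0 in the Shannon entropy; summands of the Schnakenberg rates
# with p = 0 on either side are excluded (their current factor vanishes but
# the log diverges; exclusion is the standard limit convention).

#' Shannon entropy of a probability vector
#'
#' `S_sys = -k_B * sum(p * log(p))` with `0 * log(0) = 0`; bounded by
#' `[0, k_B log n]`.
#'
#' @param state probability vector or `probability_state`.
#' @param k_B Boltzmann constant (default 1, dimensionless units).
#' @return entropy in units of `k_B`.
#' @export
shannon_entropy <- function(state, k_B = 1) {
  p <- as_prob_vector(state)
  pos <- p > 0
  -k_B * sum(p[pos] * log(p[pos]))
}

#' Schnakenberg system-entropy rate
#'
#' `dS_sys/dt = (k_B/2) * sum_{x != xp} J[x,xp] * log(p[xp]/p[x])`, the exact
#' time derivative of the Shannon entropy along the master equation (the 1/2
#' prevents double counting of each current). Terms with `p = 0` on either
#' side are excluded.
#'
#' @param J current matrix computed from the same `p` (see
#'   [current_matrix()]).
#' @param state probability vector or `probability_state`.
#' @param k_B Boltzmann constant.
#' @return entropy rate in `k_B` per unit time.
#' @export
system_entropy_rate <- function(J, state, k_B = 1) {
  p <- as_prob_vector(state)
  if (length(p) != nrow(J)) stop("dimension mismatch between J and p")
  pos <- p > 0
  L <- numeric(length(p))
  L[pos] <- log(p[pos])
  M <- outer(-L, L, `+`)                # M[x, xp] = log p[xp] - log p[x]
  ok <- outer(pos, pos, `&`)
  (k_B / 2) * sum(J[ok] * M[ok])
}

#' Schnakenberg total entropy-production rate
#'
#' `dS_tot/dt = (k_B/2) * sum_{x != xp} J[x,xp] *
#' log( K[x,xp] p[xp] / (K[xp,x] p[x]) )`. Every summand has the form
#' `(a - b) log(a/b) >= 0`, so the total is non-negative and vanishes exactly
#' at detailed balance. If exactly one of the two conjugate flows on an edge
#' is zero the rate is `+Inf`; the offending edges are attached as the
#' `"infinite_edges"` attribute.
#'
#' @param K rate matrix.
#' @param state probability vector or `probability_state`.
#' @param k_B Boltzmann constant.
#' @param per_edge if `TRUE`, also attach the matrix of ordered-pair
#'   summands as attribute `"terms"` (each individually >= 0).
#' @return entropy-production rate (>= 0) in `k_B` per unit time.
#' @export
total_entropy_production <- function(K, state, k_B = 1, per_edge = FALSE) {
  p <- as_prob_vector(state)
  n <- nrow(K)
  if (length(p) != n) stop("dimension mismatch between K and p")
  A <- sweep(unclass(K), 2, p, "*")     # A[x, xp] = K[x,xp] p[xp], flow xp->x
  diag(A) <- 0
  B <- t(A)
  terms <- matrix(0, n, n)
  both <- A > 0 & B > 0
  terms[both] <- (A[both] - B[both]) * log(A[both] / B[both])
  one_sided <- xor(A > 0, B > 0)
  out <- (k_B / 2) * sum(terms)
  if (any(one_sided)) {
    out <- Inf
    attr(out, "infinite_edges") <- which(one_sided, arr.ind = TRUE)
  }
  if (per_edge) attr(out, "terms") <- (k_B / 2) * terms
  out
}

#' Reservoir (medium) entropy rate
#'
#' `dS_res/dt = (k_B/2) * sum J[x,xp] * log(K[x,xp]/K[xp,x])`: the entropy
#' delivered per unit time to the thermal reservoir. Satisfies the exact
#' decomposition `dS_tot = dS_sys + dS_res`.
#'
#' @inheritParams total_entropy_production
#' @return reservoir entropy rate in `k_B` per unit time.
#' @export
reservoir_entropy_rate <- function(K, state, k_B = 1) {
  p <- as_prob_vector(state)
  Ku <- unclass(K)
  diag(Ku) <- 0
  both <- Ku > 0 & t(Ku) > 0
  J <- current_matrix(K, p)
  R <- matrix(0, nrow(Ku), ncol(Ku))
  R[both] <- log(Ku[both] / t(Ku)[both])
  (k_B / 2) * sum(J[both] * R[both])
}

#' Heat released to the reservoir by a single jump
#'
#' For the jump `from -> to`, `Q = E_from - E_to + delta[to, from]`: the
#' energy drop plus any driving energy supplied to that directed edge is
#' dumped into the reservoir.
#'
#' @param landscape an [energy_landscape()].
#' @param field optional `driving_field` (default: no driving).
#' @param from,to state indices of an adjacent pair.
#' @return heat in energy units.
#' @export
heat_per_jump <- function(landscape, field = NULL, from, to) {
  stopifnot(inherits(landscape, "energy_landscape"))
  n <- landscape$n_states
  if (is.null(field)) field <- matrix(0, n, n)
  e <- topology_edges(n, landscape$topology)
  adjacent <- any((e[, "a"] == from & e[, "b"] == to) |
                  (e[, "a"] == to & e[, "b"] == from))
  if (!adjacent) stop("(", from, ", ", to, ") is not an edge of the topology")
  landscape$energies[from] - landscape$energies[to] + field[to, from]
}

#' Cumulative entropy bookkeeping along a trajectory
#'
#' Integrates the recorded total entropy-production rate by the trapezoid
#' rule into the cumulative produced entropy `S_int_cum` (non-decreasing,
#' since `dS_tot >= 0`) and closes the balance with the cumulative exchanged
#' entropy `S_exp_cum = S_sys(t) - S_sys(0) - S_int_cum` (Prigogine's
#' decomposition; `S_exp_cum` is typically negative for a dissipating,
#' exporting system). The reservoir-rate series `dS_res` is kept alongside so
#' `S_exp_cum` can be cross-checked against `-integral(dS_res)`.
#'
#' @param trajectory a `trajectory` with at least 2 records.
#' @return data frame with columns
#'   `t, S_sys, dS_sys, dS_tot, dS_res, S_int_cum, S_exp_cum`.
#' @export
accumulate_thermo <- function(trajectory) {
  th <- trajectory$thermo
  if (nrow(th) < 2) stop("need at least 2 records")
  S_int_cum <- as.vector(pracma::cumtrapz(th$t, th$dS_tot))
  th$S_int_cum <- S_int_cum
  th$S_exp_cum <- th$S_sys - th$S_sys[1] - S_int_cum
  th
}

#' Glansdorff-Prigogine stability diagnostic
#'
#' Second time derivative of the cumulative produced entropy, i.e. the first
#' derivative of the entropy-production rate `dS_tot`, estimated by central
#' finite differences of a moving-average-smoothed series on a uniform time
#' grid. The stability criterion for a driven system relaxing toward its
#' steady state is that this quantity be non-positive (the production rate
#' monotonically relaxes); the fraction of interior points with value
#' `<= +tol` is reported, not asserted, since protocol discontinuities
#' violate it transiently.
#'
#' @param records thermo data frame (from [accumulate_thermo()] or a
#'   trajectory's `$thermo`) with uniformly spaced `t`.
#' @param smooth_window moving-average window in points (default 5; 1
#'   disables smoothing).
#' @param tol non-positivity slack in `k_B` per squared time unit.
#' @return list with `t`, `d2S_int` (NA at the ends), and `fraction`.
#' @export
gp_diagnostic <- function(records, smooth_window = 5L, tol = 1e-9) {
  tt <- records$t
  if (length(tt) < 5) stop("need at least 5 records")
  h <- diff(tt)
  if (max(abs(h - h[1])) > 1e-8 * max(h))
    stop("records must be uniformly spaced in time")
  h <- h[1]
  x <- records$dS_tot
  w <- as.integer(smooth_window)
  if (w > 1) x <- as.vector(stats::filter(x, rep(1 / w, w), sides = 2))
  m <- length(x)
  d <- rep(NA_real_, m)
  d[2:(m - 1)] <- (x[3:m] - x[1:(m - 2)]) / (2 * h)
  ok <- !is.na(d)
  list(t = tt, d2S_int = d, fraction = mean(d[ok] <= tol))
}
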