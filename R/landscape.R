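# Energy landscapes and the effective jump-rate matrices they induce.
#
# Index convention (fixed throughout the package): K[x, xp] is the effective
# rate of jumping FROM state xp TO state x, so the master equation reads
# dp/dt = K %*% p and every column of K sums to zero.

#' Undirected edge list of a chain or ring topology
#'
#' States are numbered `1..n`. A chain has edges `(1,2), ..., (n-1,n)`; a ring
#' additionally closes the loop with the edge `(n,1)`. Each row is one
#' undirected pair; the first column (`a`) is the lower-index ("downstream")
#' state of the pair, except for the ring's wrap edge where `a = n`, `b = 1`.
#'
#' The *forward* directed edge of a pair is `b -> a` (toward decreasing state
#' index, wrapping `1 -> n` on a ring), i.e. the direction in which the main
#' driving force acts; *backward* is `a -> b`.
#'
#' @param n_states number of states (>= 2).
#' @param topology `"chain"` or `"ring"`.
#' @return integer matrix with columns `a`, `b`, one row per undirected edge.
#' @export
topology_edges <- function(n_states, topology = c("chain", "ring")) {
  topology <- match.arg(topology)
  stopifnot(n_states >= 2)
  e <- cbind(a = seq_len(n_states - 1L), b = seq.int(2L, n_states))
  if (topology == "ring") {
    if (n_states < 3) stop("a ring needs at least 3 states")
    e <- rbind(e, c(a = n_states, b = 1L))
  }
  e
}

# linear indices into an n x n matrix of the forward (b -> a, i.e. K[a, b])
# and backward (a -> b, i.e. K[b, a]) directed edges
edge_indices <- function(n_states, topology) {
  e <- topology_edges(n_states, topology)
  list(
    pairs   = e,
    forward = (e[, "b"] - 1L) * n_states + e[, "a"],  # K[a, b]
    backward = (e[, "a"] - 1L) * n_states + e[, "b"]  # K[b, a]
  )
}

#' Construct an energy landscape
#'
#' A one-dimensional arrangement of potential wells with energies `E_x`,
#' separated by barriers `E_B` (one per undirected edge, shared by both jump
#' directions). Energies are in units of `1/beta` (k_B T at `beta = 1`);
#' `omega` is the intrinsic attempt frequency setting the time unit.
#'
#' @param n_states number of wells (>= 2).
#' @param energies numeric vector of well energies, length `n_states`.
#' @param barriers numeric vector of barrier heights, one per edge
#'   (`n_states - 1` for a chain, `n_states` for a ring); each barrier must be
#'   at least the larger of the two adjacent well energies.
#' @param beta inverse temperature (> 0), default 1 (dimensionless units).
#' @param omega intrinsic jump frequency (> 0), default 1.
#' @param topology `"chain"` or `"ring"`.
#' @return an object of class `energy_landscape`.
#' @export
energy_landscape <- function(n_states, energies, barriers, beta = 1, omega = 1,
                             topology = c("chain", "ring")) {
  topology <- match.arg(topology)
  n_states <- as.integer(n_states)
  if (n_states < 2) stop("n_states must be >= 2")
  if (length(energies) != n_states) stop("energies must have length n_states")
  edges <- topology_edges(n_states, topology)
  if (length(barriers) != nrow(edges))
    stop(sprintf("barriers must have one value per edge (%d for this topology)",
                 nrow(edges)))
  if (!(beta > 0)) stop("beta must be > 0")
  if (!(omega > 0)) stop("omega must be > 0")
  lo <- pmax(energies[edges[, "a"]], energies[edges[, "b"]])
  if (any(barriers < lo - 1e-12))
    stop("every barrier must be at least the larger adjacent well energy")
  structure(
    list(n_states = n_states, energies = as.numeric(energies),
         barriers = as.numeric(barriers), beta = beta, omega = omega,
         topology = topology),
    class = "energy_landscape"
  )
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("Energy landscape: %d wells (%s), beta = %g, omega = %g\n",
              x$n_states, x$topology, x$beta, x$omega))
  cat(sprintf("  well energies in [%.3g, %.3g], barriers in [%.3g, %.3g]\n",
              min(x$energies), max(x$energies),
              min(x$barriers), max(x$barriers)))
  invisible(x)
}

#' Validate a per-directed-edge driving field
#'
#' The driving field `delta[x, xp]` is the extra energy supplied to the jump
#' `xp -> x` by external driving. It must be non-negative and zero wherever
#' the topology has no edge (and on the diagonal).
#'
#' @param delta n x n numeric matrix of driving energies.
#' @param topology `"chain"` or `"ring"`.
#' @return `delta`, invisibly classed `driving_field`.
#' @export
driving_field <- function(delta, topology = c("chain", "ring")) {
  topology <- match.arg(topology)
  n <- nrow(delta)
  if (ncol(delta) != n) stop("delta must be square")
  if (any(delta < 0)) stop("driving energies must be >= 0")
  idx <- edge_indices(n, topology)
  allowed <- matrix(FALSE, n, n)
  allowed[idx$forward] <- TRUE
  allowed[idx$backward] <- TRUE
  if (any(delta[!allowed] != 0))
    stop("delta must be zero on non-edges and on the diagonal")
  structure(delta, class = c("driving_field", "matrix"))
}

#' Uniform driving field on all forward or backward edges
#'
#' @param n_states number of states.
#' @param amplitude driving energy placed on every edge of the chosen
#'   direction.
#' @param topology `"chain"` or `"ring"`.
#' @param direction `"forward"` (toward decreasing state index, the main-drive
#'   direction) or `"backward"` (the stressor direction).
#' @return a `driving_field` matrix.
#' @export
uniform_driving_field <- function(n_states, amplitude,
                                  topology = c("chain", "ring"),
                                  direction = c("forward", "backward")) {
  topology <- match.arg(topology)
  direction <- match.arg(direction)
  if (amplitude < 0) stop("amplitude must be >= 0")
  idx <- edge_indices(n_states, topology)
  d <- matrix(0, n_states, n_states)
  d[if (direction == "forward") idx$forward else idx$backward] <- amplitude
  driving_field(d, topology)
}

new_rate_matrix <- function(K, topology) {
  diag(K) <- 0
  diag(K) <- -colSums(K)
  structure(K, class = c("rate_matrix", "matrix"), topology = topology)
}

#' Validate a rate-matrix (generator) object
#'
#' Checks the generator invariants: non-negative off-diagonal entries and
#' zero column sums (probability conservation).
#'
#' @param K matrix to check.
#' @param tol numeric tolerance on the column sums.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_rate_matrix <- function(K, tol = 1e-12) {
  n <- nrow(K)
  off <- K; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  if (any(abs(colSums(K)) > tol * max(1, max(abs(K)))))
    stop("columns of a generator must sum to zero")
  invisible(TRUE)
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("Rate matrix (generator), %d states, topology: %s\n",
              nrow(x), attr(x, "topology") %||% "unknown"))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))], ...)
  if (nrow(x) > 6) cat(sprintf("  ... (%d x %d)\n", nrow(x), ncol(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Arrhenius jump rates from an energy landscape
#'
#' For each directed edge `xp -> x` across barrier `E_B`, the effective rate
#' is `(omega/2) * exp(beta * (E_xp - E_B + delta[x, xp]))` -- the Arrhenius
#' law with activation energy `E_B - E_xp`, lowered by any driving energy
#' `delta` supplied to that direction. Without driving the rates satisfy
#' detailed balance, `k(xp->x)/k(x->xp) = exp(beta * (E_xp - E_x))`.
#'
#' @param landscape an [energy_landscape()].
#' @param field optional `driving_field` matrix (default: no driving).
#' @return a `rate_matrix` (class keeps the topology as an attribute).
#' @export
build_rates <- function(landscape, field = NULL) {
  stopifnot(inherits(landscape, "energy_landscape"))
  n <- landscape$n_states
  if (is.null(field)) field <- matrix(0, n, n)
  if (nrow(field) != n || ncol(field) != n)
    stop("driving field dimensions do not match the landscape")
  field <- driving_field(unclass(field), landscape$topology)
  idx <- edge_indices(n, landscape$topology)
  e <- idx$pairs
  K <- matrix(0, n, n)
  E <- landscape$energies; EB <- landscape$barriers
  w2 <- landscape$omega / 2; b <- landscape$beta
  # forward edge b -> a lives at K[a, b]; its departure energy is E[b]
  K[idx$forward]  <- w2 * exp(b * (E[e[, "b"]] - EB + field[idx$forward]))
  K[idx$backward] <- w2 * exp(b * (E[e[, "a"]] - EB + field[idx$backward]))
  new_rate_matrix(K, landscape$topology)
}

#' Sample undriven base rates uniformly
#'
#' Draws every directed-edge base rate independently from
#' `U[low, high]` (the bathtub simulations use `[0.01, 0.02]`) and completes
#' the diagonal so columns sum to zero. Reproducible for a given seed; the
#' global RNG state is left untouched.
#'
#' @param n_states number of states (>= 2).
#' @param low,high bounds of the uniform rate distribution, `0 < low <= high`.
#' @param topology `"chain"` or `"ring"`.
#' @param seed integer seed (mandatory).
#' @return a `rate_matrix`.
#' @export
sample_base_rates <- function(n_states, low = 0.01, high = 0.02,
                              topology = c("chain", "ring"), seed) {
  topology <- match.arg(topology)
  if (missing(seed)) stop("a seed is required for reproducibility")
  if (!(low > 0 && high >= low)) stop("need 0 < low <= high")
  if (n_states < 2) stop("n_states must be >= 2")
  idx <- edge_indices(n_states, topology)
  m <- length(idx$forward)
  r <- withr::with_seed(as.integer(seed), stats::runif(2L * m, low, high))
  K <- matrix(0, n_states, n_states)
  K[idx$forward] <- r[seq_len(m)]
  K[idx$backward] <- r[m + seq_len(m)]
  new_rate_matrix(K, topology)
}

#' Apply a driving field multiplicatively to base rates
#'
#' Each off-diagonal rate is multiplied by `exp(beta * delta)` for that
#' directed edge (the driven Arrhenius form factorizes as
#' base rate x `exp(beta*delta)`); the diagonal is recomputed. A zero field
#' returns the base rates unchanged.
#'
#' @param base a `rate_matrix` of undriven rates.
#' @param field `driving_field` matrix (or plain matrix of per-edge energies).
#' @param beta inverse temperature.
#' @return a driven `rate_matrix`.
#' @export
apply_drive_to_base <- function(base, field, beta = 1) {
  n <- nrow(base)
  if (nrow(field) != n || ncol(field) != n)
    stop("field dimensions do not match the rate matrix")
  K <- unclass(base)
  diag(K) <- 0
  K <- K * exp(beta * unclass(field))
  new_rate_matrix(K, attr(base, "topology"))
}

#' Rates from symmetric/antisymmetric edge parameters
#'
#' Parameterizes each directed-edge rate as `exp(B + S/2)` where `B` is
#' symmetric (barrier part) and `S` antisymmetric (thermodynamic-force part),
#' so that the log-ratio of conjugate rates is exactly `S[x, xp]`.
#'
#' @param B symmetric numeric matrix (edge structure taken from the nonzero
#'   off-diagonal pattern of `|B| + |S|`).
#' @param S antisymmetric numeric matrix.
#' @param tol tolerance for the symmetry checks.
#' @return a `rate_matrix` with topology attribute `"custom"`.
#' @export
rates_from_BS <- function(B, S, tol = 1e-8) {
  n <- nrow(B)
  if (ncol(B) != n || nrow(S) != n || ncol(S) != n)
    stop("B and S must be square matrices of the same size")
  if (max(abs(B - t(B))) > tol) stop("B must be symmetric")
  if (max(abs(S + t(S))) > tol) stop("S must be antisymmetric")
  on_edge <- (abs(B) + abs(S) + t(abs(B) + abs(S))) > 0
  diag(on_edge) <- FALSE
  K <- matrix(0, n, n)
  K[on_edge] <- exp(B[on_edge] + S[on_edge] / 2)
  new_rate_matrix(K, "custom")
}
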