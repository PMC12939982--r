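# Synthetic test fixtures with independently computed reference values.
#
# The oracle routines here deliberately use naive nested loops and closed
# forms, sharing no code with the vectorized main paths they are used to
# check. Reference values are recomputed at construction time, never stored
# stale.

#' Two-state fixture with closed-form references
#'
#' Bundles a two-state generator, its closed-form relaxation
#' `p1(t) = p1_eq + (p1(0) - p1_eq) exp(-(k12 + k21) t)` with
#' `p_eq = (k12, k21)/(k12 + k21)`, and hand-evaluated entropy rates at the
#' supplied distribution. With symmetric unit rates and `p0 = (0.75, 0.25)`
#' the system and total entropy rates both equal `0.5 * log(3)` and the
#' reservoir rate is zero.
#'
#' @param k12 rate of the jump `2 -> 1` into state 1.
#' @param k21 rate of the jump `1 -> 2` into state 2.
#' @param p0 initial probability vector of length 2.
#' @return a `fixture_case` list with elements `K`, `p0`, `expected`
#'   (each value tagged with its provenance), and `p1_of_t` (the closed-form
#'   relaxation function).
#' @export
two_state_fixture <- function(k12 = 1, k21 = 1, p0 = c(0.75, 0.25)) {
  if (!(k12 > 0 && k21 > 0)) stop("rates must be > 0")
  K <- new_rate_matrix(matrix(c(0, k21, k12, 0), 2, 2), "chain")
  p0 <- p0 / sum(p0)
  p_eq <- c(k12, k21) / (k12 + k21)
  # hand evaluation of the two-term sums (no shared code with thermo module)
  J12 <- k12 * p0[2] - k21 * p0[1]          # current into state 1
  dS_sys <- J12 * log(p0[2] / p0[1])
  dS_tot <- J12 * log((k12 * p0[2]) / (k21 * p0[1]))
  dS_res <- J12 * log(k12 / k21)
  expected <- list(
    p_eq = list(value = p_eq, provenance = "closed-form"),
    db_ratio = list(value = k12 / k21, provenance = "closed-form"),
    dS_sys = list(value = dS_sys, provenance = "closed-form"),
    dS_tot = list(value = dS_tot, provenance = "closed-form"),
    dS_res = list(value = dS_res, provenance = "closed-form"),
    rate_sum = list(value = k12 + k21, provenance = "closed-form")
  )
  p1_of_t <- function(t) p_eq[1] + (p0[1] - p_eq[1]) * exp(-(k12 + k21) * t)
  structure(list(name = "two_state", K = K, p0 = probability_state(p0),
                 expected = expected, p1_of_t = p1_of_t),
            class = "fixture_case")
}

#' Uniformly driven ring fixture (strict-NESS witness)
#'
#' A ring of `n` states with every forward rate (increasing-index
#' orientation) equal to `base_rate * exp(beta * delta)` and every backward
#' rate equal to `base_rate`. By symmetry the stationary distribution is
#' uniform, the circulating current per edge is
#' `(base_rate/n) (exp(beta*delta) - 1)`, and the Kolmogorov cycle ratio is
#' `exp(n * beta * delta)`. The stationary entropy-production rate is stored
#' as a brute-force sum, not a transcribed formula.
#'
#' @param n number of states (>= 3).
#' @param base_rate undriven rate per directed edge.
#' @param delta driving energy per forward edge.
#' @param beta inverse temperature.
#' @return a `fixture_case` with expected `p_st`, `edge_current`,
#'   `cycle_ratio`, and `dS_tot_stationary`.
#' @export
driven_ring_fixture <- function(n, base_rate = 0.01, delta = 1, beta = 1) {
  if (n < 3) stop("a ring needs n >= 3")
  kf <- base_rate * exp(beta * delta)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L    # forward jump i -> j (increasing)
    K[j, i] <- kf
    K[i, j] <- base_rate
  }
  K <- new_rate_matrix(K, "ring")
  p_st <- rep(1 / n, n)
  current <- (base_rate / n) * (exp(beta * delta) - 1)
  ratio <- prod(rep(kf, n)) / prod(rep(base_rate, n))  # brute-force product
  # brute-force stationary entropy production: loop over ordered pairs
  dS_tot <- 0
  for (x in seq_len(n)) for (xp in seq_len(n)) {
    if (x == xp || K[x, xp] == 0) next
    a <- K[x, xp] * p_st[xp]; b <- K[xp, x] * p_st[x]
    dS_tot <- dS_tot + 0.5 * (a - b) * log(a / b)
  }
  expected <- list(
    p_st = list(value = p_st, provenance = "construction"),
    edge_current = list(value = current, provenance = "construction"),
    cycle_ratio = list(value = ratio, provenance = "brute-force"),
    dS_tot_stationary = list(value = dS_tot, provenance = "brute-force")
  )
  structure(list(name = "driven_ring", K = K,
                 p0 = probability_state(rep(1 / n, n)),
                 expected = expected),
            class = "fixture_case")
}

#' Brute-force oracle for small systems
#'
#' Computes probability currents, all three entropy rates, and the
#' stationary distribution of a small generator by naive nested loops and an
#' SVD null-space solve -- an implementation independent of the vectorized
#' main paths, for cross-checking.
#'
#' @param K rate matrix with `n <= 10`.
#' @param state probability vector or `probability_state`.
#' @return list `J`, `dS_sys`, `dS_tot`, `dS_res`, `p_st`.
#' @export
brute_force_oracle <- function(K, state) {
  n <- nrow(K)
  if (n > 10) stop("oracle is restricted to n <= 10")
  p <- as_prob_vector(state)
  Ku <- unclass(K)
  J <- matrix(0, n, n)
  dS_sys <- 0; dS_tot <- 0; dS_res <- 0
  for (x in seq_len(n)) for (xp in seq_len(n)) {
    if (x == xp) next
    J[x, xp] <- Ku[x, xp] * p[xp] - Ku[xp, x] * p[x]
    if (p[x] > 0 && p[xp] > 0)
      dS_sys <- dS_sys + 0.5 * J[x, xp] * log(p[xp] / p[x])
    a <- Ku[x, xp] * p[xp]; b <- Ku[xp, x] * p[x]
    if (a > 0 && b > 0)
      dS_tot <- dS_tot + 0.5 * (a - b) * log(a / b)
    else if (xor(a > 0, b > 0)) dS_tot <- Inf
    if (Ku[x, xp] > 0 && Ku[xp, x] > 0)
      dS_res <- dS_res + 0.5 * J[x, xp] * log(Ku[x, xp] / Ku[xp, x])
  }
  s <- svd(Ku)
  v <- s$v[, n]
  if (s$d[n - 1] < 1e-10 * s$d[1])
    stop("degenerate null space: stationary state not unique")
  p_st <- abs(v) / sum(abs(v))
  list(J = J, dS_sys = dS_sys, dS_tot = dS_tot, dS_res = dS_res, p_st = p_st)
}

#' Naive Euler reference trajectory
#'
#' Scalar-loop Euler integration of the master equation (no matrix
#' products), as an ultra-plain reference for the main integrator.
#'
#' @param K rate matrix (`n <= 10`).
#' @param p0 initial probability vector.
#' @param t_end,dt integration horizon and step.
#' @return final probability vector.
#' @export
oracle_propagate <- function(K, p0, t_end, dt) {
  n <- nrow(K)
  if (n > 10) stop("oracle is restricted to n <= 10")
  Ku <- unclass(K)
  p <- as_prob_vector(p0)
  for (step in seq_len(round(t_end / dt))) {
    dp <- numeric(n)
    for (x in seq_len(n)) {
      acc <- 0
      for (xp in seq_len(n)) acc <- acc + Ku[x, xp] * p[xp]
      dp[x] <- acc
    }
    p <- p + dt * dp
    p[p < 0] <- 0
    p <- p / sum(p)
  }
  p
}

#' Random small Markov system for property tests
#'
#' Dense generator with rates drawn log-uniformly from `[1e-3, 1]` on every
#' ordered pair, plus a probability vector from a symmetric Dirichlet
#' (normalized exponentials). Reproducible for a given seed.
#'
#' @param n number of states.
#' @param seed integer seed.
#' @param topology `"dense"` (all-to-all), `"chain"`, or `"ring"`.
#' @return list `K` (rate matrix), `p` (probability vector).
#' @export
random_markov_system <- function(n, seed, topology = "dense") {
  withr::with_seed(as.integer(seed), {
    if (topology == "dense") {
      K <- matrix(exp(stats::runif(n * n, log(1e-3), log(1))), n, n)
      K <- new_rate_matrix(K, "custom")
    } else {
      idx <- edge_indices(n, topology)
      K <- matrix(0, n, n)
      K[idx$forward] <- exp(stats::runif(length(idx$forward),
                                         log(1e-3), log(1)))
      K[idx$backward] <- exp(stats::runif(length(idx$backward),
                                          log(1e-3), log(1)))
      K <- new_rate_matrix(K, topology)
    }
    g <- stats::rexp(n)
    list(K = K, p = g / sum(g))
  })
}

#' Export a fixture as a JSON bundle
#'
#' @param fixture a `fixture_case`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fixture_json <- function(fixture, path) {
  x <- list(name = fixture$name, K = unclass(fixture$K),
            p0 = fixture$p0$p,
            expected = lapply(fixture$expected, function(e)
              list(value = e$value, provenance = e$provenance)))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
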