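# Seeded random test systems and small utilities shared across test files.

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# chain landscape with random well energies in [0,1] and barriers at least
# one unit above the higher adjacent well (rates then lie in ~[0.2, 0.4]
# for omega = 2, fast enough to equilibrate in a short test run)
random_chain_landscape <- function(n, seed, beta = 1, omega = 2) {
  withr::with_seed(seed, {
    E <- stats::runif(n)
    e <- topology_edges(n, "chain")
    EB <- pmax(E[e[, 1]], E[e[, 2]]) + 1 + stats::runif(nrow(e), 0, 0.5)
    energy_landscape(n, E, EB, beta = beta, omega = omega, topology = "chain")
  })
}

random_ring_landscape <- function(n, seed, beta = 1, omega = 2) {
  withr::with_seed(seed, {
    E <- stats::runif(n)
    e <- topology_edges(n, "ring")
    EB <- pmax(E[e[, 1]], E[e[, 2]]) + 1 + stats::runif(nrow(e), 0, 0.5)
    energy_landscape(n, E, EB, beta = beta, omega = omega, topology = "ring")
  })
}

boltzmann <- function(landscape) {
  w <- exp(-landscape$beta * landscape$energies)
  w / sum(w)
}

# relative entropy D(p || q), the H-theorem Lyapunov function
rel_entropy <- function(p, q) {
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}
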