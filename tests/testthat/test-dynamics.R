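# Master-equation propagation, currents, stationary states, cycle ratios.

test_that("probability currents match hand evaluation and are exactly antisymmetric", {
  K <- two_state_fixture(1, 1)$K
  expect_equal(current_matrix(K, c(0.5, 0.5)), matrix(0, 2, 2))
  J <- current_matrix(K, c(0.75, 0.25))
  expect_equal(J[1, 2], -0.5)            # net flow out of state 1
  expect_identical(J, -t(J))

  sys <- random_markov_system(6, 21)
  J <- current_matrix(sys$K, sys$p)
  expect_identical(J, -t(J))
  expect_equal(rowSums(J), as.vector(unclass(sys$K) %*% sys$p))
})

test_that("stationary states of chains carry no currents", {
  base <- sample_base_rates(8, seed = 5)
  f <- uniform_driving_field(8, 1, "chain", "forward")
  Kd <- apply_drive_to_base(base, f)
  p_st <- stationary_distribution(Kd)
  expect_lt(max(abs(current_matrix(Kd, p_st))), 1e-12)
  expect_lt(detailed_balance_residual(Kd, p_st), 1e-10)
})

test_that("Euler steps conserve probability and respect the stability guard", {
  st <- probability_state(c(0.2, 0.3, 0.5))
  Kzero <- entropybathtub:::new_rate_matrix(matrix(0, 3, 3), "chain")
  expect_equal(euler_step(st, Kzero, 0.05)$p, st$p)

  sys <- random_markov_system(5, 31)
  st <- probability_state(sys$p)
  expect_error(euler_step(st, sys$K, dt = 10), "stability guard")
  s2 <- euler_step(st, sys$K, dt = 0.01)
  expect_lt(abs(sum(s2$p) - 1), 1e-12)
  expect_gte(min(s2$p), 0)
  expect_equal(s2$t, 0.01)

  # uniform distribution is a fixed point of a doubly-symmetric generator
  Ksym <- rates_from_BS(matrix(c(0, 1, 1, 0), 2, 2), matrix(0, 2, 2))
  su <- euler_step(probability_state(c(0.5, 0.5)), Ksym, 0.01)
  expect_equal(su$p, c(0.5, 0.5))
})

test_that("Euler propagation converges to the two-state closed form at first order", {
  fx <- two_state_fixture(k12 = 1, k21 = 2, p0 = c(0.9, 0.1))
  errs <- vapply(c(0.05, 0.025, 0.0125), function(dt) {
    tr <- propagate(fx$p0, fx$K, t_end = 2, dt = dt, record_every = 1L)
    max(abs(tr$p[, 1] - fx$p1_of_t(tr$time)))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 1.7)
  expect_lt(errs[1] / errs[2], 2.4)
  expect_gt(errs[2] / errs[3], 1.7)
  expect_lt(errs[2] / errs[3], 2.4)
})

test_that("Euler, matrix-exponential, and naive-loop propagators agree", {
  base <- sample_base_rates(6, seed = 8)
  f <- uniform_driving_field(6, 0.5, "chain", "forward")
  K <- apply_drive_to_base(base, f)
  p0 <- probability_state(rep(1 / 6, 6))
  tr <- propagate(p0, K, t_end = 50, dt = 0.05, record_every = 1000L)
  pf <- tr$p[nrow(tr$p), ]
  expect_lt(tv_dist(pf, propagate_exact(p0, K, 50)), 1e-3)
  expect_lt(tv_dist(pf, oracle_propagate(K, p0, 50, 0.05)), 1e-12)
})

test_that("undriven propagation relaxes to the stationary distribution", {
  lnd <- random_chain_landscape(8, 13)
  K <- build_rates(lnd)
  p0 <- probability_state(withr::with_seed(14, {
    x <- stats::runif(8); x / sum(x)
  }))
  tr <- propagate(p0, K, t_end = 4000, dt = 0.1, record_every = 500L)
  p_st <- stationary_distribution(K)
  expect_lt(tv_dist(tr$p[nrow(tr$p), ], p_st), 1e-6)
  expect_lt(tv_dist(p_st, boltzmann(lnd)), 1e-12)
  # probability conserved at every record
  expect_lt(max(abs(rowSums(tr$p) - 1)), 1e-12)
  expect_gte(min(tr$p), 0)
  # Boltzmann start stays put
  trB <- propagate(probability_state(boltzmann(lnd)), K, t_end = 50,
                   dt = 0.1, record_every = 50L)
  expect_lt(max(abs(sweep(trB$p, 2, boltzmann(lnd)))), 1e-12)
})

test_that("relative entropy to the stationary state never increases (H-theorem)", {
  base <- sample_base_rates(10, seed = 17)
  f <- uniform_driving_field(10, 1, "chain", "forward")
  K <- apply_drive_to_base(base, f)
  p_st <- stationary_distribution(K)
  p0 <- probability_state(withr::with_seed(18, {
    x <- stats::runif(10); x / sum(x)
  }))
  tr <- propagate(p0, K, t_end = 2000, dt = 0.5, record_every = 10L)
  D <- apply(tr$p, 1, rel_entropy, q = p_st)
  expect_true(all(diff(D) <= 1e-12))
})

test_that("stationary solve matches closed forms and the null-space oracle", {
  fx <- two_state_fixture(k12 = 2, k21 = 1)
  expect_equal(stationary_distribution(fx$K), c(2 / 3, 1 / 3))
  # general two-state: p2/p1 = k21/k12
  fx2 <- two_state_fixture(k12 = 0.3, k21 = 0.8)
  p <- stationary_distribution(fx2$K)
  expect_equal(p[2] / p[1], 0.8 / 0.3)

  rf <- driven_ring_fixture(3, 0.01, 1)
  p_st <- stationary_distribution(rf$K)
  expect_lt(max(abs(p_st - brute_force_oracle(rf$K, rf$p0)$p_st)), 1e-10)

  Kdisc <- entropybathtub:::new_rate_matrix(
    matrix(c(0, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 1, 0, 0, 1, 0), 4, 4), "custom")
  expect_error(stationary_distribution(Kdisc), "disconnected")
})

test_that("detailed balance holds at equilibrium but not on a driven ring", {
  lnd <- random_chain_landscape(6, 23)
  K <- build_rates(lnd)
  expect_lt(detailed_balance_residual(K, boltzmann(lnd)), 1e-10)
  rf <- driven_ring_fixture(5, 0.01, 1)
  expect_gt(detailed_balance_residual(rf$K, stationary_distribution(rf$K)),
            1e-4)
})

test_that("Kolmogorov cycle ratios: trees have none, equilibrium rings telescope to 1, driven rings to exp(n beta delta)", {
  expect_length(kolmogorov_cycle_ratios(sample_base_rates(6, seed = 2)), 0)
  lnd <- random_ring_landscape(6, 29)
  cr <- kolmogorov_cycle_ratios(build_rates(lnd))
  expect_length(cr, 1)
  expect_equal(cr[[1]]$ratio, 1)
  rf <- driven_ring_fixture(4, 0.015, 0.8, beta = 1.2)
  expect_equal(kolmogorov_cycle_ratios(rf$K)[[1]]$ratio, exp(4 * 1.2 * 0.8),
               tolerance = 1e-12)
})

test_that("relaxation time recovers the two-state rate constant at the 1/e convention", {
  fx <- two_state_fixture(k12 = 0.4, k21 = 0.6)
  tr <- propagate(probability_state(c(0.999, 0.001)), fx$K, t_end = 30,
                  dt = 0.02, record_every = 1L)
  tau <- relaxation_time(tr, "total_variation", tol = exp(-1))
  expect_equal(tau, 1 / (0.4 + 0.6), tolerance = 0.2)
  # constant trajectory: relaxation time is the first record
  trB <- propagate(probability_state(stationary_distribution(fx$K)), fx$K,
                   t_end = 5, dt = 0.02, record_every = 5L)
  expect_equal(relaxation_time(trB, "entropy"), 0)
})
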