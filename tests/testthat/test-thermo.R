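# Entropy functionals, entropy-production bookkeeping, GP diagnostic.

test_that("Shannon entropy matches closed forms and respects its bounds", {
  expect_equal(shannon_entropy(rep(1 / 30, 30)), log(30))
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  expect_equal(shannon_entropy(c(0.5, 0.5), k_B = 1.38), 1.38 * log(2))
  for (seed in 1:20) {
    p <- random_markov_system(7, seed)$p
    S <- shannon_entropy(p)
    expect_gte(S, 0)
    expect_lte(S, log(7) + 1e-12)
  }
})

test_that("Schnakenberg system-entropy rate reproduces the hand-evaluated two-state value", {
  fx <- two_state_fixture()
  J <- current_matrix(fx$K, fx$p0)
  expect_equal(system_entropy_rate(J, fx$p0), 0.5 * log(3))
  # stationary chain: all currents vanish, rate is zero
  base <- sample_base_rates(6, seed = 41)
  p_st <- stationary_distribution(base)
  expect_equal(system_entropy_rate(current_matrix(base, p_st), p_st), 0,
               tolerance = 1e-12)
})

test_that("the Schnakenberg rate is the time derivative of Shannon entropy (first-order FD check)", {
  for (seed in 1:20) {
    sys <- random_markov_system(6, seed + 400)
    st <- probability_state(sys$p)
    rate <- system_entropy_rate(current_matrix(sys$K, st), st)
    fd_err <- function(dt) {
      s2 <- euler_step(st, sys$K, dt)
      abs((shannon_entropy(s2) - shannon_entropy(st)) / dt - rate)
    }
    e1 <- fd_err(0.01); e2 <- fd_err(0.005)
    expect_lt(e2, e1)                    # error shrinks with dt
    expect_gt(e1 / e2, 1.5)              # at first order
    expect_lt(e1 / e2, 3.0)
  }
})

test_that("total entropy production is non-negative with non-negative per-edge terms and vanishes at equilibrium", {
  lnd <- random_chain_landscape(7, 43)
  K <- build_rates(lnd)
  expect_lt(total_entropy_production(K, boltzmann(lnd)), 1e-12)

  fx <- two_state_fixture()
  expect_equal(total_entropy_production(fx$K, fx$p0), 0.5 * log(3))
  expect_equal(reservoir_entropy_rate(fx$K, fx$p0), 0)

  for (seed in 1:50) {
    sys <- random_markov_system(5, seed + 600)
    tot <- total_entropy_production(sys$K, sys$p, per_edge = TRUE)
    expect_gte(tot, 0)
    expect_true(all(attr(tot, "terms") >= 0))
    # term-by-term against an explicit loop
    o <- brute_force_oracle(sys$K, sys$p)
    expect_equal(as.numeric(tot), o$dS_tot, tolerance = 1e-12)
  }
})

test_that("one-sided zero flux is flagged as infinite with the offending edge", {
  # the jump 1 -> 2 exists but its reverse does not
  K <- entropybathtub:::new_rate_matrix(
    matrix(c(0, 0.5, 0, 0), 2, 2), "custom")
  out <- total_entropy_production(K, c(0.5, 0.5))
  expect_identical(as.numeric(out), Inf)
  expect_false(is.null(attr(out, "infinite_edges")))
})

test_that("total = system + reservoir to near machine precision", {
  for (seed in 1:50) {
    sys <- random_markov_system(6, seed + 800)
    tot <- total_entropy_production(sys$K, sys$p)
    s <- system_entropy_rate(current_matrix(sys$K, sys$p), sys$p)
    r <- reservoir_entropy_rate(sys$K, sys$p)
    expect_lt(abs(tot - s - r), 1e-12 * max(1, abs(tot)))
  }
  # at a driven chain's stationary state all three vanish together
  base <- sample_base_rates(8, seed = 45)
  Kd <- apply_drive_to_base(base, uniform_driving_field(8, 1, "chain"))
  p_st <- stationary_distribution(Kd)
  expect_lt(abs(total_entropy_production(Kd, p_st)), 1e-10)
  expect_lt(abs(system_entropy_rate(current_matrix(Kd, p_st), p_st)), 1e-10)
  expect_lt(abs(reservoir_entropy_rate(Kd, p_st)), 1e-10)
})

test_that("heat per jump is the energy drop plus the driving energy", {
  lnd <- energy_landscape(2, energies = c(0, 1), barriers = 1.5,
                          beta = 1, omega = 1)
  expect_equal(heat_per_jump(lnd, NULL, from = 2, to = 1), 1)
  expect_equal(heat_per_jump(lnd, NULL, from = 1, to = 2), -1)
  lnd0 <- energy_landscape(2, c(0.3, 0.3), 1.5)
  expect_equal(heat_per_jump(lnd0, NULL, 1, 2), 0)
  d <- matrix(0, 2, 2); d[1, 2] <- 0.5    # drive on the jump 2 -> 1
  expect_equal(heat_per_jump(lnd, driving_field(d, "chain"), 2, 1), 1.5)
  lnd3 <- energy_landscape(3, c(0, 0, 0), c(1, 1))
  expect_error(heat_per_jump(lnd3, NULL, 1, 3), "not an edge")
})

test_that("cumulative bookkeeping closes the Prigogine balance and cross-checks by dual integration", {
  base <- sample_base_rates(8, seed = 47)
  prot <- protocol_rectangular(1, t_on = 50, t_off = 900)
  p0 <- probability_state(withr::with_seed(48, {
    x <- stats::runif(8); x / sum(x)
  }))
  tr <- propagate(p0, base, prot, t_end = 1500, dt = 0.5, record_every = 4L)
  th <- accumulate_thermo(tr)
  expect_true(all(diff(th$S_int_cum) >= -1e-14))
  expect_true(all(th$dS_tot >= -1e-12))
  # closure is exact by construction
  expect_lt(max(abs(th$S_sys - th$S_sys[1] - th$S_int_cum - th$S_exp_cum)),
            1e-12)
  # independent route: S_exp_cum ~ -integral dS_res (trapezoid error only)
  S_exp_dual <- -as.vector(pracma::cumtrapz(th$t, th$dS_res))
  expect_lt(max(abs(th$S_exp_cum - S_exp_dual)), 0.02)
  # equilibrium trajectory: flat everything
  trEq <- propagate(probability_state(stationary_distribution(base)), base,
                    t_end = 100, dt = 0.5, record_every = 4L)
  thEq <- accumulate_thermo(trEq)
  expect_lt(max(abs(thEq$S_int_cum)), 1e-10)
  expect_lt(diff(range(thEq$S_sys)), 1e-10)
  expect_error(accumulate_thermo(list(thermo = thEq[1, ])), "2 records")
})

test_that("GP diagnostic reports zero curvature for constant production and non-positive curvature for a relaxing system", {
  rec <- data.frame(t = seq(0, 10, by = 0.5), dS_tot = 0.3)
  g <- gp_diagnostic(rec, smooth_window = 1L)
  expect_equal(g$fraction, 1)
  expect_true(all(abs(g$d2S_int[!is.na(g$d2S_int)]) < 1e-12))

  fx <- two_state_fixture(1, 1, p0 = c(0.9, 0.1))
  tr <- propagate(fx$p0, fx$K, t_end = 4, dt = 0.01, record_every = 4L)
  g2 <- gp_diagnostic(tr$thermo, smooth_window = 1L)
  # production decays monotonically toward equilibrium
  expect_equal(g2$fraction, 1)
  expect_error(gp_diagnostic(data.frame(t = c(0, 1, 3, 7, 9),
                                        dS_tot = 1:5)), "uniformly spaced")
})
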