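# entropybathtub

Stochastic-thermodynamic simulation of driven continuous-time Markov jump
processes on one-dimensional energy landscapes, for researchers studying
dissipative structures, non-equilibrium steady states (NESS), and
entropy-based caricatures of living systems. The package reproduces the
characteristic **entropy bathtub** — the life-cycle entropy trajectory of a
driven system: a descent while a unidirectional drive self-organizes the
probability distribution, a low-entropy plateau while the drive sustains a
steady state (the thermodynamic analogue of homeostasis), and a recovery to
equilibrium once the drive ceases — together with reversible (pulse) and
irreversible (step) stressor perturbations of the plateau.

## The model

The probability vector `p` over `n` potential wells obeys the master
equation

    dp/dt = K p

where the generator `K` holds effective jump rates over the barriers,
either in Arrhenius form

    k_eff(x' -> x) = (omega/2) exp( beta (E_x' - E_B + delta_xx') )

or sampled directly (base rates uniform in [0.01, 0.02], the bathtub
default), with the driving energy `delta >= 0` multiplying a rate by
`exp(beta delta)`. Full thermodynamic accounting runs alongside the
dynamics:

* Shannon system entropy `S_sys = -k_B sum p ln p`;
* Schnakenberg system-entropy rate
  `(k_B/2) sum J_xx' ln(p_x'/p_x)` — the exact derivative of `S_sys`, with
  the probability current `J_xx' = k_xx' p_x' - k_x'x p_x`;
* total entropy-production rate
  `(k_B/2) sum J_xx' ln( k_xx' p_x' / (k_x'x p_x) )`, non-negative term by
  term, zero exactly at detailed balance;
* reservoir rate with the exact split `dS_tot = dS_sys + dS_res`, and
  cumulative produced/exchanged entropy closing the Prigogine balance
  `dS_sys = dS_int + dS_exp`;
* NESS certification: stationarity plus the Kolmogorov cycle criterion
  (forward and backward rate products around a cycle must differ). A driven
  ring is a strict NESS; a driven chain is a tree, has no cycles, and is
  certified non-strict — the package keeps this structural distinction
  explicit.

## Worked example

The canonical life-cycle run — 30 wells in a chain, base rates uniform in
[0.01, 0.02], uniform-random initial distribution, rectangular drive of
amplitude 1 toward state 1, all in dimensionless units:

```r
library(entropybathtub)

run <- run_bathtub(run_config(seed = 1))
print(run)
#> Entropy-bathtub run
#>   equilibrium entropy: 3.3570 (max ln n = 3.4012)
#>   plateau entropy:     1.0664 (depth 2.2907)
#>   final entropy:       3.3569 (recovery gap 0.01%)
#>   relaxation time:     26990
#>   GP fraction (drive plateau): 1.000
```

Reading the numbers: before the drive the system sits at its undriven
equilibrium entropy 3.357 (just below the uniform maximum ln 30 = 3.401);
the drive pushes it down to the plateau at 1.066 — a bathtub 2.29 deep —
where it is held as a driven steady state (the plateau value equals the
Shannon entropy of the driven generator's stationary distribution, an
independent linear solve); after drive-off at t = 45000 the entropy climbs
back to within 0.01% of equilibrium. The drive-window record enters its
plateau band at t ≈ 27000, i.e. about 2000 time units after drive onset.
The Glansdorff–Prigogine fraction 1.0 says the entropy-production rate
relaxed monotonically throughout the constant-drive plateau.
`plot(run$trajectory)` draws the entropy trace over the drive profile;
`accumulate_thermo()` yields the cumulative produced/exchanged entropy
curves.

Certifying a strict NESS on a uniformly driven 6-ring:

```r
cert <- certify_ness(driven_ring_fixture(6, 0.015, delta = 1)$K)
print(cert)
#> NESS certificate
#>   stationarity residual: 1.388e-17
#>   max per-edge current:  4.296e-03
#>   cycle ratio(s): 403.429
#>   strict NESS: TRUE
```

The cycle ratio is `exp(n beta delta) = exp(6) = 403.43`.

A thin command-line front end lives in `inst/cli/entropybathtub.R`
(subcommands `simulate`, `stressor`, `certify-ness`, `analyze`, YAML
configs in, CSV/JSON/PNG out).

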