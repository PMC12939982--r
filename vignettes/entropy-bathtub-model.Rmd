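---
title: "The entropy bathtub: driven Markov jump processes with thermodynamic accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The entropy bathtub: driven Markov jump processes with thermodynamic accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entropybathtub)
```

## The model

A living system viewed as a dissipative structure can be caricatured as a
particle hopping on a one-dimensional landscape of potential wells — a
continuous-time Markov jump process over $n$ mesostates whose probability
vector $p$ obeys the master equation

$$\dot p = K\,p,$$

where $K$ is the generator: off-diagonal entries $K_{xx'} \ge 0$ are the
effective rates of the jump $x' \to x$, and each diagonal entry is minus its
column sum, so probability is conserved. Two constructions of $K$ are
supported:

* **Arrhenius path.** Given well energies $E_x$ and one barrier $E_B$ per
  adjacent pair (shared by both jump directions),
  $K_{xx'} = \tfrac{\omega}{2}\, e^{\beta (E_{x'} - E_B + \delta_{xx'})}$,
  with $\omega$ the intrinsic attempt frequency, $\beta$ the inverse
  temperature and $\delta_{xx'} \ge 0$ an external driving energy supplied to
  that directed edge. With $\delta = 0$ the rates obey detailed balance,
  $K_{xx'} / K_{x'x} = e^{\beta (E_{x'} - E_x)}$, and the stationary state is
  the Boltzmann distribution of the well energies.
* **Sampled-rate path** (the default for life-cycle runs). Undriven base
  rates are drawn uniformly from $[0.01, 0.02]$ per directed edge; driving
  multiplies each rate by $e^{\beta \delta}$. This is the construction the
  bathtub simulations use, and it is algebraically consistent with the
  Arrhenius path: building with $\delta$ equals building undriven and then
  applying the drive (a package invariant, tested to $10^{-12}$).

A third parameterization, $K_{xx'} = e^{B_{xx'} + S_{xx'}/2}$ with $B$
symmetric (barriers) and $S$ antisymmetric (thermodynamic forces), is
provided for completeness; the log-ratio of conjugate rates is exactly
$S_{xx'}$.

Units are dimensionless throughout: $k_B = 1$, $\beta = 1$ by default, and
time is measured in units of the inverse intrinsic jump rate.

## Entropy accounting

Per recorded time point the package computes, from the instantaneous $(K, p)$:

* **System entropy** $S_\mathrm{sys} = -k_B \sum_x p_x \ln p_x$ (Shannon,
  with $0 \ln 0 = 0$), bounded by $[0, k_B \ln n]$.
* **System-entropy rate** (Schnakenberg form)
  $\dot S_\mathrm{sys} = \tfrac{k_B}{2} \sum_{x \ne x'} J_{xx'}
  \ln (p_{x'} / p_x)$, with the probability current
  $J_{xx'} = K_{xx'} p_{x'} - K_{x'x} p_x$. This is the *exact* time
  derivative of the Shannon entropy along the master equation; the test
  suite verifies first-order agreement with finite differences under
  dt-halving.
* **Total entropy-production rate**
  $\dot S_\mathrm{tot} = \tfrac{k_B}{2} \sum_{x \ne x'} J_{xx'}
  \ln \frac{K_{xx'} p_{x'}}{K_{x'x} p_x}$. Every summand has the form
  $(a - b)\ln(a/b) \ge 0$, so the rate is non-negative and vanishes exactly
  at detailed balance — the second law at the level of the network.
* **Reservoir rate** $\dot S_\mathrm{res} = \tfrac{k_B}{2} \sum J_{xx'}
  \ln(K_{xx'}/K_{x'x})$, with the exact split
  $\dot S_\mathrm{tot} = \dot S_\mathrm{sys} + \dot S_\mathrm{res}$.

Cumulative bookkeeping integrates $\dot S_\mathrm{tot}$ by the trapezoid
rule into the produced entropy $S_\mathrm{int}$ (non-decreasing) and closes
the Prigogine balance with the exchanged entropy
$S_\mathrm{exp} = \Delta S_\mathrm{sys} - S_\mathrm{int}$, so the identity
$\Delta S_\mathrm{sys} = S_\mathrm{int} + S_\mathrm{exp}$ holds at every
record by construction. $S_\mathrm{exp}$ is typically negative for a
dissipating, exporting system; the independent route
$-\int \dot S_\mathrm{res}\,dt$ agrees within trapezoid error and is
cross-checked in the tests. Summands of the Schnakenberg sums with $p = 0$
on either side are excluded (the standard limit convention); an edge with
exactly one of the two conjugate flows zero yields $+\infty$, flagged with
the offending edge rather than silently dropped.

The heat released to the reservoir by a single jump $x' \to x$ is
$Q = E_{x'} - E_x + \delta_{xx'}$: the energy drop plus the driving energy.

## Driving protocols and the life cycle

The main drive acts with a scalar amplitude $a(t)$ on every *forward* edge —
toward decreasing state index, so probability piles up near state 1 and the
Shannon entropy falls. The direction is a convention; any single consistent
direction produces the same phenomenology. Two shapes are built in:
rectangular (sudden on/off) and trapezoidal (linear ramps flanking a
plateau); segment boundaries are left-closed, right-open.

The canonical run (`run_config()` defaults) is a chain of $n = 30$ wells,
base rates $U[0.01, 0.02]$, uniform-random initial distribution, $\beta = 1$
and amplitude 1 — with every parameter configurable. The drive amplitude is
1 because the study conditions set all otherwise-unspecified parameters to
unity. The timeline is:

* **equilibration, 25 000 time units**: the slowest undriven mode relaxes at
  $\lambda_2 \approx 2\bar k\,(1 - \cos(\pi/n)) \approx 1.6\times10^{-4}$,
  i.e. $\tau \approx 6\,000$, so 25 000 units bring the start within ~1% of
  the undriven stationary state before the drive appears;
* **drive, 20 000 units**: the driven (strongly biased) chain relaxes in a
  few hundred units, so the plateau — the non-equilibrium steady state,
  the analogue of homeostasis — lasts tens of relaxation times;
* **recovery, 40 000 units**: several undriven relaxation times, enough for
  the entropy to return within 2% of its equilibrium value.

With the default Euler step `dt = 0.5` the full run is 170 000 steps and
takes a few seconds; a record is kept every 20 steps.

Stressors are opposing driving forces on the *backward* edges. A **pulse**
(finite duration) is reversible: entropy rises while the bias ratio
$e^{\beta(a - \Delta\delta)}$ is reduced, then relaxes back to the original
plateau. A **step** (persisting to the end of the run) is irreversible: the
system settles into a *new* steady state whose entropy lies strictly between
the original plateau and the equilibrium maximum, monotone in the step
amplitude. Stressors are kept as explicit backward-edge drives rather than
subtractions from the forward amplitude: both conventions give the same bias
ratio, but the absolute rates (and hence the heat per jump, which includes
$\delta$) differ, and the explicit form keeps that bookkeeping honest. In
stressor runs the main drive stays on to the end of the run so the
perturbed and recovered steady states are both visible; each configured
event runs in its own trajectory (a step, by definition, never ends). The
step-stressor settling window is 30 000 time units — at the weakest net bias
used ($e^{0.25}$) the stressed chain's relaxation time is roughly 1 500–2 000
units, and the final state is required to match the stationary distribution
of the stressed generator (an independent linear solve) to $10^{-6}$ total
variation, which needs on the order of 15–20 relaxation times.

## Steady states and NESS certification

A stationary distribution solves $K p = 0$; on a connected graph it is
unique and found by a dense linear solve with an appended normalization row
(a degenerate null space is an error, not averaged over). Whether a
stationary state is a *true* non-equilibrium steady state is decided by two
conditions: stationarity, and the Kolmogorov cycle criterion — around some
cycle, the product of forward rates must differ from the product of backward
rates. A linear chain is a tree: it has no cycles, its stationary state
balances every edge pairwise even under strong driving, and
`certify_ness()` therefore always returns `is_strict_ness = FALSE` for
chains, with an explanatory note. This is a genuine structural point: the
bathtub geometry (a 30-well chain) *cannot* satisfy the cycle condition
literally, while its driven plateau still shows the operational NESS
signature ($\dot S_\mathrm{sys} \approx 0$ with the drive on and
$\dot S_\mathrm{tot}$ set by the drive). The package therefore implements
both geometries and keeps the distinction explicit: a uniformly driven ring
(`driven_ring_fixture()`) is the strict-NESS witness, with uniform
stationary distribution, circulating current
$\tfrac{k_0}{n}(e^{\beta\delta} - 1)$ per edge and cycle ratio
$e^{n\beta\delta}$.

```{r ness-example}
cert <- certify_ness(driven_ring_fixture(6, 0.015, delta = 1)$K)
cert$is_strict_ness
cert$cycle_ratios[[1]]$ratio   # exp(6)
```

## Numerical choices

* **Integrator**: explicit Euler with per-step renormalization — the direct
  discrete-time evaluation of the master equation, which is the procedure
  the model prescribes. The stability guard
  $dt \cdot \max_x |K_{xx}| \le 0.1$ guarantees the update is a positive
  map (each state keeps at least 90% of the probability it would retain),
  so clamping is only ever needed for $-10^{-12}$-scale round-off; anything
  more negative is an error, not silently repaired. Because the Euler fixed
  point $(I + dt\,K)p = p$ has exactly the null space of $K$, long runs
  converge to the *exact* stationary distribution regardless of `dt`;
  `dt` only affects transient accuracy, at first order (verified by
  dt-halving against the two-state closed form). A matrix-exponential
  propagator (`propagate_exact()`, via `Matrix::expm`) serves as an
  independent oracle on constant-drive segments, and a scalar-loop Euler
  (`oracle_propagate()`) shares no code with the vectorized path.
* **Rate-matrix caching**: the driven generator is rebuilt only when the
  protocol amplitudes change, so rectangular segments cost one rebuild each
  while trapezoid ramps rebuild per step.
* **Plateau detection**: earliest window of the configured length
  (default 10% of the drive duration) in which the series spans less than
  `tol` (default 1%) of its full range, extended while values stay in band.
* **Relaxation time**: plateau-band entry time, band `tol` $\times$ the
  plateau value (or $\times$ the series range for observables that decay to
  zero, such as TV distance — this reproduces the $1/e$ convention for the
  two-state system).
* **Glansdorff–Prigogine diagnostic**: $\ddot S_\mathrm{int}$, i.e. the time
  derivative of $\dot S_\mathrm{tot}$, by central differences of a 5-point
  moving average on the uniform record grid. During any constant-drive
  segment the production rate relaxes monotonically toward its steady value,
  so the diagnostic is non-positive away from protocol switches — but the
  switches themselves are discontinuities where it cannot hold pointwise,
  so the package *reports* the fraction of interior points satisfying the
  criterion (within a $10^{-9}$ slack for flat, round-off-dominated
  stretches) rather than asserting it globally.

## What the synthetic systems do and do not emulate

All inputs are self-generated: seeded uniform base rates, seeded random
initial distributions, and deterministic protocols. The generator reproduces
the study conditions exactly where they are stated (30 wells, rate range,
uniform-random start, unit parameters) and fills the rest with explicit
choices (drive direction, phase durations, stressor amplitudes 0.25/0.5/0.75
spanning the range below the main amplitude). The dynamics are the
deterministic evolution of the probability vector — there is no Gillespie
sampling of single trajectories, so the "fluctuations" of a real mesoscopic
system (or of a single organism) are not rendered, and passing tests say
nothing about biological data: they certify the thermodynamic consistency of
the model (second law, exact rate decomposition, oracle-matched steady
states), not any claim about organisms. The entropy bathtub here is a
property of a driven Markov model whose life-cycle reading — development as
entropy descent, homeostasis as the driven plateau, aging/death as the
recovery toward equilibrium — is an interpretation layered on top.

## Known limitations

* Geometries are 1-D chains and rings; no higher-dimensional landscapes.
* The continuum (Fokker–Planck) entropy-production form
  $k_B \int J^2/(D p)\,dx$ is out of scope.
* No stochastic single-trajectory sampling and no fluctuation-theorem
  estimators.
* Cycle enumeration covers the built-in topologies (a ring's single
  fundamental cycle); arbitrary graphs would need a cycle-basis routine.
* The explicit-Euler integrator is first-order; it is the prescribed method
  and is cross-checked, but stiff rate matrices (far outside the study's
  rate scales) would need smaller steps than the guard suggests.
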