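---
title: "Methods: replicator dynamics of the supervision game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicator dynamics of the supervision game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phsgame)
```

## The game and its assumptions

`phsgame` models the supervision of government-purchased public health
services for older adults as an asymmetric evolutionary game between two
infinite, boundedly rational populations: public health service
institutions (PHSIs), who choose between *self-discipline* and *fraud*, and
local governments, who choose between *positive* and *passive* supervision.
The state `(x, y)` holds the frequency of self-discipline among PHSIs and
of positive supervision among governments.

The stage-game payoffs are parameterised by the maximum reward `S`, the
maximum penalty `P`, the government's incremental supervision cost `I > 0`,
the PHSI's incremental self-discipline cost `C > 0`, the extra fraud gain
`dL >= 0`, plus a baseline PHSI return `L` and a government social benefit
`G1`. With the static mechanism the bimatrix is

| | positive (y) | passive (1 − y) |
|---|---|---|
| self-discipline (x) | `L + S − C` ; `G1 − S − I` | `L − C` ; `G1` |
| fraud (1 − x) | `L − P + dL` ; `P − I − G1` | `L + dL` ; `−G1` |

`L` and `G1` cancel from every payoff *difference*, so they can never
influence the replicator dynamics; they are kept only so the full matrix is
reproducible, defaulting to 0. The model deliberately ignores heterogeneity
across institutions, strategies beyond the two listed, and any currency
conversion — all parameters must share one unit.

Both populations evolve by replicator dynamics: a strategy's frequency
grows in proportion to its payoff advantage over the population average,
giving

```
dx/dt = x (1 − x) [ (S_eff + P_eff) y − C − dL ]
dy/dt = y (1 − y) [ P_eff − I − x (S_eff + P_eff) ] .
```

Four incentive mechanisms set `(P_eff, S_eff)`: static `(P, S)`; dynamic
penalty `((1 − x) P, S)`; dynamic reward `(P, (1 − x) S)`; and both scaled.
The dynamic schedules use the population-level `x`: intensities are
proportional to the prevailing fraction of fraudulent institutions. A
useful implementation fact, verified algebraically and by property tests:
substituting the effective incentives into the payoff differences
reproduces exactly the per-mechanism polynomial systems, so one generic
right-hand side serves all four mechanisms, with the quadratic
"government bracket" `B(x)` and the bilinear "institution bracket"
`A(x, y)` differing only in three mechanism-dependent coefficients.

## Equilibria and stability

The four corners of the unit square are rest points for every mechanism;
an interior mixed-strategy point exists when its closed form lies strictly
inside `(0, 1)^2`:

* static: `x* = (P − I)/(P + S)`, `y* = (C + dL)/(P + S)`;
* dynamic penalty: `x* = 1 − (sqrt(S² + 4P(S + I)) − S)/(2P)`;
* dynamic reward: `x* = 1/2 + (P − sqrt((P − S)² + 4SI))/(2S)`;
* dynamic both: `x* = (2P + S − sqrt(S² + 4I(P + S)))/(2(P + S))`;

each with the matching `y*`. Two design choices deserve comment:

* **Existence is interiority.** The textbook-style printed inequalities
  that are sometimes quoted for when the dynamic interior points exist are
  ambiguous once typeset denominators are lost; the mathematically
  operative condition is simply that the closed-form root lies strictly
  inside the unit square, and that is what the package checks. The "minus"
  branch of each quadratic is taken and then polished by a short Newton
  iteration on `B(x)` to remove the cancellation error of the quadratic
  formula; degenerate leading coefficients (`P = 0` or `S = 0`) fall back
  to a bracketing root search.
* **Stability is numerical.** Every equilibrium is classified from its
  analytic Jacobian by the planar trace–determinant rule: `det J < 0`
  saddle; `det J > 0` and `tr J < 0` an asymptotically stable sink — the
  evolutionary stable strategy (ESS); `tr J ≈ 0` a center; `tr J > 0` a
  source. The trace tolerance is `1e-9 · max(1, ‖J‖)`. For the dynamic
  interior points the package reports whatever the eigenvalues actually
  are (at reference parameters, a complex pair with negative real part —
  a stable spiral) rather than relying on printed algebra, which is used
  only as a property to verify (`det J > 0`, `tr J < 0`). One known typo
  in the circulating statement of the static Jacobian (`a22` printed with
  an undefined symbol in place of `P`) is corrected in the implementation.

The static system's parameter space splits into the regimes `ESS_00`
(`P < I`), `ESS_01` (`I < P < C + dL − S`), and `CENTER`
(`P > max(I, C + dL − S)`), with a `BOUNDARY` class for ties (relative
tolerance `1e-9`) rather than silently resolving a knife-edge case.

## The center regime: orbits and a conserved quantity

In the `CENTER` regime the interior Jacobian is `[[0, tau1], [tau2, 0]]`
with `tau1 = (I + S)(P − I)/(P + S) > 0` and
`tau2 = (C + dL)(C + dL − P − S)/(P + S) < 0`: purely imaginary
eigenvalues, no asymptotic stability, and closed orbits. The angular
frequency is implemented as `omega = sqrt(|tau1 · tau2|)` — the square
root is required for the harmonic solution to have consistent dimensions
and to match the characteristic roots `±sqrt(tau1 tau2)`, although the
quantity is sometimes printed without it. The harmonic approximation
`x(t) = x* + Am cos(omega t + phi)` (and identically for `y`) is treated
as first-order only and held to amplitude and period accuracy: its shared
cosine forces `x` and `y` into phase, while the true linearized flow keeps
them a quarter period apart, so phase relations are explicitly *not* a
supported prediction.

Exact orbits come instead from the conserved first integral

```
H(x, y) = (P − I) log x + (S + I) log(1 − x)
        + (C + dL) log y + (S + P − C − dL) log(1 − y),
```

derived by separating variables in the static system; `dH/dt ≡ 0` was
verified symbolically before the function was relied on, and the tests
check gradient-flow orthogonality at random states, numerical drift below
`1e-6` along integrated cycles, and stationarity of `H` at the center.
Orbit closure is detected by a first return to the initial state; because
the continuous orbit crosses between output samples, the squared distance
is interpolated parabolically around each sampled local minimum before
being compared with the return tolerance, which makes the detector robust
at moderate sampling density.

## Numerical choices

* **Integrator.** `deSolve`'s Dormand–Prince 4(5) adaptive pair with
  `rtol = 1e-9`, `atol = 1e-12`. The center-regime orbits are the binding
  constraint: at looser tolerances the conserved `H` drifts visibly and
  closed orbits spiral artificially.
* **Clamping.** Replicator dynamics preserve the unit square analytically;
  the solver may overshoot by round-off near corners. Output states within
  `1e-8` outside `[0, 1]` are clamped (this threshold, not machine epsilon,
  is what Dormand–Prince at the above tolerances actually needs near
  absorbing corners); larger excursions raise a solver-failure error.
* **Currency rescaling.** Parameter sets in raw yuan (the case study has
  `S = 1.2e6`) are divided by their largest magnitude before integration.
  The replicator direction field is invariant under a common positive
  payoff scaling; only time rescales, and trajectories report both the
  integration time and the original model time.
* **Horizons and sampling.** Default horizon `t_end = 500` with 2,000
  output samples; convergence is judged on the trailing 5% window of
  samples together with the residual of the right-hand side at the final
  state. Closed-orbit analyses densify to 8,000 samples. These sizes were
  chosen so every regime's qualitative outcome (corner convergence,
  spiral capture, full cycles of the widest case-study orbit) is resolved
  comfortably.
* **Convergence-time metric.** "Evolves to a stable state faster" is
  operationalised, for sweeps, as the first time after which the
  trajectory stays within 0.01 of the interior equilibrium.

## Scenarios, randomness, and what the tests do and do not show

The built-in scenario registry carries the reference parameterizations:
two convergent static cases (`S=1, P=1.5, I=2, C=1, dL=4` and
`S=1, P=3, I=2, C=1, dL=4`), the mechanism-comparison set
(`S=3, P=9, I=3, C=1, dL=4`), two dynamic-reward sweeps, and the
case study: an 8,000-client home-care provider with a ¥150 per-person
purchase price, ¥105 contracted service cost and ¥120 per-person fraud
gain, ¥10,000 supervision cost and a ¥700,000 penalty, aggregating to
`S = 1,200,000`, `C = 840,000`, `dL = 960,000` and penalty threshold
`600,000`. The per-person fraud gain is taken as the printed ¥120 even
though the narrative's actual per-person spend (¥20–30) suggests other
decompositions; the registry reproduces the printed number. Initial
conditions behind the reference simulations are not specified anywhere, so
they are exposed as user inputs defaulting to `(0.5, 0.5)`.

Random parameter sets for property tests are drawn log-uniformly from
`[0.1, 20]` — spanning two orders of magnitude around the unit-scale
reference values — through a named stream that is deterministic in a
single integer seed and never touches the caller's RNG state. Regime
requests are satisfied by rejection sampling with an explicit budget.

The cross-mechanism ranking `x*(reward) > x*(both) > x*(penalty)` is
demonstrated at one parameter set; the package therefore implements the
general claim as an *audit* (`audit_mechanism_ordering()`) that reports
counterexamples rather than asserting the ordering as an axiom. Across the
audited draws in the test suite no counterexample has appeared.

What passing tests show: the implemented dynamics agree pointwise with the
published polynomial systems; closed forms agree with an independent
grid-plus-Newton root oracle; classifications follow the Jacobian rule;
the conserved quantity is conserved. What they do not show: anything about
real supervision data. The model is a stylised two-strategy game with
homogeneous populations, deterministic dynamics and no noise, delay or
finite-population effects; its value is qualitative mechanism comparison,
not calibrated prediction.

## Known limitations

* Only two strategies per population; no institution-level heterogeneity.
* No stochastic or finite-population replicator variants.
* Sweeps are one-dimensional; no 2-D phase diagrams or continuation.
* The harmonic orbit approximation is amplitude/period-accurate only.
* `run_report()` bundles analyses but does not render plots.
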