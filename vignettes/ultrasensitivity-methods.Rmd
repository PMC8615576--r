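---
title: "Models, metrics and numerical methods in cmcscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, metrics and numerical methods in cmcscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cmcscan` quantifies the steady-state input–output behavior of a covalent
modification cycle (CMC) whose protein substrate is synthesized and degraded
— and whose degradation rate may itself depend on the modification state.
This vignette documents the models, the metric conventions, and every
numerical choice a user relying on the package's numbers should know about.

## The two model variants

**Michaelis–Menten (MM) variant.** The substrate R is synthesized at a
constant rate `k0`, phosphorylated by a kinase at level `X` with
Michaelis–Menten kinetics (`Vmax = k1*X`, Michaelis constant `Km1`),
dephosphorylated by a phosphatase at level `Y` (`Vmax = k2*Y`, `Km2`), and
both forms are degraded with first-order rate constants `k3` (for R) and
`k4` (for Rp):

$$\frac{dR}{dt} = k_0 - \frac{k_1 X R}{K_{m1}+R} + \frac{k_2 Y R_p}{K_{m2}+R_p} - k_3 R,
\qquad
\frac{dR_p}{dt} = \frac{k_1 X R}{K_{m1}+R} - \frac{k_2 Y R_p}{K_{m2}+R_p} - k_4 R_p.$$

**Full mass-action variant.** Binding, dissociation and catalysis are
resolved into elementary steps with explicit complexes RX and RpY; free
enzyme is the algebraic difference `Xtot − RX` (and `Ytot − RpY`), which
makes enzyme conservation exact by construction rather than a property the
integrator must maintain. Substrate in a complex is degraded with the same
rate constant as the corresponding free form (`k3` for R and RX, `k4` for Rp
and RpY); degradation of a complex removes the complex and releases the
enzyme intact. This equal-stability assumption is the one structural
uncertainty of the mass-action variant: selective degradation of one subunit
of a complex is well documented, but a complexed substrate could in
principle be more or less stable than its free form. Only the equal-rate
case is implemented.

All quantities are in arbitrary concentration and time units; there is no
unit-conversion layer. Parameter objects are immutable values — scans and
scenario overrides always derive fresh copies (`set_params()`), so no run
can contaminate another.

### Default parameterization and what it encodes

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `k0` | 1 | synthesis rate; sets the basal substrate `k0/k3 = 100` |
| `k1`, `k2` (`k1c`, `k2c`) | 10 | catalytic rate constants |
| `Km1`, `Km2` | 10 | basal substrate exceeds both tenfold: zero-order regime |
| `k3`, `k4` | 0.01 | turnover is 1/100 of the apparent modification rates `k1/Km1`, `k2/Km2`, reflecting the hours-vs-seconds time-scale separation between protein half-lives and (de)phosphorylation |
| `X` / `Xtot` | 0 | kinase off at baseline; usually the dose axis |
| `Y` / `Ytot` | 1 | phosphatase level; substrate ≫ enzyme at default |
| `k1f`, `k2f` | 10; `k1b`, `k2b` = 90 | chosen so the apparent `Km = (kb+kc)/kf` equals the MM value of 10 |

Stability regulation is expressed entirely through `k4`: `k4 < k3` means
the modification stabilizes the protein, `k4 > k3` destabilizes it.

## Dose–response scans

A scan solves one steady state per point of a geometric dose grid
`from * (1 + step/100)^i`, truncated at `to`, with a default step of 1%.
The increment is deliberately multiplicative: the local response coefficient
is a log–log derivative, and a uniform log-dose spacing makes its finite
difference uniformly accurate across the range; dose–response analysis is
log-scaled by convention. The grid interpretation is recorded in every
output manifest.

Default ranges are `[1e-2, 1e2]` for kinase-level (`X`/`Xtot`) and
synthesis-rate (`k0`) axes — wide enough to span the transitions of all
default-parameter scenarios. Procedures that push a Michaelis constant
toward large values scale the upper dose bound with it (`10 * Km1`),
because the 10–90% transition of the response shifts right in proportion to
`Km1`; a fixed range would either truncate the transition or fail the
saturation check. Saturation (plateau) detection validates every range
choice at metric time.

The zero-dose **background** is the basal steady state (axis value 0) when
the axis is the kinase level; for axes like `k0` where zero is not a
meaningful operating point, the background is the response at the lower grid
bound, and the choice is recorded as `background_at`.

## Steady-state solver

- **MM variant:** at a steady state the turnover balance `k0 = k3 R + k4 Rp`
  eliminates one unknown; the remaining scalar balance is solved by
  bracketed bisection (`uniroot`, tolerance 1e-15), which cannot diverge and
  cannot leave the physical region. Degenerate cases are handled in closed
  form where possible: `X = 0` gives `(k0/k3, 0)`; `k4 = 0` pins
  `R = k0/k3`; `k3 = 0` pins `Rp = k0/k4`. If a pinned flux exceeds the
  capacity of the opposing reaction no finite steady state exists and the
  solver falls through to integration (which then reports the divergence).
- **Full variant:** damped Newton iteration with the analytic Jacobian,
  line-searched to stay inside the physical box (all species ≥ 0,
  `RX ≤ Xtot`, `RpY ≤ Ytot`) and to decrease the residual; convergence at
  max |derivative| < 1e-11.
- **Fallback:** if root finding fails or returns a state violating the
  residual tolerance (1e-8 in derivative units), the system is integrated
  from the basal state with the stiff solver (`deSolve::ode`, `lsoda`,
  rtol 1e-9, atol 1e-12), doubling the horizon until the scaled residual
  max|dx/dt| / max(state, 1) stays below 1e-10 across a doubling of
  integration time. The tight integration tolerances matter because the LRC
  is a finite difference on a 1% grid, which amplifies solver noise roughly
  a hundredfold.

Scans warm-start each solve from the previous dose's solution. Both model
variants are monostable throughout the regimes explored here, so warm
starting affects speed only; a test verifies that cold- and warm-started
scans agree to 1e-8.

**Closed-cycle mode.** With `k0 = k3 = k4 = 0` the cycle conserves total
substrate and no synthesis/degradation balance defines a basal level, so
the conserved total becomes an explicit input (`total =`); the MM steady
state then reduces to a single bracketed root in `Rp`.

## Ultrasensitivity metrics

**Hill coefficient.** The response is normalized to
`f(D) = (r(D) − r_bg) / (r_plateau − r_bg)` with the plateau taken at the
high-dose end of the scan; `X_0.1` and `X_0.9` are located by monotone
piecewise-linear interpolation in (log dose, f) — on a 1% grid, higher-order
interpolation changes nothing but reproducibility. Then
`n_H = ln 81 / ln(X_0.9/X_0.1)`, negated for decreasing responses. For an
inhibitory curve the same normalization measures the fractional *decrease*
from the basal level, which is the only reading under which the mirror-image
R and Rp responses of the baseline cycle get equal and opposite
coefficients.

`n_H` is reported as **undefined — a flagged NA, not an error** — when the
curve is not monotone (beyond 1e-9 relative rounding noise) or does not
saturate. Scenario tables therefore carry "not evaluated" cells rather than
halting, which is the correct behavior for synthesis-rate scans whose R and
Rtot responses grow without bound.

**Saturation check.** A readout is saturated when its variation over the
last half-decade of doses is below 1% of the curve's overall scale (its
largest magnitude). The variation is measured against the curve scale, not
the local value: an inhibitory readout decaying toward zero always has a
large *relative-to-local* tail slope even when the remaining change is a
negligible fraction of the response, and a local-value criterion would
declare every such curve unsaturated — including ones whose steepness is
plainly well-defined. The 1% threshold separates all saturating scenarios
shipped with the package from linearly or unboundedly growing ones.

**Local response coefficient.** Centered finite differences of log response
against log dose at interior points, one-sided at the endpoints; responses
at or below 1e-12 are masked. Spline or smoothing estimators were
deliberately avoided: they introduce a smoothing-parameter choice, and the
uniform log grid makes plain differences accurate. `lrc_max()` reports the
largest |LRC| with ties broken toward the lower dose.

**Asymptotic readings** (`metric_plateau()`): "the metric as `k4` (or
`Km1`) becomes very large" is operationalized as repeated multiplication by
a factor (doubling by default; factor 10 where a coarser ladder is the
documented procedure) until the metric changes by less than 1% per step,
reporting the value after the final step.

## What the scenario generator emulates — and what it does not

The built-in scenarios are deterministic ODE experiments: parameter sets,
dose axes and ranges that place the cycle in the zero-order, titration,
emergence, destabilization and synthesis-driven regimes. They emulate the
*structure* of signaling responses (saturable opposing enzymes, turnover,
stability coupling) under idealized conditions: no expression noise, no
cell-to-cell variability, no measurement error, a single cycle rather than a
cascade, constant enzyme levels, and arbitrary units. Passing tests
therefore demonstrate correctness of the mathematics and the
implementation, not that any particular biological system realizes these
parameter values. Where enzyme and substrate abundances are comparable —
the regime motivating the mass-action variant — conclusions from the MM
variant are checked against the full model rather than assumed.

## Numerical edge cases and conventions

- Flat responses (e.g. total substrate when `k3 = k4`): monotone by
  convention, `n_H` undefined with reason "flat response".
- Responses crossing 1e-12 are masked in LRC space rather than propagating
  log(0).
- The full model's curve tables include the complex species and
  `total_substrate = R + Rp + RX + RpY`; the free-substrate readout
  `Rtot_free = R + Rp` is distinct, and is the readout that can become
  nonmonotonic under stabilization with abundant phosphatase.
- CSV outputs are written in plain decimal at 17 significant digits via a
  locale-independent formatter, making scenario runs byte-identical across
  repetitions; JSON manifests record parameters, grid (including the
  multiplicative-increment convention), backgrounds and tolerances, so
  every table can be regenerated from its manifest.

## Problem sizes

The shipped tests and the reproduction script use the 1% grid throughout:
926 steady states per `[1e-2, 1e2]` scan, up to ~1,600 for the widest
large-`Km1` scans, a handful of scans per plateau walk, and eight random
parameter draws for the root-vs-integration cross-check. A full test run
performs on the order of 10^5 steady-state solves.

## Known limitations

- Deterministic steady-state analysis only: no stochastic simulation, no
  bistability or oscillation analysis (the models here are monostable).
- Single substrate and enzyme pair: no multi-substrate competition for a
  shared degradation pathway, no cascades.
- Complexed and free substrate share degradation rate constants (see
  above).
- The Hill coefficient depends on the scan range through the plateau
  estimate for slowly saturating curves; the saturation flag guards against
  the worst of this, and grid-refinement stability (metrics move < 0.5%
  when the step is halved) is itself a tested property, but `n_H` for a
  curve that barely saturates should be read with its `X_90` location in
  mind.
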