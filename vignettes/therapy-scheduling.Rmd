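---
title: "Modelling EGFR-TKI resistance evolution and drug-switching schedules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling EGFR-TKI resistance evolution and drug-switching schedules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkievolve)
```

## The model

EGFR-mutant non-small cell lung cancer responds well to EGFR tyrosine
kinase inhibitors (TKIs), but resistance mutations reliably emerge: the
T790M gatekeeper mutation defeats first/second-generation TKIs
(erlotinib, gefitinib, afatinib — "drug A" here), and C797S defeats the
third-generation inhibitor osimertinib ("drug B"). `tkievolve` tracks
four genotypes: Type-W (driver mutation only, sensitive to both drugs),
Type-X (T790M, resists A), Type-Y (C797S, resists B) and Type-Z (both
mutations, resists everything). Under a constant regimen each
population grows or declines exponentially and seeds more-resistant
types at small per-day mutation rates:

$$
\begin{aligned}
\dot w &= a\,w \\
\dot x &= g\,w + b\,x \\
\dot y &= h\,w + c\,y \\
\dot z &= k\,w + p\,x + q\,y + f\,z
\end{aligned}
$$

The assumptions matter as much as the equations: growth is
density-independent (no carrying capacity), mutation is irreversible
(no back-mutation, so the system is triangular), counts are continuous
non-negative reals (no extinction threshold — a deterministic
mean-field view, not a branching process), and a drug acts only through
the values of the nine rates.

Because the coupling is triangular the system solves exactly by
variation of constants. `w` is a pure exponential; `x` and `y` each add
one divided-difference term fed by `w`; `z` collects one term per
distinct upstream eigenvalue, including the two double-mutation chains
W→X→Z and W→Y→Z:

$$
\begin{aligned}
w(t) &= W_0 e^{at}\\
x(t) &= X_0 e^{bt} + \frac{gW_0}{a-b}\left(e^{at}-e^{bt}\right)\\
y(t) &= Y_0 e^{ct} + \frac{hW_0}{a-c}\left(e^{at}-e^{ct}\right)\\
z(t) &= Z_0 e^{ft}
  + U_a\frac{e^{at}-e^{ft}}{a-f}
  + U_b\frac{e^{bt}-e^{ft}}{b-f}
  + U_c\frac{e^{ct}-e^{ft}}{c-f},
\end{aligned}
$$

with
$U_a = kW_0 + p\,\tfrac{gW_0}{a-b} + q\,\tfrac{hW_0}{a-c}$,
$U_b = p\,(X_0 - \tfrac{gW_0}{a-b})$ and
$U_c = q\,(Y_0 - \tfrac{hW_0}{a-c})$.

`closed_form_state()` implements this cascade; `numeric_reference_state()`
integrates the same right-hand side with `deSolve::lsoda` and serves as
an independent oracle in the test suite (agreement is required to a
relative 1e-6, and measures around 1e-9 at the defaults).

## Parameters and standard conditions

`default_parameter_table()` carries the built-in rates (per day):

| regimen | a (W) | b (X) | c (Y) | f (Z) | mutation rates |
|---|---|---|---|---|---|
| A (erlotinib) | -0.17 | 0.045 | -0.13 | 0.022 | all 1e-7 |
| B (osimertinib) | -0.32 | -0.15 | 0.024 | 0.022 | all 1e-7 |
| C (combination) | -0.064 | -0.0335 | -0.0335 | 0.022 | all 1e-7 |

The growth rates derive from published genome-edited cell-line
measurements under each drug; the combination regimen scales the
drug-A rates by the observed ratio of Type-Y growth under combination
versus drug A. Type-Z grows at +0.022/day under every regimen — it
must, being resistant to both drugs; the sign is what makes the
eventual relapse inevitable in this model.

The standard initial condition is a clinically detectable tumor of
1e9 cells (about 1 cm diameter) with resistant subclones
X0 = Y0 = 1e4 and Z0 = 10, Type-W making up the remainder
(`standard_initial_state()`). The default schedules switch drugs at
day 307 (A-first) or day 567 (B-first), the median progression-free
survival times reported for each first-line drug, over a 1000-day
horizon — long enough for every strategy to relapse and separate.

## Simulating schedules

`simulate_schedule()` evaluates the closed form once per output point
from the phase-start state, so trajectories carry no accumulated
stepping error and the horizon total is independent of the output grid
(verified to a relative 1e-12 in the tests). All arithmetic stays in
linear space: the largest factors involved (growth e^22 on 1e9 cells)
are far inside double-precision range, so log-space bookkeeping would
only add complexity.

```{r}
params <- default_parameter_table()
trajectory <- simulate_schedule(params, strategy_schedule("B-first"))
glance(trajectory)
```

**Recurrence** needs an operational definition, because "the tumor
recurred" is used loosely in the clinical literature. The package
defines the recurrence day as the first return of the total burden to
its baseline (day-0) value after a treatment-induced nadir, located by
linear interpolation between grid points. Under the defaults this gives
day ~255 (A-first), ~478 (B-first) and ~621 (combination); a published
description of the same dynamics quotes day 490 for the B-first
schedule under an unstated criterion, so the ordering of strategies is
the robust conclusion and the absolute day is reported, not enforced.

## Numerical choices

* **Degenerate rate combinations.** The cascade divides by the rate
  differences a−b, a−c, a−f, b−f, c−f. When any of these is below
  1e-8 of the largest growth-rate magnitude the propagator switches to
  adaptive integration at rtol 1e-12 and signals a
  `tki_degenerate_fallback` message (counted and logged by
  `run_all()`). The default rates never trigger this, but wide
  sensitivity sweeps do — e.g. a 21-point sweep of `b` under regimen A
  passes exactly through b = f = 0.022 — and the fallback keeps those
  grid cells exact to tolerance instead of special-casing repeated
  eigenvalues analytically.
* **Comparison floor.** Test comparisons use a relative error with a
  one-cell floor: components below one cell are compared absolutely,
  since sub-cell counts are beneath the resolution of a continuous
  deterministic model (after 1000 days of decline at −0.32/day a
  population underflows to ~1e-70 "cells"; demanding relative accuracy
  there is meaningless).
* **Ties on the selection map.** Horizon totals agreeing to a relative
  1e-9 are ties, resolved by the fixed precedence B-first > A-first >
  C (an arbitrary but documented choice; ties essentially never occur
  off razor-edge grids).
* **CSV round-trips.** `run_all()` writes numbers through `readr`,
  which serialises doubles losslessly, so re-read results are
  bit-identical to the computed ones.

## The experiments and their grids

Five experiment functions reproduce the study designs end-to-end;
`run_all()` executes all of them and writes CSVs plus a JSON summary.

* `sweep_switch_time()` — horizon total versus switch day, integer days
  1–999 by default. The computed optima are ~1.90e12 cells (A-first,
  switch near day 92) and ~1.08e12 (B-first, near day 190); both curves
  have long flat valleys (within-10% windows of roughly days 49–302 and
  148–948), so the clinically relevant message is the breadth of the
  acceptable window, not the precise argmin.
* `sweep_initial_proportion()` — horizon total versus the initial
  fraction of one resistant genotype, decade endpoints 1e-8…1e-1 for X
  and Y and 1e-9…1e-5 for Z, refined by 8 log-spaced points per decade
  so threshold locations are visible between decades. A rise is scored
  as a ≥10% increase over the low-proportion plateau (threshold
  configurable): Type-X matters only to A-first therapy (threshold
  near 1e-4), Type-Y only to B-first (near 1e-3), Type-Z to every
  strategy (near 1e-7). One caveat the sweeps make visible: at
  fractions approaching 1e-1 every strategy's final drifts a few
  percent upward simply because W0 shrinks at fixed total — the
  "unaffected strategies are flat" statement holds to <1% only below
  ~1e-3.
* `build_selection_map()` — best strategy per cell of a 25×25
  log-spaced grid of initial X and Y fractions (Z fixed at 10 cells).
  The resolution is a speed/smoothness compromise and is configurable;
  region boundaries move by less than a grid cell when refined.
* `parameter_sensitivity_grid()` — horizon total while one rate varies
  under the first-line regimen (grid rows) and second-line regimen
  (columns), or one-dimensionally under the combination. Growth rates
  sweep their default ±0.1/day on 21 linear points (wide enough to
  cross zero, i.e. to flip a drug from suppressive to permissive);
  mutation rates sweep 1e-9…1e-5 on 17 log points, bracketing
  biologically plausible per-day rates.
* `selection_area_composition()` — fraction of the map on which each
  strategy is optimal, as one focused rate varies; uses a coarser
  15×15 map per value (area fractions are insensitive to resolution
  well before 15×15) and the sensitivity ranges above.

## The scenario generator

`sample_regimen_parameters()` and `sample_initial_state()` generate the
randomised inputs the property tests run on: growth rates uniform
within ±50% of the default magnitudes with the sign structure of the
drug effects preserved (under A: W,Y decline and X,Z grow; under B:
W,X decline and Y,Z grow; under C only Z grows), mutation rates
log-uniform in [1e-9, 1e-5], and initial X/Y fractions log-uniform in
[1e-8, 1e-2] (Z in [1e-9, 1e-5]) with W absorbing the remainder. Draws
whose growth rates nearly coincide are rejected (at most 1000
attempts) so every scenario admits the closed form. Randomness uses
R's default Mersenne-Twister via `withr::with_seed`, making draws
reproducible across platforms and leaving the caller's RNG untouched.

The generator emulates the *structure* of the study inputs, not
patient data: scenarios share the model's own assumptions
(exponential growth, fixed rates, no noise). Passing property tests
therefore demonstrate internal correctness — closed form ≡ integrator,
linearity, semigroup composition, monotonicity — across the plausible
parameter regime; they say nothing about how well exponential
growth-mutation kinetics describe a real tumor.

## Problem sizes used by the checks

Unit tests cross-check the closed form against the integrator on 25
random scenarios at three horizons; the full property suite uses 100
scenarios (rel. error ≤ 1e-6 required throughout). Switch-day sweeps
run all 999 integer days; map assertions use 2- to 15-point grids per
axis, and the pipeline test runs `run_all()` on reduced grids (5×5
map, 3-point sensitivity sweeps). These sizes keep the whole suite in
the tens of seconds while exercising every code path at full numeric
fidelity — the closed form makes each evaluation O(1), so larger grids
change nothing but resolution.

## Known limitations

* Deterministic continuous counts: no extinction of small clones, no
  variance between patients; with Z0 = 10 "cells" the model is really
  propagating an expectation.
* Exponential growth without density dependence — totals like 4e12
  cells at day 1000 should be read as a severity score, not a literal
  burden a patient could carry.
* Irreversible, drug-independent mutation at a single shared rate;
  only four genotypes; no dose effects, pharmacokinetics or toxicity
  constraints.
* Schedules are fixed in advance (at most two phases in the
  experiments); adaptive switching triggered by tumor size is out of
  scope, as is fitting the rate parameters to trajectories.
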