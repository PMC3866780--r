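---
title: "Two-compartment kinetics of nicardipine-cyclodextrin complexes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-compartment kinetics of nicardipine-cyclodextrin complexes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncpk)
```

## The problem

Nicardipine (NC) is a dihydropyridine calcium-channel blocker with poor oral
bioavailability: it dissolves slowly (high log P) and is rapidly converted in
the liver to its pyridine metabolite, so free NC produces a sharp, short
plasma peak. Formulating it as a cyclodextrin inclusion complex changes the
release profile: the hydrophilic hydroxypropyl-β-cyclodextrin complex
(NC/HPβCD) dissolves within about 15 min, the hydrophobic
triacetyl-β-cyclodextrin complex (NC/TAβCD) only after about 480 min,
against 180 min for the free drug. This package implements the
two-compartment linear-kinetics analysis of these three formulations: rate
calibration from half-lives, a short-range absorption–metabolism model, a
fold-based refinement against in-vivo peak data, and a long-range
periodic-dosing simulation.

## Rate calibration

All transfers are first-order, so each half-life maps to a rate constant,

$$k = \frac{\ln 2}{t_{1/2}},$$

(`half_life_to_rate()`). The bundled half-lives are: GI 30 min / plasma
1.6 h for NC, 4 h / 5.49 h for NC/HPβCD, and 2.2 h / 7.38 h for NC/TAβCD.
Internally every rate is stored in min⁻¹; the rate tables of the source
study print $k \times 10^3$, which we treat strictly as a display
convention (`display_rate()`). The published tables label these columns
"mL/min", which is dimensionally impossible for a first-order rate; only
the min⁻¹ reading makes the table equal $\ln 2 / t_{1/2}$ for the quoted
half-lives, so that is the reading used.

`rate_table()` reproduces the published six-entry table and classifies each
entry as `exact`, `within_1ulp` (one unit in the last printed digit — the
published rounding is not uniform: 2.888 prints as 2.88, 1.565 as 1.56), or
`discrepancy`. One entry is a genuine discrepancy: the TAβCD GI rate prints
5.28 where the formula gives 5.251 → 5.25. The published downstream
arithmetic is consistent with 5.28 (23.1/5.28 = 4.375 → the quoted 4.38
GI-rate ratio), so the table value was likely back-calculated from a
slightly different half-life. We do not guess: the computed value and the
printed value are both surfaced, and the later pipeline stages consume the
*printed* table rates, which is the only convention that reproduces the
published results.

## Short-range model

The short-range stage follows a unit load through the irreversible chain

$$\mathrm{GI} \xrightarrow{k_{GI}} \mathrm{plasma}
  \xrightarrow{k_{Plasma}} \mathrm{metabolite},$$

i.e. $dC_A/dt = -k_{GI} C_A$, $dC_B/dt = k_{GI} C_A - k_{Plasma} C_B$,
$C_C = C_A(0) - C_A - C_B$, with $C_A(0) = 1$ ng/mL. Three solution routes
are implemented and cross-checked:

* the closed-form (Bateman) plasma curve
  $C_B(t) = C_A(0)\,\frac{k_{GI}}{k_{Plasma}-k_{GI}}
  (e^{-k_{GI} t} - e^{-k_{Plasma} t})$, with the degenerate equal-rate limit
  $C_A(0)\,k t e^{-kt}$ (`bateman_plasma()`);
* the matrix exponential $C(t) = e^{At} C(0)$ (`solve_linear_system()`),
  computed by eigendecomposition when the eigenvector matrix is well
  conditioned (reciprocal condition > 1e-8) and by scaling-and-squaring
  Taylor otherwise — the contract is agreement with an independent RK4
  integration to 1e-6 relative, not a particular algorithm;
* fixed-step RK4 (`rk4_integrate()`), used as the numerical cross-check.

The analytic peak is $T_{max} = \ln(k_{GI}/k_{Plasma})/(k_{GI}-k_{Plasma})$
(limit $1/k$ at equal rates), $C_{max} = C_B(T_{max})$ (`bateman_peak()`),
verified in the tests against a dense-grid maximiser.

An important convention: the short-range runs use the printed table
*magnitudes* as min⁻¹ rates (e.g. 23.1 min⁻¹ for NC), not the ×10⁻³
values. Only that reading reproduces the published sub-minute peak times
(0.07 min for NC, 0.40 min for NC/HPβCD); the 10³ factor belongs to the
table display alone. Both conventions are explicit in the code.

### The hydrophobic adjustment

The slow-dissolving NC/TAβCD complex gets two adjustments: its initial GI
load is divided by the GI-rate ratio
$k_{GI}(\mathrm{NC})/k_{GI}(\mathrm{NC/TA\beta CD})$ (= 23.1/5.28 = 4.38
with printed rates), and its plasma level carries a factor of 2.5 whose
mechanistic placement the source analysis does not specify. We implement
the 2.5 factor as an explicit strategy (`apply_hydrophobic_adjustment()`):

* `output_scale` (default): the reported plasma series/peak is multiplied
  by 2.5 — a pure reporting transform; the underlying solution still
  conserves mass;
* `slow_elimination`: the plasma elimination rate is divided by 2.5.

Neither strategy reproduces the published TAβCD precalculated pair
(0.18 ng/mL, 0.44 min): `output_scale` gives (0.34, 0.33 min) and
`slow_elimination` (0.17, 0.46 min). Rather than hide this, the validation
table quantifies the gap per strategy in `discrepancy_notes`, and the fold
calibration for TAβCD proceeds from the *printed* precalculated pair, which
is what makes the published 5.38 divisor and the validated 18.46 ng/mL
reproducible.

## Fold refinement and validation

The calibration step aligning simulated and experimental peaks divides both
rates by

$$\mathrm{Fold} = \frac{T_{max}\, C_{max}^{pre}}{T_{max}^{pre}\, C_{max}},$$

where $(C_{max}^{pre}, T_{max}^{pre})$ is the precalculated short-range peak
and $(C_{max}, T_{max})$ the experimental one. The folds are computed from
the printed rounded inputs (0.58 ng/mL, 0.07 min, 69.64 ng/mL, 60 min for
NC, and so on), because the published divisors (7.14, 4.88, 5.38) are
reproducible only that way; full-precision intermediates give slightly
different values. Likewise `refine_rates()` divides the printed table rates.
The published refined NC row (3.18, 0.99) does not equal 23.1/7.14 and
7.2/7.14 (3.24, 1.01) under any rounding we could construct; the pipeline
computes the formula's value and flags the difference rather than adopting
either silently.

The final validation maps the refined short-range peak back to plasma
concentration units. The scaling formula is not written out in the source;
we reconstruct it as

$$C_{max}^{val} = C_{max}^{ref} \cdot \frac{T_{max}^{exp}}{T_{max}^{ref}},$$

and validate the reconstruction against all three published outputs before
relying on it: with printed refined peaks it returns 39.09 and 18.46 ng/mL
exactly (2 d.p.) and 68.08 vs the published 68.07 for NC — the 0.01
difference is attributed to unrounded intermediates on the authors' side
and carried in `discrepancy_notes`. All three validated peaks fall within
one experimental SD of the in-vivo means (69.64 ± 8.57, 39.65 ± 1.11,
18.25 ± 0.74 ng/mL).

## Long-range periodic dosing

The long-range stage integrates the dosage-driven system

$$\frac{dx}{dt} = D(t)\,\mathrm{DR} - k_{GI}\,x,\qquad
  \frac{dy}{dt} = k_{GI}\,x - k_{Plasma}\,y,$$

with $x(0) = y(0) = 0$, rates in h⁻¹ from the same half-lives. The source
writes the loss terms as divisions by $t_{1/2}$ (and the plasma loss with an
extra factor of $t$), but quotes parameter values ($2\ln 2$, $\ln 2/1.6$, …)
that are rate constants in h⁻¹ consistent with the stated half-lives; we
therefore implement standard first-order elimination $k = \ln 2 / t_{1/2}$
and document the notational conflation. A literally time-proportional
plasma loss would preclude the stated periodic limit cycles.

Dosing is a periodic pulse train (`dose_regimen()`): every 6 h for NC and
every 24 h for the complexes. The pulse shape is not specified in the
source; the default is a rectangular pulse of width 0.5 h (an oral dose
dissolving over ~30 min), with an instantaneous bolus available — the tests
confirm the bolus is the narrow-pulse limit. The delivered dose is scaled
by the dissolution ratio: relative to the fast-dissolving NC/HPβCD
reference (15 min), NC carries 1/12 and NC/TAβCD 1/32 (180/15 and 480/15,
`dissolution_fold()`). The base dose defaults to the precalculated
0.49 µg/mL concentration-equivalent; because the source's exact pulse shape
and absolute dose are under-specified, the published figure peak heights
(54.6, 60.1, 81.5, 41.5, 28.9, 21.6 ng/mL) are matched only qualitatively
and deliberately excluded from quantitative checks. The properties that
*are* checked do not depend on those choices: nonnegativity, superposition
(the system is linear), asymptotic periodicity with the detected limit-cycle
period equal to the dosing period, and for the bolus shape the analytic
limit-cycle mean $\bar y = (\text{dose}\cdot\mathrm{DR}/\text{period})/
k_{Plasma}$, matched within 1%.

Integration is classical fixed-step RK4, default dt = 0.01 h over 15 dose
periods with a 10-cycle burn-in before limit-cycle metrics. A step within a
tenth of the fastest kinetic timescale triggers a warning; a step at or
beyond it is refused. The fourth-order convergence of the scheme is
measured in the tests (halving dt cuts the decay-problem error ≈16×).

## Synthetic data and parameter recovery

`generate_observations()` draws noisy plasma observations from the Bateman
curve: multiplicative Gaussian noise (observed = true × (1 + ε),
ε ~ N(0, cv)) by default, mirroring the mean ± SD structure of plasma assay
summaries; additive noise is available. Negative values are clipped to zero
and the clipping rate reported. Every draw is seeded and reproducible. The
default schedule is 25 log-spaced samples over 0.1–30 min — dense around
the sub-minute peaks, covering the decay tail.

`fit_bateman()` estimates the rates by least squares on the log-parameter
scale (Levenberg–Marquardt, relative-change tolerance 1e-10). With a free
amplitude the Bateman curve is exchangeable — $(a, b, c_0)$ and
$(b, a, c_0 a/b)$ trace the same curve — so the output is normalised to
$k_{GI} \ge k_{Plasma}$ via that exact identity (all three study compounds
satisfy it). Non-convergence is reported through `converged = FALSE` with
the objective, never as an exception. The recovery harness
(`recovery_study()`) shows median absolute relative errors of ~2% per rate
at cv = 0.05 with n = 50 samples, and bias shrinking monotonically along a
cv ladder (0.2, 0.05, 0.01).

What the generator does *not* emulate: inter-individual variability,
assay detection limits, sparse clinical sampling, or model misspecification
(e.g. enterohepatic recirculation). Passing recovery tests therefore show
identifiability and estimator correctness under the model's own
assumptions, not robustness on real clinical data.

## Numerical choices and problem sizes

* Short-range grid: 0–30 min at 0.01 min (covers all reported events —
  plasma plateaus at 5.5 / 15 / 26 min).
* Solver cross-checks run at RK4 dt = 1e-4 min against the closed form and
  matrix exponential, agreement 1e-6 relative; routine test oracles use
  dt = 1e-3 min to keep the suite fast.
* Long-range: dt = 0.01 h, 15 periods, burn-in 10 cycles; limit-cycle
  period detected from peak-to-peak spacing of the plasma series (median),
  convergence ratio from the last two peak heights.
* Table reproduction rounds half-away-from-zero to the printed number of
  decimals; mismatches beyond one unit in the last printed digit are
  reported, never absorbed.
* Recovery study: 100 replicates at cv = 0.05 for the headline check;
  smaller replicate counts (20–40) for the monotonicity ladder.

## Known limitations

* The model is linear and unsaturated: no saturable (Michaelis–Menten)
  elimination, protein binding, reversible transfer, or enterohepatic
  recirculation.
* Units are min/h only; no general unit framework.
* The published TAβCD precalculated peak and the refined NC rate row cannot
  be derived from the stated formulas; the package reproduces the formulas'
  values and reports the differences, so those two published numbers remain
  unexplained inputs rather than outputs.
* Long-range peak heights depend on the unspecified pulse shape and
  absolute dose; only shape-independent properties are asserted.
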