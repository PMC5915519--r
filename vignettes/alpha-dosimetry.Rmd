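---
title: "Methods: alpha dosimetry, efficacy monitoring and survival statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alpha dosimetry, efficacy monitoring and survival statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphadose)
```

This vignette documents the models, conventions and numerical choices behind
`alphadose`, in the spirit of a statistical-methods section: what is assumed,
which knobs exist, and what the validation suite does and does not
demonstrate.

## The dosimetry model

For an alpha emitter distributed in tissue, essentially all emitted energy is
absorbed within < 100 µm of the decay, so organ self-dose with absorbed
fraction 1 is the appropriate model at whole-organ scale. The absorbed dose
per unit administered activity is the product of two organ-independent
factors and one organ-dependent one:

* the **time-integrated activity per gram** `Ã` (fraction·h/g): the integral
  over all time of the *physical* fraction of injected activity per gram;
* the **mean alpha energy per decay** `Ē` (J): the branch-weighted sum over
  alpha branches;
* unit conversions (3600 s/h, 10⁶ decays·s⁻¹·MBq⁻¹, 10³ g/kg), giving
  `D = Ã · 3600 · 10⁶ · Ē · 10³` in Gy/MBq.

### Radionuclide constants

²¹¹At constants are not usually printed in therapy studies; `at211_scheme()`
uses standard nuclear data: half-life 7.214 h, branches 41.8% at 5.867 MeV
(direct alpha to ²⁰⁷Bi) and 58.2% at 7.450 MeV via electron capture to
²¹¹Po. ²¹¹Po has a 0.52 s half-life — seven orders of magnitude below the
sampling scale — so it is folded into the parent as an instantaneous branch
rather than solved as a decay chain. Ē = 0.418·5.867 + 0.582·7.450 =
6.788 MeV. Electron-capture photons/electrons and the long-lived ²⁰⁷Bi
granddaughter are excluded: the dose reported is alpha-only self-dose.
Alternative constants can be supplied via `decay_scheme()` or a YAML file
(`read_decay_scheme()`); agreement of the resulting coefficients with the
published reference table (see below) supports the default to within a few
percent, though a reference computed with a slightly different energy
constant could differ in the third digit.

### The decay-correction convention

Published biodistribution tables almost universally report **decay-corrected**
%ID/g, and `read_biodistribution()` assumes so unless the file says
otherwise (`# decay_corrected: false`). The assumption is consequential: for
²¹¹At the correction at 24 h is a factor of 10. Treating the packaged table
as decay-corrected reproduces the published tumor coefficient within 5%;
treating it as physical would overshoot roughly three-fold. The flag exists
so either convention can be loaded explicitly.

### Integrating a five-point curve

The curve is sampled at 1, 3, 6, 12 and 24 h; the integral needs a policy for
the unobserved head (0–1 h) and tail (> 24 h):

* **head** (`integration_options(head = ...)`): `"zero-origin"` (default)
  draws a trapezoid from (0, 0) to the first sample, modelling uptake from
  zero at injection; `"plateau"` holds the first sample back to t = 0;
  `"start-at-first"` drops the segment.
* **tail**: `"physical-decay"` (default) assumes no further biological
  clearance, contributing exactly `a(t_last)·t½/ln 2`; this is conservative
  (an upper bound on the tail for any clearing tissue).
  `"fitted-effective-decay"` fits a log-linear effective rate to the last
  `fit_tail_points` samples and falls back to the physical rate, with a
  warning, when the terminal samples do not decrease.

The defaults (zero-origin, physical tail) are the assumption-minimal choice.
Against the published reference coefficients bundled as
`table2_absorbed_dose.csv` they reproduce tumor (10.68 vs 10.21 Gy/MBq),
adrenals (5.30 vs 5.07), blood (0.183 vs 0.18), liver (1.54 vs 1.41) and
kidney (0.64 vs 0.61) within 10%. Two organs do not match under any simple
trapezoid convention we tested: **heart** (3.29 computed vs 4.08 published —
a fitted uptake model must lie above the sampled chords there) and **brain**
(0.026 vs 0.02 — at this magnitude the printed value has only one
significant digit, and the head policy alone moves the result across the
rounding boundary: start-at-first gives 0.024 → 0.02). Both are documented
rather than tuned for; the reference table's own fitting scheme is not
public, and all policies are exposed so users can match other conventions.

**Thyroid** is reported as whole-organ %ID; converting to per-gram needs an
organ mass that the reference does not state, so no default mass is
asserted — `organ_dose_table()` skips such rows with a warning unless
`organ_masses` supplies one.

## Therapy monitoring conventions

* Caliper axes are canonicalised (`length := max`, `width := min`) before
  `V = l·w²/2`, so data-entry order is irrelevant.
* Relative series are per-animal percentages of the day-0 baseline, and group
  summaries average those per-animal ratios (**mean of ratios**). With
  heterogeneous baselines this differs substantially from the ratio of group
  means, and it is the convention behind published relative-tumor-volume
  figures.
* Days without a measurement are linearly interpolated between flanking
  observations; there is no extrapolation outside an animal's observed range.
* Endpoint comparisons: body-weight loss is **strict** (`> 20%`, so an animal
  reaching exactly 20% does not trigger), volume thresholds are **inclusive**
  (`≥ 500` / `≥ 800` mm³) for determinism at the printed bound. Ties between
  the two rules on the same day are attributed to volume.
* The MTD rule is deliberately simple and matches its field use: the highest
  tested activity whose group shows no weight failure; `NA` when every
  activity fails. "Moribund state" criteria are not operationalised — they
  enter only as a manually recorded reason.

## Survival statistics

`kaplan_meier()`, `logrank_test()` and `dunnett_many_to_one()` are
implemented from first principles (the test suite cross-checks them against
`survival` and `multcomp`, which are never used in the computation itself).
Conventions: at tied times events are processed before censorings; the
log-rank statistic uses the hypergeometric variance and the χ²(1)
approximation (a permutation check in the suite confirms the approximation
is adequate at the study's group sizes); an undefined statistic (no events)
returns `NA` rather than an error.

The Dunnett adjustment needs the null distribution of the maximum absolute
of k correlated t statistics sharing a control mean and a pooled variance.
Rather than tabulated quantiles, the adjusted p-value
`P(max_j |T_j| ≥ |t_i|)` is computed by seeded Monte Carlo on the exact joint
null (normal group means, χ² pooled variance), default 100,000 draws —
reproducible, and accurate to ~0.002 in p. The family-wise error calibration
is verified in the suite over 2,000 simulated null experiments.

## The synthetic-data generator

No raw per-animal data are deposited for studies of this kind, so the
generator emulates their statistical structure with known ground truth:

* **Biodistribution**: decay-corrected biexponential uptake
  `u(t) = A₀(e^(−λ_c t) − e^(−λ_u t))` with lognormal inter-animal scatter.
  Tumor defaults (A₀ = 43.2 %ID/g, λ_u = 1.0/h, λ_c = 0.042/h, CV = 0.4,
  n = 5) put the peak near 36 %ID/g at ~3.3 h with ~16 %ID/g at 24 h,
  matching the packaged table's tumor row in location and dispersion. The
  analytic cumulated activity of the corresponding physical curve is
  returned alongside the table.
* **Therapy cohorts**: a two-compartment log-kill convention. A fraction
  `f = e^(−αD)` of the tumor survives dose D and regrows at the control rate
  g after a regrowth delay; the killed fraction regresses exponentially.
  Defaults: g = ln(591.8/48.9)/21 ≈ 0.119/day (the published control group
  grew 48.9 → 591.8 mm³ over 21 days), baseline 50 ± 8 mm³, α = 0.6/Gy,
  delay 16 d, regression 0.2/day — giving nadirs near day 18–21 and a
  day-21 relative volume of ~7% at 0.56 MBq with the published tumor dose
  coefficient. Body weight follows a gamma-shaped loss pulse peaking on day
  3 with depth `0.21·(A/1.85)^1.3` (capped at 95%), reproducing the
  published tolerability pattern: < 5% loss at ≤ 0.56 MBq, 10–20% at
  1.11 MBq, > 20% by day 3–4 at ≥ 1.85 MBq, recovery by ~day 10 at
  tolerated activities. Calipers are back-solved from volume at a fixed 0.7
  width/length ratio; volumes carry 10% and weights 2% multiplicative
  lognormal measurement noise. Log-kill is a generator convention chosen for
  identifiability, not a radiobiological claim about PC12 cells.
* **In-vitro plates**: readouts proportional to `e^(−kc)` with lognormal
  replicate noise (default k = 0.5 per kBq/mL, CV = 10%, 6 replicates on the
  0–20 kBq/mL grid).

All generators are pure functions of (spec, seed). What they deliberately do
**not** emulate: inter-animal growth-rate heterogeneity (so noise-free
control relative volume is e^(g·21) ≈ 1200%, the ratio-of-means figure,
rather than the smaller mean-of-ratios seen with heterogeneous baselines),
mechanistic pharmacokinetics, immune or histological dynamics, and attrition
(trajectories are generated in full; endpoint logic truncates them
analytically). Passing recovery tests therefore shows the pipeline is
mathematically faithful, not that real cohorts satisfy the model.

### Parameter recovery and problem sizes

The validation suite recovers: the generator-true cumulated activity within
2% (noise-free, quarter-hour sampling to 96 h); the log-kill α within 15%
mean error across 20 cohort seeds (groups 0/0.28/0.56/1.11 MBq, n = 5 —
recovery inverts the known kinetics at day 21, which is only identifiable
while the surviving-fraction signal exceeds the regressing-compartment
floor, hence the tolerated-activity groups); and the in-vitro k within 10%
mean error across 50 seeds. Monte-Carlo calibrations use 10,000 label
permutations (log-rank) and 2,000 simulated experiments with 2,000 null
draws each (Dunnett). These sizes keep the full suite under half a minute
while leaving Monte-Carlo error well below the asserted tolerances.

## Numerical and degenerate-input choices

* Round-trip decay correction is exact to machine precision; `t = 0` is the
  identity.
* All-zero activity curves integrate to zero; empty curves are errors, as is
  a single sample when the head segment is discarded.
* Lognormal noise is parameterised by mean and CV with the mean-preserving
  `meanlog = −σ²/2` offset, so CV → 0 degenerates smoothly to the mean.
* The monoexponential fitter seeds `nls` with the through-origin log-linear
  slope and returns it directly when it already interpolates the data
  (noise-free case), avoiding spurious convergence warnings; k is truncated
  at 0.
* Zero pooled variance (all observations identical) makes t statistics
  undefined and raises an error rather than returning Inf.

## Known limitations

* Self-dose only: no cross-organ beta/photon terms, no remainder-of-body
  compartment, no S-value phantoms, and no human extrapolation.
* The dose point estimate propagates no uncertainty from the biodistribution
  SDs (the reference table reports none either); SDs are carried for
  generator calibration only.
* Heart-type uptake curves (convex early washout) are under-integrated by
  chord trapezoids; a fitted uptake model would be needed to match reference
  values there.
* The log-rank p relies on the χ²(1) approximation; at very small samples an
  exact or permutation p (provided in the test utilities) is preferable.
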