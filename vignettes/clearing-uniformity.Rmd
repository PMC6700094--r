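---
title: "Quantifying the uniformity of tissue-clearing expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the uniformity of tissue-clearing expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clearcv)
```

## The scientific problem

Hydrogel-embedding clearing protocols remove lipids from fixed tissue with
SDS, rendering it transparent — and swelling it. Swelling per se is not
disqualifying: every fixation protocol distorts tissue, and PFA alone is
known to shrink it. What matters for downstream anatomy is whether the
expansion is *uniform*: the same linear factor in the cortex and the
striatum, for nuclei and for whole somata, at the millimetre scale of
cortical thickness and the micrometre scale of single cells. If it is,
measurements from cleared tissue can be interpreted as confidently as from
conventional sections, up to a global scale factor.

`clearcv` operationalises that question. Measures of different spatial
dimensionality respond to a linear expansion λ differently — thickness
grows as λ, areal cell density falls as λ², cell volume grows as λ³ — so
raw ratios between cleared and uncleared tissue are not comparable across
measure kinds. The package's core statistic removes the dimensionality:

1. **Relative expansion** per measure: the ratio of condition means,
   `cleared / uncleared` for volume and thickness and the inverse for
   density, so every ratio reads "> 1 means swelling".
2. **Adjusted expansion ratio**: the *d*-th root of the relative
   expansion, *d* being the measure's dimensionality. Under uniform
   isotropic expansion every adjusted ratio equals λ.
3. **Clearing CV**: the coefficient of variation (sample SD over mean,
   *n* − 1 denominator) of the adjusted ratios across all measures. Zero
   would mean perfectly uniform expansion.
4. **Acceptability threshold**: CVs have no universal "low enough", so the
   yardstick is the variability the field already tolerates — the mean of
   the per-measure CVs of the same quantities within *uncleared* tissue
   from a single subject. The verdict is *uniform* when the clearing CV
   does not exceed this threshold; the boundary case counts as uniform,
   the conservative reading of "similar magnitude".

On the ten published relative expansions this yields adjusted ratios
between 1.08 and 1.42, a clearing CV of 0.110 against a threshold of
0.173, and hence a uniform verdict:

```{r published}
res <- reproduce_published_analysis()
res$ratios
round(res$clearing_cv, 3)
res$verdict
```

Two conventions in `reproduce_published_analysis()` deserve a note. The
clearing CV uses the sample (*n* − 1) standard deviation: the population
formula yields 0.104 on the same inputs and is not used anywhere in the
package. And adjusted ratios are rounded to two decimals — the precision
at which the source table was printed — before the CV; unrounded ratios
give 0.111. Both choices are configurable (`round_digits`), and rounding
is **off** by default for new data (`clearing_report()`), where there is
no printed-precision argument for discarding digits.

## The synthetic-data generator

No raw images or measurement tables are deposited for the original
experiment, so validation rests on simulation with known ground truth.
`simulate_tissue_sample()` draws cell centroids from a homogeneous spatial
Poisson process in a reference block, with radii `r0 · (1 + ε)` and, in
cortical regions, a ground-truth cortical thickness. A cleared sample is
the *same* reference point process scaled by λ (per-axis λ is available to
emulate anisotropy). Two design points matter:

- **Paired by construction.** A cleared/uncleared comparison pair shares
  one reference point process (`simulate_tissue_pair(paired = TRUE)`, the
  default): expansion is then the *only* systematic difference between
  conditions, which is the cleanest possible test of the statistic.
  `paired = FALSE` draws two independent Poisson fields, emulating the
  noisier littermate design of a real experiment; the λ⁻² density test in
  the suite uses this independent mode so that it is not trivially exact.
- **Expansion dilutes, it does not delete.** Cells are conserved under
  scaling; apparent density changes arise purely from the λ³ volume change
  (plus block cropping when counting within a fixed physical volume).

Noise defaults are a radius CV of 0.10 and a relative thickness noise of
0.03, chosen as plausible spreads for marker-positive cell populations and
repeated cortical line measurements; radius and thickness noise are drawn
per condition (independent measurement noise), while the centroids are
shared. The generator does **not** model optical realism — no
depth-dependent attenuation, refractive-index artefacts, vascular or
laminar structure — so passing tests demonstrate that the measurement and
statistics chain is correct, not that it is robust to every real-world
imaging artefact.

`render_image_stack()` rasterises a sample onto a voxel grid (0-based
indices, voxel value at the voxel centre, world coordinate = index ×
voxel size, array stored depth–row–column), paints cells as solid
spheres, applies a separable Gaussian point-spread blur (border kernels
renormalised, so total intensity is conserved) and adds Gaussian or
Poisson noise from a seeded stream. Cells smaller than one voxel are
painted on their nearest voxel with a warning rather than silently
dropped.

## Measurement operators

The original workflow measured everything manually in ImageJ; `clearcv`
replaces it with deterministic operators.

- `count_cells_2d()` counts cells whose sphere *intersects* a focal plane
  (|z − plane| < r) per unit field area. Plane intersection was chosen
  over fixed-slab counting because it makes areal density scale exactly as
  λ⁻² under isotropic expansion — the geometric premise of square-rooting
  2D density ratios. The slab variant remains available
  (`method = "slab"`).
- `segment_cells_3d()` thresholds the stack (fixed value, or the
  between-class-variance-maximising bimodal split when `threshold = NULL`),
  labels 26-connected components, discards specks below `min_voxels = 27`
  (a 3×3×3 cube — smaller than any realistic cell at the default 1 µm
  voxel), and returns voxel-count volumes. For noiseless spheres of
  radius ≥ 4 voxels the result matches a direct voxel-centre-in-sphere
  count within 2%.
- `measure_cortical_thickness()` is the length of a straight line drawn
  across the cortex (or the sample's ground truth, for simulated data).
- `measure_penetration_depth()` is the maximum depth of detected
  brightly-positive cells, guarded by `min_cells = 3` so a single stray
  detection cannot set the depth. The intensity criterion for "brightly
  positive" is qualitative in the source workflow and is therefore a
  configuration parameter here, not a claimed reproduction. A fitted
  front position was deliberately not used: the operational definition is
  "depth at which positive cells could be seen".

## The penetration model

Antibody staining depth over incubation time is modelled as
`D(t) = A(1 − e^(−kt))`, constrained through the origin (no staining at
t = 0; the published curve `0.8 − 0.8·e^(−0.38x)` has no intercept
either). `fit_penetration()` minimises unweighted least squares — the
original fitting method and weighting are unstated, so unweighted is
assumed and labelled as such — using `minpack.lm` with the analytic
Jacobian, positivity bounds, parameter tolerance 10⁻¹⁰, and start values
A₀ = max depth, k₀ = 1/mean(t). A two-parameter smooth problem does not
need more; robustness was preferred over speed. Non-convergence is
reported via the `converged` flag, and a flat series (constant depths,
which cannot identify the rate) warns and marks the fit non-converged
instead of returning a silently meaningless rate.

```{r penetration}
fit <- fit_penetration(simulate_penetration_series(
  penetration_model(A = 0.8, k = 0.38), times = c(1, 3, 7, 11)))
glance(fit)
```

## The end-to-end study

`run_study()` chains simulate → measure → analyse under one seeded config.
The default design mirrors a two-littermate comparison: four density
measures (20 fields per condition, 40 for cortical parvalbumin), four
volume measures (30 cells per condition each) and two thickness measures
(9 hemispheres per condition), ten measures in all, with a true λ of 1.2.
Density values come from plane-intersection counting on the generated
samples and volumes from the per-cell sphere volumes; the rendering →
segmentation imaging route is validated separately by the scaling-law
tests and kept out of the default path so that a full multi-seed recovery
study stays fast. Per measure, Welch's unequal-variance t-test compares
conditions (the test used throughout the original comparisons) with a
Shapiro–Wilk normality check that is *reported but not acted on* — the
source analysis ran parametric tests even where one distribution failed
normality, and the pipeline mirrors that advisory role rather than
endorsing it. No multiple-testing correction is applied, matching the
source analysis; `p.adjust`-style Holm correction can be applied by the
user on the comparisons table.

```{r study}
st <- run_study(study_config(expansion = 1.2, seed = 7))
glance(st)
head(tidy(st), 3)
```

With the noise switched off the recovery is exact (every adjusted ratio
equals λ to machine precision and the clearing CV collapses to ~10⁻¹⁶),
and with anisotropic expansion (different per-axis λ) the clearing CV
rises monotonically with the anisotropy — the statistic detects
non-uniformity, which is the property it exists for.

Outputs written by `run_study(output_dir = ...)` are formatted at six
significant digits, making repeated runs byte-identical; every run writes
a manifest with the seed, the generator settings and a config hash.
P-values appear at three significant figures in machine output; the
star convention is confined to the human-readable summary.

## Grouping choice behind the threshold

Which ROI grouping produced each uncleared CV in the original analysis
(per image, per slice, or pooled per measure) is not stated.
`acceptability_threshold()` pools per measure by default — the most
direct reading of "the CV of each of the individual measures" — and the
`group` argument exposes alternative groupings without claiming fidelity
to the original choice. A bootstrap confidence interval over ROIs for the
clearing CV is deliberately *not* part of the report: no uncertainty
interval is claimed for the published value, and resampling extensions
are left to the user.

## Problem sizes and numerical choices

The test suite and the acceptance script use deliberately small problems:
blocks of a few hundred micrometres with 10²–10³ cells, 60³–192³ voxel
stacks, 200–1000 Monte-Carlo seeds for distributional checks, and
20-seed recovery studies. These sizes were chosen so that Monte-Carlo
standard errors are small relative to the tested tolerances (bands are
set at 3 standard errors computed a priori from Poisson counting
statistics, never fitted to an observed run). Degenerate inputs are
contracts, not crashes: empty stacks segment to an empty table, samples
with too few detected cells yield `NA` with a warning, and a zero-mean CV
or a single-value set is an error naming the offending set.

## Known limitations

- The generator's cells are spheres; touching-cell splitting (watershed)
  is out of scope, so segmentation-based volumetry assumes separable
  cells at the simulated densities.
- Penetration is a phenomenological saturating front, not a
  diffusion–binding PDE; antibody depletion in dense antigen fields is
  explicitly outside the model.
- The published group means and p-values for the density/volume/thickness
  comparisons cannot be reproduced (raw data are available only on
  request); the package validates *directionality* on synthetic data —
  lower density, higher volume, thicker cortex in cleared tissue —
  and reproduces the published table-level statistics exactly.
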