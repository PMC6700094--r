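# clearcv

Hydrogel-based tissue clearing (CLARITY-style protocols) makes fixed brain
tissue transparent for deep imaging, but it also swells the tissue. That
expansion is harmless for downstream anatomy *only if it is uniform* —
across brain regions, across cell types, and across spatial scales from
whole-cortex thickness down to single nuclei. `clearcv` is an R package for
neuroscientists who need to quantify that uniformity: it measures cell
density, cell volume, cortical thickness and antibody penetration in
cleared versus uncleared tissue, reduces them to a single uniformity
statistic, and provides a fully seeded synthetic-tissue simulator to
validate the whole measurement chain against known ground truth.

## The statistic

For each measure *m* with spatial dimensionality *d* (1 for thickness, 2
for areal cell density, 3 for cell volume), the **relative expansion** is
the ratio of condition means, oriented so that values above 1 mean
swelling:

- volume, thickness: `R_m = mean(cleared) / mean(uncleared)`
- density: `R_m = mean(uncleared) / mean(cleared)` (expansion dilutes cells)

Each ratio is normalised to one spatial dimension as the **adjusted
expansion ratio** `A_m = R_m^(1/d)`: under uniform isotropic expansion by a
linear factor λ, every `A_m` equals λ regardless of what was measured. The
**clearing CV** is the coefficient of variation (sample SD / mean) of the
`A_m` across all measures; it is compared against an **acceptability
threshold**, the mean CV of the same measures within uncleared tissue —
the variability the field routinely accepts. Expansion is judged
*uniform* when the clearing CV does not exceed that threshold.

Antibody penetration depth over incubation time *t* (days) is modelled as
the saturating exponential `D(t) = A·(1 − e^(−kt))` with asymptote `A`
(mm) and rate `k` (per day), fitted by bounded nonlinear least squares.

## Worked example

Reproduce the published uniformity analysis from the ten printed relative
expansion values:

```r
library(clearcv)
res <- reproduce_published_analysis()
res$ratios[c(1, 5, 9), ]
#> # A tibble: 3 × 4
#>   measure_id             kind      dimensionality relative_expansion adjusted_expansion_ratio
#>   density_cortical_ctip2 density                2               1.83                     1.35
#>   volume_cortical_ctip2  volume                 3               1.68                     1.19
#>   thickness_motor_cortex thickness              1               1.14                     1.14
round(res$clearing_cv, 3)
#> [1] 0.11
res$verdict
#> [1] "uniform"
```

The clearing CV of 0.110 sits below the uncleared-tissue threshold of
0.173, so the expansion is judged uniform: clearing spread every measure —
2D densities, 3D volumes, 1D thicknesses, in cortex and striatum — by a
similar linear factor.

Run a fully synthetic study with known ground truth (λ = 1.2) end to end:

```r
st <- run_study(study_config(expansion = 1.2, seed = 7))
glance(st)
#> # A tibble: 1 × 4
#>   n_measures clearing_cv threshold verdict
#>        <int>       <dbl>     <dbl> <chr>
#> 1         10      0.0174     0.173 uniform
```

All ten adjusted ratios land near the true 1.2 and the clearing CV is an
order of magnitude below the threshold. `tidy(st)` gives the per-measure
ratio table, `autoplot(st)` the per-condition measurement distributions,
and `run_study(cfg, output_dir = "out")` writes the measurement CSV, the
ratio table, the JSON report, the Welch comparison table and a run
manifest.

Fit the antibody-penetration curve:

```r
fit <- fit_penetration(simulate_penetration_series(
  penetration_model(A = 0.8, k = 0.38), times = c(1, 3, 7, 11)))
glance(fit)
#> # A tibble: 1 × 5
#>    A_mm k_per_day      rss     n converged
#> 1   0.8      0.38 1.23e-32     4 TRUE
```

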