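# junctionzone

Quantifying photoreceptor-layer thinning outside geographic atrophy (GA)
from en-face OCT thickness maps.

## What this is for

Eyes with GA — the atrophic late stage of age-related macular
degeneration — lose photoreceptors not only inside the atrophic lesion but
also in the surrounding retina: the outer nuclear layer (ONL),
photoreceptor inner segments (IS) and outer segments (OS) thin in a
junctional zone around the lesion border and, more diffusely, across the
macula. For anyone analyzing a GA treatment trial, the question is whether
a drug that slows lesion growth *also* protects these extra-lesional
photoreceptors — and the two effects are confounded if thickness is read
at fixed retinal locations, because a slower-growing lesion leaves any
fixed location farther from the boundary.

`junctionzone` implements the analysis that disentangles them:

1. **Normative z-score standardization.** Each thickness map `t(x)` (µm)
   becomes `z(x) = (t(x) − μ(x, age)) / σ(x)`, with `μ` a per-pixel linear
   age-adjusted normative mean and `σ` the location-specific normative SD,
   fitted from a reference set of non-atrophic eyes
   (`fit_normative()`, `standardize()`).
2. **Traveling contour rings.** At every visit, extra-lesional pixels are
   binned by exact Euclidean distance `d` to the current lesion into bands
   `((k−1)w, kw]`, `w = 0.43°`; rings 1, 6, 12 are the 0.43°, 2.58° and
   5.16° contour lines (≈125, 751, 1502 µm at 291 µm/°). The rings are
   recomputed per visit, so they travel with the growing boundary and the
   extracted mean ring z is independent of the growth rate
   (`compute_contour_rings()`, `extract_ring_means()`).
3. **Longitudinal mixed models.** Per layer × contour line, change in ring
   z from baseline is modeled as
   `change ~ arm * visit + baseline_z + (1 | participant)` (REML), with
   pairwise arm contrasts at each visit, Satterthwaite (or Kenward-Roger)
   denominator df and single-step multivariate-t (Tukey-type) adjustment
   for the family of three contrasts
   (`fit_change_lmm()`, `arm_contrasts()`).
4. **Trial plumbing.** mITT / per-protocol / fellow-eye population
   filters, the 3 × 3 × 3 model grid (27 models), a sqrt-area atrophy
   progression model with percent growth reduction, and Bland–Altman
   geometry QC (`run_full_analysis()`).

Because no participant-level trial data are distributable, the package
ships a synthetic-cohort generator (`generate_cohort()`) that emulates the
full longitudinal data structure — growing lesions that are linear on the
sqrt-area scale, a steep-then-shallow junctional thinning gradient, an
arm-dependent macula-wide drift, stable fellow eyes, realistic noise
structure — so the whole pipeline is testable and its estimators can be
calibrated against known injected effects.

## Worked example

Simulate a 30-participant trial (10 per arm, study + fellow eyes,
200 × 200 maps) and run the full analysis:

```r
library(junctionzone)

cfg    <- trial_config(n_per_arm = 10, seed = 1)
cohort <- generate_cohort(cfg)
print(cohort)
#> Synthetic GA cohort: 30 participants, 60 eyes, 284 eye-visits
#>   arms: sham_pooled, monthly, eom
#>   maps: yes; normative eyes: 40

report <- run_full_analysis(cohort = cohort)
print(report)
#> Contour-line analysis report: 27 mixed models (3 x 3 x 3)
#>   primary outcome (ONL, 5.16 deg, month 12, monthly - sham):
#>     +0.306 z [0.069, 0.543], adj. p = 0.007933
#>   growth reduction vs sham: monthly 25.0%, eom 22.2%
#>   area QC bias: 0.004 mm [-0.008, 0.015]
```

Reading the output: the generator injects a monthly-vs-sham macula-wide
drift difference of 0.30 z/year, and the primary-outcome model (ONL along
the 5.16° contour line at month 12, mITT) recovers +0.306 z with an
adjusted 95% CI excluding zero — treated eyes thinned less along their
*traveling* contour line, i.e. the effect is not a byproduct of slower
lesion growth. The progression model recovers the injected 25% (monthly)
and 22.2% (every-other-month) reductions of the 0.30 mm/year sham
sqrt-area growth, and the mask-derived areas agree with the reference
measurement (bias ≈ 0.004 mm on the sqrt scale).

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate.R` … `05_figures.R`), each writing its tables under
`results/`; run them in order from the repository root.

## Learn more

The methods vignette
(`vignettes/junctional-zone-methods.Rmd`) documents the model, the
generator's assumptions and what passing tests do and do not show, the
numerical conventions (distance binning, mirroring, df approximations,
multiplicity adjustment) and known limitations.
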