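---
title: "Quantifying photoreceptor thinning around geographic atrophy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying photoreceptor thinning around geographic atrophy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Geographic atrophy (GA) — the atrophic late stage of age-related macular
degeneration — is usually tracked by the area of retinal pigment epithelium
(RPE) loss. But the disease also thins the photoreceptor laminae *outside*
the atrophic boundary: the outer nuclear layer (ONL), inner segments (IS)
and outer segments (OS) are reduced in a junctional zone around the lesion
and, more subtly, across the whole macula. A treatment that slows atrophy
growth may or may not also protect these photoreceptors, and the two
effects are easily confounded: if a lesion grows more slowly, a band at a
fixed retinal location ends up farther from the boundary and looks
"thicker" for purely geometric reasons.

`junctionzone` implements an analysis that separates the two effects. The
key ideas are:

1. **Z-score standardization.** Every en-face thickness map is transformed
   pixelwise to `z(x) = (t(x) - mu(x, age)) / sigma(x)`, where `mu` and
   `sigma` are the age-adjusted mean and location-specific SD of a
   normative reference population. This removes normal topography (the
   foveal peak, nasal/temporal asymmetry) and normal aging, so maps from
   different retinal locations and different patients are comparable.
2. **Traveling contour rings.** At every visit, the extra-lesional field
   is partitioned into evenly spaced distance bands around the *current*
   atrophy boundary: ring k holds the pixels whose Euclidean distance to
   the nearest lesion pixel lies in `((k-1)w, kw]`, with `w = 0.43`
   degrees. Because the bands are recomputed per visit they travel outward
   with the lesion, so the ring-k feature always describes tissue at the
   same distance from the boundary, independent of how fast the boundary
   moved. Rings 1, 6 and 12 (0.43, 2.58, 5.16 degrees; roughly 125, 751
   and 1502 µm at the emmetropic scale of 291 µm/degree) are carried into
   the statistics.
3. **Change-from-baseline mixed models.** For each layer and ring, the
   change in mean ring z from baseline is modeled with fixed effects for
   treatment arm, visit (categorical), their interaction and the baseline
   ring z, plus a random intercept per participant (REML). The three
   pairwise arm contrasts at a visit are tested with small-sample
   denominator degrees of freedom and a single-step multiplicity
   adjustment.

Under this construction, genuine photoreceptor protection shows up as a
positive treated-minus-sham contrast in change of ring z — even though the
rings themselves moved — while a pure slowing of atrophy growth does not.

## The synthetic cohort: what it emulates

No participant-level trial data are distributed with the package, so every
stage runs against a synthetic cohort generator whose defaults emulate the
design of a 12-month randomized anti-complement GA trial with follow-up to
month 18:

* three arms (pooled sham, monthly and every-other-month dosing), 2:2:2 by
  default, visits at months 0, 2, 6, 12, 18;
* 20 × 20 degree fovea-centered maps at 0.1 degree/pixel (200 × 200);
* baseline square-root lesion area 2.80 mm (SD 0.72, truncated to
  1.6–4.2 mm), growing linearly on the sqrt scale at 0.30 mm/year under
  sham with 25% (monthly) and 22.2% (every-other-month) growth reduction;
* a junctional deficit `depth * g(d)` with
  `g(d) = 0.6 exp(-d/0.7) + 0.4 exp(-d/3)` (degrees): a steep gradient
  within about 2 degrees of the boundary flattening at eccentric
  locations, depth 2 z at the boundary;
* a macula-wide thinning drift per arm (z/year): −0.30 under sham, 0 under
  monthly dosing, −0.04 under every-other-month dosing. The arm
  differences of this drift are the treatment effect the models estimate —
  0.30 z and 0.26 z at month 12, mirroring the magnitude of the effects
  the method is meant to resolve;
* noise at three levels: a per-eye random intercept (SD 0.3 z), a per-scan
  acquisition deviation shared by all layers of a visit (SD 0.15 z, the
  dominant term in ring-mean precision), and i.i.d. per-pixel noise
  (SD 0.25 z);
* fellow eyes with naturally growing lesions but zero drift — their
  traveling-ring features are longitudinally flat, which is the
  specificity control;
* a normative reference set (40 eyes, ages 55–95) drawn as mean surface +
  linear age effect + location-specific population variation.

In z-space the generative model for a study-eye map at visit time `t`
(years) is

```
z(x, t) = b_eye + s_{eye,t} + drift_arm * t - depth * g(d(x, t)) + eps(x)
```

and thickness is `mu(x) + beta_age * age + sigma_layer * z`. Because the
ring at distance `d_k` travels, the deficit term is (up to discretization)
constant over visits and cancels in change scores; the expected month-12
change is `drift_arm`, which is how a known effect size is injected.

### What the generator does not emulate

Real OCT data carry segmentation errors, vessel shadows, media opacity,
motion artifacts, spatially correlated noise, non-circular and truly
multifocal lesions (a two-focus mode exists but is off by default),
informative dropout, and normative models of unknown functional form.
Passing tests on the synthetic cohort therefore demonstrate that the
*pipeline* is correct — geometry exact, estimators unbiased, error rates
calibrated under the stated model — not that the scientific conclusions
transfer to any particular real data set.

## Design choices

**Distance transform, not iterated dilation.** "Evenly spaced contour
lines derived through dilation" can be implemented by iterated
morphological dilation or by binning an exact Euclidean distance
transform. The package defaults to the distance transform: it is
anisotropy-free (a discrete disc kernel bulges along diagonals) and has a
clean brute-force oracle (nearest-lesion-pixel search), which the test
suite exercises pixel by pixel. An iterated-dilation mode
(`method = "dilation"`) is kept for comparison; on disk lesions the two
agree for >90% of banded pixels.

**Half-open bands.** Rings are `((k-1)w, kw]`; boundary pixels (distance
0) belong to the lesion, not to ring 1. This makes the rings a partition
of the extra-lesional field within `Kw`, which several invariants rely
on. Ring means are unweighted arithmetic means over available pixels;
frame-truncated rings (flagged `frame_clipped`) simply average over what
remains, and empty rings are dropped rather than imputed.

**291 µm per degree.** The emmetropic conversion is fixed at 291 µm/deg,
which reproduces the conventional distances 582 µm (2 deg), 751 µm
(2.58 deg) and 1502 µm (5.16 deg). (At this scale 0.43 deg is 125 µm;
the figure of 126 µm sometimes quoted for the first contour line is a
rounding artifact and is not matched.)

**Linear, homoscedastic age model.** The normative model is a per-pixel
linear fit of thickness on age with a single location-specific residual
SD; nothing in the problem pins down a more elaborate form, and the model
sits behind a small interface (`fit_normative()` / `standardize()`) where
a nonlinear or heteroscedastic variant could be swapped in. The SD map is
floored (default 1 µm) purely for numerical safety. Left eyes are mirrored
to the right-eye orientation before fitting because retinal topography is
nasal/temporal-asymmetric; z-maps are returned in the eye's native
orientation so they stay aligned with the lesion masks.

**Satterthwaite df by default.** The cited analysis convention for such
models is the Kenward-Roger approximation. Kenward-Roger is available
(`df_method = "kenward-roger"`), but the default is Satterthwaite: for the
balanced random-intercept designs generated here the two agree to a
fraction of a degree of freedom (a test asserts this), and Satterthwaite
is several times faster across a 27-model grid and hundreds of simulation
replicates. The multiplicity adjustment is the single-step
multivariate-t method over the 3-contrast correlation matrix — the exact
analogue of the Tukey procedure for a family of three estimates; its
quasi-random integration runs on a locally fixed RNG stream so reports
are bit-reproducible. REML estimation throughout, as the df
approximations require. Singular fits (zero random-intercept variance)
are flagged, never silently refit.

**Per-protocol thresholds.** The per-protocol population requires at
least 75% of expected injections, implemented as
`floor(0.75 * expected)`: 9 of 12 for the monthly regimen and 4 of 6 for
the every-other-month regimen, matching the conventional cut-offs (note
4/6 is the stated cut-off even though it is 67%).

**Population grid.** The main 27-model grid crosses mITT, per-protocol
and fellow-eye populations with three layers and three contour lines; the
per-protocol-without-exudation population is run as a supplementary grid.
Fellow eyes reuse the study-eye model formula with the fellow
participant's randomized arm, which is what makes them a specificity
control: every fellow contrast should be null.

**Progression percentages.** Whether a "percent growth reduction" is
computed from month-12 contrasts or from annualized slopes is a reporting
convention; `fit_ga_progression()` emits both (`pct_reduction_month12`,
`pct_reduction_slope`).

**Baseline covariate.** "Baseline layer thickness" enters as the
standardized baseline ring z of the same layer and ring — the modeled
quantity itself — since the response is in z units.

## Numerical and degenerate-input behavior

* Distance binning uses `ceiling(d / w)` on exact Euclidean distances;
  ties at band edges (d exactly `kw`) go to ring k by the half-open
  convention.
* An empty mask, a full-frame mask, constant reference ages, geometry
  mismatches and unknown population names are errors; an age outside the
  normative range warns (extrapolation) but proceeds; eyes without a
  baseline observation are dropped with a warning listing them.
* The generator is bit-reproducible from `trial_config(seed = )`; the
  analysis report is deterministic given config and seed (a test runs the
  pipeline twice and compares tables).
* Mixed models converge with lme4 defaults; the convergence tolerance is
  not altered. Zero-residual degenerate constructions are exercised in
  tests with noise at 1e-7 to stay inside lme4's supported regime.

## Problem sizes

The bundled analysis scripts and the acceptance script use 10
participants per arm (60 eyes with fellows) on the full 200 × 200 grid —
enough for every structural property (27 models, traveling rings, QC) at
interactive runtimes. Calibration studies (effect recovery and coverage,
200 replicates; familywise error, 500 replicates) run on the ring-level
marginal simulator `simulate_ring_features()`, which draws ring means
directly from the annulus geometry instead of synthesizing rasters; a
dedicated test confirms the marginal matches the raster pipeline.
Statistical power at these sizes: with 15 participants per arm and
acquisition noise 0.15 z, the month-12 contrast SE is about 0.08 z, so
the injected 0.30 z effect is detected essentially always, while the
fellow grid stays null.

## Known limitations

* Circular (optionally two-focus) lesions only; real GA is irregular and
  the ring geometry, while correct for any mask, is only *tested* against
  analytic oracles on disks and rectangles.
* The normative model is linear in age and homoscedastic; reference data
  of a different shape would need a new `fit_normative()` backend.
* Anisotropic native scan spacing is out of scope: inputs are assumed
  resampled to isotropic en-face grids, and ring means are unweighted by
  A-scan density.
* No imputation and no informative-missingness modeling: eyes contribute
  the visits they have.
* Multiplicity is controlled within each model (family of three
  contrasts), not across the 27-model grid.
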