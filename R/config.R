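#' Configuration for a synthetic geographic-atrophy trial
#'
#' Bundles every parameter of the synthetic-cohort generator: trial design
#' (arms, visit schedule, sample size), imaging geometry (field size, pixel
#' pitch), lesion kinetics (baseline size and square-root-area growth rates),
#' the junctional thinning gradient, the slow macula-wide thinning drift, and
#' the noise structure. Defaults emulate a 12-month anti-complement
#' geographic-atrophy trial with follow-up to month 18: three arms (pooled
#' sham, monthly dosing, every-other-month dosing), visits at months
#' 0/2/6/12/18, 20 x 20 degree fovea-centered maps, baseline square-root
#' lesion area 2.80 (SD 0.72) mm growing at 0.30 mm/year under sham with
#' 25% (monthly) and 22.2% (every-other-month) growth reduction.
#'
#' @param n_per_arm Participants per arm.
#' @param arms Arm labels. The two sham regimens are generated pooled under a
#'   single label, matching how such trials are analyzed.
#' @param visit_months Ordered visit schedule in months; must include 0
#'   (baseline) and 12 (primary endpoint).
#' @param grid_size_deg Width/height of the square en-face field, degrees.
#' @param pixel_pitch_deg Pixel size in degrees per pixel.
#' @param age_mean,age_sd Baseline age distribution, years.
#' @param baseline_sqrt_area_mean,baseline_sqrt_area_sd Study-eye baseline
#'   square-root lesion area distribution, mm (truncated to 1.6--4.2 mm).
#' @param sham_growth_rate Square-root-area growth under sham, mm/year.
#' @param treatment_growth_reduction Named fractional growth reduction per
#'   arm, each in `[0, 1)`.
#' @param junctional_deficit_depth_z Depth of the junctional thinning deficit
#'   at the atrophy boundary, z-score units.
#' @param junctional_steep_scale_deg,junctional_shallow_scale_deg Decay
#'   scales (degrees) of the two-exponential junctional gradient: a steep
#'   component within about 2 degrees of the boundary and a shallow one
#'   beyond.
#' @param junctional_steep_weight Weight of the steep component in `[0, 1]`.
#' @param macula_wide_drift Named per-arm macula-wide thinning drift,
#'   z-units/year (negative = thinning). The arm differences here are the
#'   treatment effect the longitudinal models estimate.
#' @param noise_sd Per-pixel i.i.d. measurement noise, z-units.
#' @param eye_intercept_sd Per-eye random intercept SD, z-units.
#' @param visit_effect_sd Per-eye-visit (acquisition-level) random deviation
#'   SD, z-units; this is what limits the precision of ring means.
#' @param n_normative Number of eyes in the synthetic normative reference
#'   set.
#' @param normative_age_range Age range (years) spanned by the normative set.
#' @param normative_noise_scale Multiplier on the per-layer reference SD
#'   governing the normative set's between-eye, location-specific
#'   variation. At the default 1 the fitted normative SD map equals the SD
#'   in which z-scores are expressed; 0 makes the reference maps
#'   deterministic in age.
#' @param exudation_rate Fraction of study eyes flagged as ever developing
#'   exudation.
#' @param low_compliance_rate Fraction of participants receiving fewer than
#'   their expected injections (exercises the per-protocol filter).
#' @param multifocal Logical; if `TRUE` each study lesion is generated as two
#'   foci whose union defines the atrophy mask.
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   config.
#'
#' @return An object of class `trial_config` (a validated named list).
#' @examples
#' cfg <- trial_config(n_per_arm = 4, pixel_pitch_deg = 0.4)
#' cfg$visit_months
#' @export
trial_config <- function(n_per_arm = 20,
                         arms = c("sham_pooled", "monthly", "eom"),
                         visit_months = c(0, 2, 6, 12, 18),
                         grid_size_deg = 20,
                         pixel_pitch_deg = 0.1,
                         age_mean = 79.4,
                         age_sd = 7.5,
                         baseline_sqrt_area_mean = 2.80,
                         baseline_sqrt_area_sd = 0.72,
                         sham_growth_rate = 0.30,
                         treatment_growth_reduction = c(sham_pooled = 0,
                                                        monthly = 0.25,
                                                        eom = 0.222),
                         junctional_deficit_depth_z = 2,
                         junctional_steep_scale_deg = 0.7,
                         junctional_shallow_scale_deg = 3,
                         junctional_steep_weight = 0.6,
                         macula_wide_drift = c(sham_pooled = -0.30,
                                               monthly = 0,
                                               eom = -0.04),
                         noise_sd = 0.25,
                         eye_intercept_sd = 0.3,
                         visit_effect_sd = 0.15,
                         n_normative = 40,
                         normative_age_range = c(55, 95),
                         normative_noise_scale = 1,
                         exudation_rate = 0.08,
                         low_compliance_rate = 0.15,
                         multifocal = FALSE,
                         seed = 1L) {
  cfg <- list(
    n_per_arm = as.integer(n_per_arm), arms = arms,
    visit_months = as.numeric(visit_months),
    grid_size_deg = grid_size_deg, pixel_pitch_deg = pixel_pitch_deg,
    age_mean = age_mean, age_sd = age_sd,
    baseline_sqrt_area_mean = baseline_sqrt_area_mean,
    baseline_sqrt_area_sd = baseline_sqrt_area_sd,
    sham_growth_rate = sham_growth_rate,
    treatment_growth_reduction = treatment_growth_reduction,
    junctional_deficit_depth_z = junctional_deficit_depth_z,
    junctional_steep_scale_deg = junctional_steep_scale_deg,
    junctional_shallow_scale_deg = junctional_shallow_scale_deg,
    junctional_steep_weight = junctional_steep_weight,
    macula_wide_drift = macula_wide_drift,
    noise_sd = noise_sd, eye_intercept_sd = eye_intercept_sd,
    visit_effect_sd = visit_effect_sd,
    n_normative = as.integer(n_normative),
    normative_age_range = normative_age_range,
    normative_noise_scale = normative_noise_scale,
    exudation_rate = exudation_rate,
    low_compliance_rate = low_compliance_rate,
    multifocal = isTRUE(multifocal),
    seed = as.integer(seed)
  )
  class(cfg) <- "trial_config"
  validate_trial_config(cfg)
  cfg
}

validate_trial_config <- function(cfg) {
  stopifnot(inherits(cfg, "trial_config"))
  if (cfg$n_per_arm < 1) stop("n_per_arm must be positive", call. = FALSE)
  if (cfg$pixel_pitch_deg <= 0) {
    stop("pixel_pitch_deg must be positive", call. = FALSE)
  }
  if (cfg$grid_size_deg <= 0) {
    stop("grid_size_deg must be positive", call. = FALSE)
  }
  v <- cfg$visit_months
  if (any(diff(v) <= 0)) {
    stop("visit_months must be strictly increasing", call. = FALSE)
  }
  if (!(0 %in% v) || !(12 %in% v)) {
    stop("visit_months must include baseline (0) and month 12", call. = FALSE)
  }
  sds <- c(cfg$age_sd, cfg$baseline_sqrt_area_sd, cfg$noise_sd,
           cfg$eye_intercept_sd, cfg$visit_effect_sd,
           cfg$normative_noise_scale)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  red <- cfg$treatment_growth_reduction
  if (any(red < 0 | red >= 1)) {
    stop("treatment_growth_reduction must lie in [0, 1)", call. = FALSE)
  }
  if (!all(cfg$arms %in% names(red))) {
    stop("treatment_growth_reduction must name every arm", call. = FALSE)
  }
  if (!all(cfg$arms %in% names(cfg$macula_wide_drift))) {
    stop("macula_wide_drift must name every arm", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.trial_config <- function(x, ...) {
  cat("Synthetic GA trial configuration\n")
  cat(sprintf("  arms: %s (n = %d per arm)\n",
              paste(x$arms, collapse = ", "), x$n_per_arm))
  cat(sprintf("  visits (months): %s\n",
              paste(x$visit_months, collapse = ", ")))
  n_px <- grid_dim(x)
  cat(sprintf("  field: %g deg at %g deg/px (%d x %d)\n",
              x$grid_size_deg, x$pixel_pitch_deg, n_px, n_px))
  cat(sprintf("  sham sqrt-area growth: %g mm/y; reductions: %s\n",
              x$sham_growth_rate,
              paste(sprintf("%s %g", names(x$treatment_growth_reduction),
                            x$treatment_growth_reduction), collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

grid_dim <- function(cfg) as.integer(round(cfg$grid_size_deg / cfg$pixel_pitch_deg))

# Pixel-center coordinates (degrees, fovea at 0) along one grid axis.
grid_axis_deg <- function(n, pitch) (seq_len(n) - (n + 1) / 2) * pitch

# Eccentricity (degrees from a center point) for every pixel of an n x n grid.
eccentricity_grid <- function(n, pitch, center_deg = c(0, 0)) {
  ax <- grid_axis_deg(n, pitch)
  dx <- ax - center_deg[1]   # rows
  dy <- ax - center_deg[2]   # columns
  sqrt(outer(dx^2, dy^2, "+"))
}

# --- Generator truth for the normative topography --------------------------
#
# Smooth radially varying mean surfaces per layer (um) plus a nasal/temporal
# asymmetry so that mirroring left eyes to a common orientation is not a
# no-op. Expressed in the common (right-eye) orientation.

layer_mean_surface <- function(layer, n, pitch) {
  ecc <- eccentricity_grid(n, pitch)
  ax <- grid_axis_deg(n, pitch)
  asym <- matrix(tanh(ax / 5), n, n, byrow = TRUE)  # columns = horizontal
  switch(layer,
    ONL = 40 + 60 * exp(-(ecc / 4.5)^2) + 5 * asym,
    IS  = 25 + 10 * exp(-(ecc / 3)^2) + 1.5 * asym,
    OS  = 20 + 15 * exp(-(ecc / 2.5)^2) + 2 * asym,
    stop("unknown layer: ", layer, call. = FALSE)
  )
}

# True age slopes (um/year, thinning) and measurement SD (um) per layer.
layer_age_slope <- function(layer) {
  c(ONL = -0.25, IS = -0.05, OS = -0.10)[[layer]]
}
layer_sd_um <- function(layer) c(ONL = 3, IS = 1.5, OS = 1.5)[[layer]]

#' Read or write a trial configuration as YAML
#'
#' @param cfg A [trial_config()] object.
#' @param path File path.
#' @return `read_trial_config()` returns a `trial_config`;
#'   `write_trial_config()` returns `path` invisibly.
#' @export
write_trial_config <- function(cfg, path) {
  validate_trial_config(cfg)
  raw <- unclass(cfg)
  # yaml drops names on atomic vectors; store per-arm vectors as maps
  for (nm in c("treatment_growth_reduction", "macula_wide_drift")) {
    raw[[nm]] <- as.list(raw[[nm]])
  }
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_trial_config
#' @export
read_trial_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("treatment_growth_reduction", "macula_wide_drift")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(trial_config, raw)
}
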