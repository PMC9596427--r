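# Synthetic longitudinal GA cohort generator.
#
# The generative model, in z-score space relative to the normative topography:
#
#   z(x, visit) = b_eye + s_{eye,visit} + drift_arm * years
#                 - depth * g(d(x, visit)) + eps(x)
#
# where d is the Euclidean distance (degrees) to the current atrophy
# boundary, g is a two-exponential junctional gradient (steep within ~2 deg,
# shallow beyond), drift_arm is the slow macula-wide thinning rate of the
# arm, b_eye ~ N(0, eye_intercept_sd), s ~ N(0, visit_effect_sd) is an
# acquisition-level deviation shared by all layers of a scan, and eps is
# i.i.d. pixel noise. Thickness is mean_surface + age_slope * age + sd * z.
# Lesions are disks whose radius grows linearly so that sqrt(area) is linear
# in time at the arm-specific rate; fellow-eye lesions grow at the natural
# (sham) rate but have zero drift, so their traveling-ring features are
# longitudinally stable.

# Union-of-disks mask on an n x n grid. centers_deg: k x 2 matrix (row, col
# offsets from fovea in degrees); radii_deg: length-k vector.
disk_mask <- function(n, pitch, centers_deg, radii_deg) {
  centers_deg <- matrix(centers_deg, ncol = 2)
  m <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(centers_deg))) {
    if (radii_deg[i] <= 0) next
    ecc <- eccentricity_grid(n, pitch, centers_deg[i, ])
    m <- m | (ecc <= radii_deg[i])
  }
  m
}

# Junctional deficit gradient g(d) in [0, 1]; d in degrees (0 at/inside the
# boundary). Two decay scales reproduce the steep near-boundary gradient
# flattening at eccentric locations.
junctional_gradient <- function(d, cfg) {
  w <- cfg$junctional_steep_weight
  w * exp(-d / cfg$junctional_steep_scale_deg) +
    (1 - w) * exp(-d / cfg$junctional_shallow_scale_deg)
}

mask_touches_frame <- function(mask) {
  any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
}

#' Generate a synthetic normative reference set
#'
#' Draws en-face thickness maps for non-atrophic eyes: a fixed topographic
#' mean surface per layer plus a linear age effect and i.i.d.
#' location-specific noise. Serves as the reference set from which the
#' age-adjusted normative model is fitted.
#'
#' @param cfg A [trial_config()].
#' @param seed Optional integer; if `NULL` the current RNG stream is used
#'   (as when called from [generate_cohort()]).
#' @return A list of class `normative_set`: `maps` (list per eye of named
#'   layer matrices, um), `ages` (years), `lateralities` (`"R"`/`"L"`),
#'   `pixel_pitch_deg`.
#' @export
generate_normative_set <- function(cfg, seed = NULL) {
  validate_trial_config(cfg)
  if (cfg$n_normative < 3) {
    stop("need at least 3 normative eyes for the age regression",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- grid_dim(cfg)
  pitch <- cfg$pixel_pitch_deg
  ages <- runif(cfg$n_normative, cfg$normative_age_range[1],
                cfg$normative_age_range[2])
  lats <- sample(c("R", "L"), cfg$n_normative, replace = TRUE)
  base <- lapply(JZ_LAYERS, layer_mean_surface, n = n, pitch = pitch)
  names(base) <- JZ_LAYERS
  maps <- vector("list", cfg$n_normative)
  for (i in seq_len(cfg$n_normative)) {
    maps[[i]] <- lapply(JZ_LAYERS, function(ly) {
      mu <- base[[ly]] + layer_age_slope(ly) * ages[i]
      if (lats[i] == "L") mu <- mirror_horizontal(mu)
      # location-specific population variation: the per-layer reference SD
      # (um) is the unit in which z-scores are later expressed
      t_map <- mu + layer_sd_um(ly) * cfg$normative_noise_scale *
        matrix(rnorm(n * n), n, n)
      pmax(t_map, 0)
    })
    names(maps[[i]]) <- JZ_LAYERS
  }
  structure(list(maps = maps, ages = ages, lateralities = lats,
                 pixel_pitch_deg = pitch),
            class = "normative_set")
}

#' Generate a synthetic longitudinal GA trial cohort
#'
#' Produces the complete inputs of the contour-line analysis: a visit-level
#' cohort manifest, per-eye/visit/layer en-face thickness maps (um), binary
#' atrophy masks nested over time, and a normative reference set. Study-eye
#' lesions grow so that the square-root area increases linearly at
#' arm-specific rates; the junctional thinning gradient travels with the
#' boundary; a macula-wide drift thins treated arms less than sham; fellow
#' eyes have zero drift.
#'
#' @param cfg A [trial_config()]; `cfg$seed` makes the output
#'   bit-reproducible.
#' @param include_maps Generate thickness maps (set `FALSE` for mask-only
#'   studies of lesion kinetics).
#' @param include_fellow Include fellow eyes.
#' @return A list of class `ga_cohort` with elements `manifest` (tibble, one
#'   row per eye and visit), `maps` (`maps[[eye_id]][[month]][[layer]]`),
#'   `masks` (`masks[[eye_id]][[month]]`, logical), `normative`
#'   (a `normative_set`), `eyes` (per-eye generating truth) and `config`.
#' @examples
#' cfg <- trial_config(n_per_arm = 2, pixel_pitch_deg = 0.4, n_normative = 5)
#' coh <- generate_cohort(cfg)
#' head(coh$manifest)
#' @export
generate_cohort <- function(cfg, include_maps = TRUE, include_fellow = TRUE) {
  validate_trial_config(cfg)
  set.seed(cfg$seed)
  n <- grid_dim(cfg)
  pitch <- cfg$pixel_pitch_deg
  half_deg <- cfg$grid_size_deg / 2
  n_part <- cfg$n_per_arm * length(cfg$arms)
  pid <- sprintf("P%03d", seq_len(n_part))
  arm <- rep(cfg$arms, each = cfg$n_per_arm)

  age <- pmin(pmax(rnorm(n_part, cfg$age_mean, cfg$age_sd), 55), 97)
  sex <- sample(c("F", "M"), n_part, replace = TRUE, prob = c(0.635, 0.365))
  lat_study <- sample(c("R", "L"), n_part, replace = TRUE)
  lat_fellow <- ifelse(lat_study == "R", "L", "R")

  # Injection schedule: monthly regimen expects 12, every-other-month 6;
  # pooled sham contains both regimens.
  expected <- ifelse(arm == "monthly", 12L,
                     ifelse(arm == "eom", 6L,
                            sample(c(12L, 6L), n_part, replace = TRUE)))
  low <- runif(n_part) < cfg$low_compliance_rate
  received <- ifelse(low,
                     pmax(0L, floor(expected * runif(n_part, 0.15, 0.72))),
                     expected - rbinom(n_part, 2, 0.04))
  received <- pmin(as.integer(received), expected)

  # Visit availability: a few participants have baseline only; otherwise
  # sporadic missed visits (missing at random, not imputed downstream).
  fu <- cfg$visit_months[cfg$visit_months > 0]
  visit_list <- vector("list", n_part)
  baseline_only <- runif(n_part) < 0.03
  for (i in seq_len(n_part)) {
    if (baseline_only[i]) {
      visit_list[[i]] <- 0
    } else {
      keep <- fu[runif(length(fu)) < 0.97]
      visit_list[[i]] <- c(0, keep)
    }
  }

  exudation <- runif(n_part) < cfg$exudation_rate

  # Study-eye lesion kinetics: sqrt(area) = s0 + g * years (mm), so the
  # disk radius r = (s0 + g * years) / sqrt(pi), converted to degrees.
  s0 <- pmin(pmax(rnorm(n_part, cfg$baseline_sqrt_area_mean,
                        cfg$baseline_sqrt_area_sd), 1.6), 4.2)
  g_arm <- cfg$sham_growth_rate *
    (1 - cfg$treatment_growth_reduction[arm])
  center_study <- cbind(runif(n_part, -1, 1), runif(n_part, -1, 1))

  # Fellow eyes: natural-history growth, zero drift; some excluded from the
  # fellow analysis by the MNV flag or the 2.5 mm^2 area criterion.
  s0_fel <- pmax(rnorm(n_part, 1.9, 0.45), 1.2)
  fellow_mnv <- runif(n_part) < 0.10
  center_fel <- cbind(runif(n_part, -1, 1), runif(n_part, -1, 1))

  b_eye_study <- rnorm(n_part, 0, cfg$eye_intercept_sd)
  b_eye_fel <- rnorm(n_part, 0, cfg$eye_intercept_sd)
  faf_noise <- rnorm(n_part, 0, 0.03)

  base_surface <- lapply(JZ_LAYERS, layer_mean_surface, n = n, pitch = pitch)
  names(base_surface) <- JZ_LAYERS

  roles <- if (include_fellow) c("study", "fellow") else "study"
  manifest <- list()
  maps <- list()
  masks <- list()
  eyes <- list()

  make_eye <- function(i, role) {
    lat <- if (role == "study") lat_study[i] else lat_fellow[i]
    s0_i <- if (role == "study") s0[i] else s0_fel[i]
    g_i <- if (role == "study") g_arm[i] else cfg$sham_growth_rate
    drift <- if (role == "study") cfg$macula_wide_drift[[arm[i]]] else 0
    ctr <- if (role == "study") center_study[i, ] else center_fel[i, ]
    b_eye <- if (role == "study") b_eye_study[i] else b_eye_fel[i]
    eye_id <- paste(pid[i], role, sep = "_")
    vis <- sort(visit_list[[i]])
    s_ev <- rnorm(length(vis), 0, cfg$visit_effect_sd)

    if (cfg$multifocal && role == "study") {
      frac <- c(0.7, 0.3)
      off <- matrix(c(-1.2, -1.2, 1.5, 1.5), 2, 2, byrow = TRUE)
      centers <- sweep(off, 2, ctr, "+")
    } else {
      frac <- 1
      centers <- matrix(ctr, 1, 2)
    }

    eye_masks <- list()
    eye_maps <- list()
    beyond <- FALSE
    rows <- vector("list", length(vis))
    for (v_idx in seq_along(vis)) {
      m_month <- vis[v_idx]
      yrs <- m_month / 12
      sqrt_area <- s0_i + g_i * yrs
      # per-focus radii: focus f holds a fixed fraction of the total area
      radii_mm <- sqrt(frac) * sqrt_area / sqrt(pi)
      mask <- disk_mask(n, pitch, centers, radii_mm / DEG_TO_MM)
      beyond <- beyond || mask_touches_frame(mask)
      eye_masks[[as.character(m_month)]] <- mask

      if (include_maps) {
        d_deg <- lesion_distance_deg(mask, pitch)
        deficit <- cfg$junctional_deficit_depth_z * junctional_gradient(d_deg, cfg)
        layer_maps <- lapply(JZ_LAYERS, function(ly) {
          mu <- base_surface[[ly]]
          if (lat == "L") mu <- mirror_horizontal(mu)
          z <- b_eye + s_ev[v_idx] + drift * yrs - deficit +
            cfg$noise_sd * matrix(rnorm(n * n), n, n)
          pmax(mu + layer_age_slope(ly) * age[i] + layer_sd_um(ly) * z, 0)
        })
        names(layer_maps) <- JZ_LAYERS
        eye_maps[[as.character(m_month)]] <- layer_maps
      }

      rows[[v_idx]] <- tibble::tibble(
        participant_id = pid[i], eye_id = eye_id, eye_role = role,
        arm = arm[i], age = age[i], sex = sex[i], laterality = lat,
        visit_month = m_month,
        injections_received_to_month12 = received[i],
        injections_expected = expected[i],
        exudation_ever = if (role == "study") exudation[i] else FALSE,
        fellow_mnv = if (role == "fellow") fellow_mnv[i] else NA,
        fellow_baseline_area_mm2 = if (role == "fellow") s0_fel[i]^2 else NA_real_,
        faf_sqrt_area_mm = s0_i + faf_noise[i],
        ga_beyond_frame = NA  # filled after all visits are known
      )
    }
    rows <- dplyr::bind_rows(rows)
    rows$ga_beyond_frame <- beyond
    list(rows = rows, masks = eye_masks, maps = eye_maps,
         truth = tibble::tibble(
           eye_id = eye_id, participant_id = pid[i], eye_role = role,
           arm = arm[i], baseline_sqrt_area_mm = s0_i,
           growth_mm_per_year = g_i, drift_z_per_year = drift,
           eye_intercept_z = b_eye,
           center_row_deg = ctr[1], center_col_deg = ctr[2]))
  }

  for (i in seq_len(n_part)) {
    for (role in roles) {
      eye <- make_eye(i, role)
      eid <- eye$truth$eye_id
      manifest[[eid]] <- eye$rows
      masks[[eid]] <- eye$masks
      if (include_maps) maps[[eid]] <- eye$maps
      eyes[[eid]] <- eye$truth
    }
  }

  normative <- if (include_maps) generate_normative_set(cfg, seed = NULL) else NULL

  structure(list(
    manifest = dplyr::bind_rows(manifest),
    maps = maps, masks = masks, normative = normative,
    eyes = dplyr::bind_rows(eyes), config = cfg
  ), class = "ga_cohort")
}

#' @export
print.ga_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Synthetic GA cohort: %d participants, %d eyes, %d eye-visits\n",
              dplyr::n_distinct(m$participant_id),
              dplyr::n_distinct(m$eye_id), nrow(m)))
  cat(sprintf("  arms: %s\n", paste(unique(m$arm), collapse = ", ")))
  cat(sprintf("  maps: %s; normative eyes: %s\n",
              if (length(x$maps)) "yes" else "no",
              if (is.null(x$normative)) "none" else length(x$normative$maps)))
  invisible(x)
}

#' Per-eye lesion areas of a cohort
#'
#' Tabulates lesion area and square-root area per eye and visit from the
#' generated masks.
#'
#' @param cohort A `ga_cohort`.
#' @param eye_role Which eyes to tabulate.
#' @return Tibble with `eye_id`, `participant_id`, `arm`, `visit_month`,
#'   `area_mm2`, `sqrt_area_mm`.
#' @export
cohort_lesion_areas <- function(cohort, eye_role = "study") {
  stopifnot(inherits(cohort, "ga_cohort"))
  pitch <- cohort$config$pixel_pitch_deg
  eyes <- cohort$eyes %||%
    dplyr::distinct(cohort$manifest, .data$eye_id, .data$participant_id,
                    .data$eye_role, .data$arm)
  keep <- eyes[eyes$eye_role %in% eye_role, ]
  out <- lapply(keep$eye_id, function(eid) {
    months <- as.numeric(names(cohort$masks[[eid]]))
    areas <- vapply(cohort$masks[[eid]], lesion_area_mm2,
                    numeric(1), pixel_pitch_deg = pitch)
    tibble::tibble(eye_id = eid,
                   participant_id = keep$participant_id[keep$eye_id == eid],
                   arm = keep$arm[keep$eye_id == eid],
                   visit_month = months, area_mm2 = unname(areas),
                   sqrt_area_mm = sqrt(unname(areas)))
  })
  dplyr::bind_rows(out)
}

# Fraction of a circle of radius rho (centered at the fovea) lying inside
# the square field of half-width h. Used by the ring-level fast simulator.
circle_in_square_fraction <- function(rho, h) {
  f <- ifelse(rho <= h, 1,
              ifelse(rho >= h * sqrt(2), 0,
                     1 - 4 * acos(pmin(h / rho, 1)) / pi))
  pmax(f, 0)
}

#' Simulate ring-level features directly (fast calibration path)
#'
#' Draws `RingFeatureTable` observations from the annulus-level marginal of
#' the raster generator, skipping map synthesis and image processing: ring
#' means are the eye intercept + acquisition deviation + arm drift -
#' junctional deficit at the ring's mid distance, plus pixel-averaged noise
#' with the pixel count implied by the annulus geometry. Because the rings
#' travel with the boundary, the deficit term is constant over visits and
#' the expected change from baseline is the arm drift times elapsed years.
#' Intended for replicate-heavy calibration studies (type-I error, coverage,
#' power) of the longitudinal models; agreement with the full raster
#' pipeline is part of the package's test suite.
#'
#' @param cfg A [trial_config()].
#' @param ring_indices Ring numbers k (band `((k-1)w, kw]`).
#' @param ring_width_deg Ring width w in degrees.
#' @param layers Layers to emit (ring noise is drawn independently per
#'   layer).
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A tibble in `RingFeatureTable` form (`participant_id`,
#'   `eye_role`, `arm`, `visit_month`, `layer`, `ring`, `ring_distance_deg`,
#'   `mean_z`, `n_pixels`).
#' @export
simulate_ring_features <- function(cfg, ring_indices = c(1, 6, 12),
                                   ring_width_deg = 0.43, layers = "ONL",
                                   seed = cfg$seed) {
  validate_trial_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  n_part <- cfg$n_per_arm * length(cfg$arms)
  pid <- sprintf("P%03d", seq_len(n_part))
  arm <- rep(cfg$arms, each = cfg$n_per_arm)
  s0 <- pmin(pmax(rnorm(n_part, cfg$baseline_sqrt_area_mean,
                        cfg$baseline_sqrt_area_sd), 1.6), 4.2)
  g_arm <- cfg$sham_growth_rate * (1 - cfg$treatment_growth_reduction[arm])
  drift <- cfg$macula_wide_drift[arm]
  b_eye <- rnorm(n_part, 0, cfg$eye_intercept_sd)
  h <- cfg$grid_size_deg / 2
  w <- ring_width_deg
  d_mid <- (ring_indices - 0.5) * w
  deficit <- cfg$junctional_deficit_depth_z * junctional_gradient(d_mid, cfg)

  out <- vector("list", n_part)
  for (i in seq_len(n_part)) {
    vis <- cfg$visit_months
    s_ev <- rnorm(length(vis), 0, cfg$visit_effect_sd)
    rows <- list()
    for (v_idx in seq_along(vis)) {
      yrs <- vis[v_idx] / 12
      r_deg <- (s0[i] + g_arm[i] * yrs) / sqrt(pi) / DEG_TO_MM
      rho <- r_deg + (ring_indices - 0.5) * w
      n_px <- pmax(1, round(2 * pi * rho * w *
                              circle_in_square_fraction(rho, h) /
                              cfg$pixel_pitch_deg^2))
      for (ly in layers) {
        mz <- b_eye[i] + s_ev[v_idx] + drift[i] * yrs - deficit +
          rnorm(length(ring_indices), 0, cfg$noise_sd / sqrt(n_px))
        rows[[length(rows) + 1]] <- tibble::tibble(
          participant_id = pid[i], eye_role = "study", arm = arm[i],
          visit_month = vis[v_idx], layer = ly, ring = ring_indices,
          ring_distance_deg = ring_indices * w, mean_z = mz,
          n_pixels = as.integer(n_px))
      }
    }
    out[[i]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}
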