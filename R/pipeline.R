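# Population filters, full-grid orchestration (populations x layers x
# contour lines), geometry quality control, and report assembly.

POPULATIONS <- c("mITT", "PP", "PP_no_exudation", "fellow")

#' Apply an analysis-population filter to a cohort manifest
#'
#' Implements the prespecified population definitions:
#' \describe{
#'   \item{mITT}{study eyes of participants with at least one injection and
#'     at least one follow-up visit at month 2 or later.}
#'   \item{PP}{mITT participants who received at least 75% of expected
#'     injections before month 12 - i.e. at least 9 (monthly regimen) or 4
#'     (every-other-month regimen).}
#'   \item{PP_no_exudation}{PP, excluding all visits of eyes that ever
#'     developed exudation.}
#'   \item{fellow}{fellow eyes without macular neovascularization and with
#'     baseline atrophy area of at least 2.5 mm^2, in mITT participants.}
#' }
#' The per-regimen injection thresholds are `floor(0.75 * expected)`,
#' which reproduces the 9-of-12 and 4-of-6 cut-offs.
#'
#' @param manifest Cohort manifest tibble (one row per eye and visit).
#' @param population One of `"mITT"`, `"PP"`, `"PP_no_exudation"`,
#'   `"fellow"`.
#' @param min_injection_fraction Fraction of expected injections required
#'   for the per-protocol population.
#' @param fellow_area_threshold_mm2 Baseline area criterion for fellow
#'   eyes.
#' @return The filtered manifest (all visit rows of qualifying eyes).
#' @export
apply_population_filter <- function(manifest, population,
                                    min_injection_fraction = 0.75,
                                    fellow_area_threshold_mm2 = 2.5) {
  if (!is.character(population) || length(population) != 1 ||
      !population %in% POPULATIONS) {
    stop("unknown population; use one of ",
         paste(POPULATIONS, collapse = ", "), call. = FALSE)
  }
  m <- manifest
  # mITT participant set: >= 1 injection, >= 1 follow-up at month >= 2
  study <- dplyr::filter(m, .data$eye_role == "study")
  mitt_ids <- study |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      ok = any(.data$injections_received_to_month12 >= 1) &&
        any(.data$visit_month >= 2), .groups = "drop") |>
    dplyr::filter(.data$ok) |>
    dplyr::pull("participant_id")

  pp_ids <- study |>
    dplyr::distinct(.data$participant_id,
                    .data$injections_received_to_month12,
                    .data$injections_expected) |>
    dplyr::filter(.data$participant_id %in% mitt_ids,
                  .data$injections_received_to_month12 >=
                    floor(min_injection_fraction * .data$injections_expected)) |>
    dplyr::pull("participant_id")

  switch(population,
    mITT = dplyr::filter(m, .data$eye_role == "study",
                         .data$participant_id %in% mitt_ids),
    PP = dplyr::filter(m, .data$eye_role == "study",
                       .data$participant_id %in% pp_ids),
    PP_no_exudation = dplyr::filter(
      m, .data$eye_role == "study", .data$participant_id %in% pp_ids,
      !.data$exudation_ever),
    fellow = dplyr::filter(
      m, .data$eye_role == "fellow", .data$participant_id %in% mitt_ids,
      !.data$fellow_mnv,
      .data$fellow_baseline_area_mm2 >= fellow_area_threshold_mm2)
  )
}

#' Participant exclusion-flow accounting
#'
#' Tabulates a trial's analysis-set accounting: randomized participants,
#' exclusions for an incompatible imaging device and for missing follow-up,
#' the resulting analyzed count, and the analyzed fractions of the
#' compatible-device and randomized totals.
#'
#' @param n_randomized Randomized participants.
#' @param n_other_device Excluded for imaging with an incompatible device.
#' @param n_no_followup Excluded for missing follow-up (or protocol
#'   deviation) among the remaining participants.
#' @return A list: `n_imaged`, `n_analyzed`, `pct_of_imaged`,
#'   `pct_of_randomized`, and a `flow` tibble of the stages.
#' @examples
#' exclusion_flow(246, 49, 5)
#' @export
exclusion_flow <- function(n_randomized, n_other_device, n_no_followup) {
  stopifnot(n_randomized > 0, n_other_device >= 0, n_no_followup >= 0)
  n_imaged <- n_randomized - n_other_device
  n_analyzed <- n_imaged - n_no_followup
  if (n_analyzed < 0) stop("exclusions exceed the randomized total",
                           call. = FALSE)
  list(
    n_imaged = n_imaged,
    n_analyzed = n_analyzed,
    pct_of_imaged = 100 * n_analyzed / n_imaged,
    pct_of_randomized = 100 * n_analyzed / n_randomized,
    flow = tibble::tibble(
      stage = c("randomized", "compatible device", "with follow-up"),
      n = c(n_randomized, n_imaged, n_analyzed),
      excluded = c(0, n_other_device, n_no_followup))
  )
}

#' Geometry quality control by Bland-Altman agreement
#'
#' Compares mask-derived square-root lesion areas with an independent
#' reference measurement of the same eyes (computed minus reference).
#'
#' @param computed_sqrt_area Mask-derived sqrt-areas, mm.
#' @param reference_sqrt_area Reference sqrt-areas, mm (same eyes, same
#'   order).
#' @return A [bland_altman()] result.
#' @export
geometry_qc <- function(computed_sqrt_area, reference_sqrt_area) {
  bland_altman(computed_sqrt_area, reference_sqrt_area)
}

#' Extract ring features for every eye, visit and layer of a cohort
#'
#' Standardizes each thickness map against the normative model and averages
#' the z-scores over the traveling contour rings recomputed from that
#' visit's lesion mask.
#'
#' @param cohort A `ga_cohort` with maps and masks.
#' @param model A [fit_normative()] model.
#' @param ring_width_deg,n_rings Ring geometry.
#' @return Long-format ring feature tibble (one row per eye x visit x
#'   layer x non-empty ring).
#' @export
extract_cohort_features <- function(cohort, model, ring_width_deg = 0.43,
                                    n_rings = 12) {
  pitch <- cohort$config$pixel_pitch_deg
  out <- vector("list", length(cohort$maps))
  i <- 0
  for (eid in names(cohort$maps)) {
    eye_rows <- cohort$manifest[cohort$manifest$eye_id == eid, ]
    meta0 <- eye_rows[1, c("participant_id", "eye_role", "arm", "age",
                           "laterality")]
    eye_feat <- list()
    for (mo in names(cohort$maps[[eid]])) {
      mask <- cohort$masks[[eid]][[mo]]
      rings <- withCallingHandlers(
        compute_contour_rings(mask, pitch, ring_width_deg, n_rings,
                              visit_month = as.numeric(mo)),
        warning = function(w) invokeRestart("muffleWarning"))
      for (ly in names(cohort$maps[[eid]][[mo]])) {
        # age-extrapolation notes are informative map-by-map but noise in a
        # batch; the cohort-level age range is visible in the manifest
        z <- withCallingHandlers(
          standardize(cohort$maps[[eid]][[mo]][[ly]], meta0$age, model,
                      ly, meta0$laterality),
          warning = function(w) {
            if (grepl("extrapolated", conditionMessage(w))) {
              invokeRestart("muffleWarning")
            }
          })
        eye_feat[[length(eye_feat) + 1]] <- extract_ring_means(
          z, rings,
          metadata = list(participant_id = meta0$participant_id,
                          eye_id = eid, eye_role = meta0$eye_role,
                          arm = meta0$arm,
                          visit_month = as.numeric(mo), layer = ly))
      }
    }
    i <- i + 1
    out[[i]] <- dplyr::bind_rows(eye_feat)
  }
  dplyr::bind_rows(out)
}

#' Run the full contour-line trial analysis
#'
#' End-to-end orchestration on a (synthetic or supplied) cohort: fit the
#' normative model, standardize every map, extract traveling contour rings,
#' build the change-from-baseline table, and fit one linear mixed model per
#' population x layer x contour line (3 x 3 x 3 = 27 models for the default
#' three populations), with pairwise arm contrasts at every follow-up
#' visit. Also fits the sqrt-area atrophy-progression model and the
#' Bland-Altman geometry QC on the subset of study eyes whose lesion stays
#' within the image frame. The primary-outcome cell - ONL, 5.16 degree
#' contour line, month 12, monthly vs sham, mITT - is flagged in the
#' contrast table.
#'
#' @param config A [trial_config()]; ignored when `cohort` is supplied.
#' @param cohort Optional pre-generated `ga_cohort`.
#' @param populations Analysis populations to run.
#' @param stat_rings Ring indices entering the models (defaults to rings 1,
#'   6, 12: the 0.43, 2.58 and 5.16 degree contour lines).
#' @param contrast_months Visits at which contrasts are computed.
#' @param layers Layers to model.
#' @param df_method Denominator df approximation.
#' @param ring_width_deg,n_rings Ring geometry.
#' @return An object of class `analysis_report`: tibbles `contrasts`,
#'   `lsmeans`, `features`, `progression` (per-arm rates and reductions),
#'   `agreement`, and a `provenance` list (model count, seed, config hash,
#'   package version).
#' @export
run_full_analysis <- function(config = trial_config(), cohort = NULL,
                              populations = c("mITT", "PP", "fellow"),
                              stat_rings = c(1, 6, 12),
                              contrast_months = c(2, 6, 12, 18),
                              layers = JZ_LAYERS,
                              df_method = c("satterthwaite", "kenward-roger"),
                              ring_width_deg = 0.43, n_rings = 12) {
  df_method <- match.arg(df_method)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cohort <- cohort %||% stage("simulate", generate_cohort(config))
  config <- cohort$config

  model <- stage("normative", fit_normative(cohort$normative))
  features <- stage("extract",
                    extract_cohort_features(cohort, model, ring_width_deg,
                                            n_rings))
  stat_dists <- stat_rings * ring_width_deg
  feat_stats <- dplyr::filter(features, .data$ring %in% stat_rings)

  all_contrasts <- list()
  all_lsmeans <- list()
  n_models <- 0
  for (pop in populations) {
    mpop <- stage(paste0("filter:", pop),
                  apply_population_filter(cohort$manifest, pop))
    eyes_pop <- unique(mpop$eye_id)
    fpop <- dplyr::filter(feat_stats, .data$eye_id %in% eyes_pop)
    ct <- stage(paste0("change:", pop), suppressWarnings(
      build_change_table(fpop)))
    for (ly in layers) {
      for (dd in stat_dists) {
        fit <- stage(sprintf("fit:%s/%s/%.2f", pop, ly, dd),
                     suppressMessages(fit_change_lmm(
                       ct, layer = ly, ring_distance_deg = dd,
                       df_method = df_method)))
        n_models <- n_models + 1
        months_avail <- intersect(contrast_months,
                                  as.numeric(fit$visits))
        res <- stage(sprintf("contrast:%s/%s/%.2f", pop, ly, dd),
                     suppressWarnings(arm_contrasts(fit, months_avail)))
        all_contrasts[[n_models]] <- res$contrasts |>
          dplyr::mutate(population = pop, layer = ly,
                        ring_distance_deg = dd,
                        singular = fit$singular)
        all_lsmeans[[n_models]] <- res$lsmeans |>
          dplyr::mutate(population = pop, layer = ly,
                        ring_distance_deg = dd)
      }
    }
  }
  contrasts <- dplyr::bind_rows(all_contrasts) |>
    dplyr::mutate(primary = .data$population == "mITT" &
                    .data$layer == "ONL" &
                    abs(.data$ring_distance_deg - 5.16) < 1e-8 &
                    .data$visit_month == 12 &
                    .data$contrast == "monthly - sham_pooled")
  lsmeans <- dplyr::bind_rows(all_lsmeans)

  # Atrophy progression + geometry QC on mITT study eyes with the lesion
  # inside the frame at every visit.
  mitt <- apply_population_filter(cohort$manifest, "mITT")
  in_frame <- dplyr::filter(mitt, !.data$ga_beyond_frame)
  areas <- cohort_lesion_areas(cohort) |>
    dplyr::semi_join(in_frame, by = c("eye_id", "visit_month"))
  progression <- if (dplyr::n_distinct(areas$participant_id) >= 6) {
    stage("progression", suppressMessages(fit_ga_progression(
      areas, df_method = df_method)))
  } else NULL

  qc_base <- areas |>
    dplyr::filter(.data$visit_month == 0) |>
    dplyr::inner_join(
      dplyr::distinct(in_frame, .data$eye_id, .data$faf_sqrt_area_mm),
      by = "eye_id")
  agreement <- if (nrow(qc_base) >= 3) {
    stage("geometry_qc",
          geometry_qc(qc_base$sqrt_area_mm, qc_base$faf_sqrt_area_mm))
  } else NULL

  structure(list(
    contrasts = contrasts, lsmeans = lsmeans, features = features,
    progression = progression, agreement = agreement,
    provenance = list(
      n_models = n_models,
      populations = populations, layers = layers,
      ring_distances_deg = stat_dists,
      df_method = df_method,
      seed = config$seed,
      config_hash = digest::digest(unclass(config)),
      package_version = as.character(utils::packageVersion("junctionzone")),
      r_version = paste(R.version$major, R.version$minor, sep = "."))
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("Contour-line analysis report: %d mixed models (%s x %s x %s)\n",
              p$n_models, length(p$populations), length(p$layers),
              length(p$ring_distances_deg)))
  prim <- dplyr::filter(x$contrasts, .data$primary)
  if (nrow(prim) == 1) {
    cat(sprintf(
      "  primary outcome (ONL, 5.16 deg, month 12, monthly - sham):\n    %+.3f z [%.3f, %.3f], adj. p = %.4g\n",
      prim$estimate, prim$ci_low, prim$ci_high, prim$p_adjusted))
  }
  if (!is.null(x$progression)) {
    cat(sprintf("  growth reduction vs sham: %s\n",
                paste(sprintf("%s %.1f%%", x$progression$reduction$arm,
                              x$progression$reduction$pct_reduction_month12),
                      collapse = ", ")))
  }
  if (!is.null(x$agreement)) {
    cat(sprintf("  area QC bias: %.3f mm [%.3f, %.3f]\n",
                x$agreement$bias, x$agreement$bias_ci[1],
                x$agreement$bias_ci[2]))
  }
  invisible(x)
}

#' Write an analysis report to CSV tables
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$contrasts, file.path(dir, "contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(report$lsmeans, file.path(dir, "lsmeans.csv"),
                   row.names = FALSE)
  if (!is.null(report$progression)) {
    utils::write.csv(report$progression$reduction,
                     file.path(dir, "ga_progression.csv"), row.names = FALSE)
  }
  if (!is.null(report$agreement)) {
    a <- report$agreement
    utils::write.csv(
      data.frame(bias = a$bias, ci_low = a$bias_ci[1],
                 ci_high = a$bias_ci[2], loa_lower = a$loa_lower,
                 loa_upper = a$loa_upper, n = a$n, p_bias = a$p_bias),
      file.path(dir, "agreement.csv"), row.names = FALSE)
  }
  yaml::write_yaml(report$provenance, file.path(dir, "provenance.yaml"))
  invisible(dir)
}
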