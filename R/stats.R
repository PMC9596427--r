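# Longitudinal mixed-model analysis of traveling-ring features:
# change-from-baseline linear mixed models, small-sample-df pairwise arm
# contrasts with single-step multiplicity adjustment, the sqrt-area
# atrophy-progression model, and Bland-Altman agreement.

ARM_LEVELS <- c("monthly", "eom", "sham_pooled")

#' Build the change-from-baseline table
#'
#' Joins every post-baseline ring observation to its baseline (same eye,
#' layer and ring) and computes `change_z = mean_z(visit) - mean_z(0)`.
#' Baseline rows are consumed as the `baseline_z` covariate. Eyes lacking a
#' baseline for a given layer/ring contribute no rows (a warning lists
#' them); missed visits simply yield no row - no imputation anywhere.
#'
#' @param features Ring feature tibble with columns `participant_id`,
#'   `eye_role`, `arm`, `visit_month`, `layer`, `ring_distance_deg`,
#'   `mean_z` (as produced by [extract_ring_means()] rows bound together).
#' @return Tibble with `change_z` and `baseline_z`, one row per
#'   eye x post-baseline visit x layer x ring.
#' @export
build_change_table <- function(features) {
  req <- c("participant_id", "eye_role", "arm", "visit_month", "layer",
           "ring_distance_deg", "mean_z")
  miss <- setdiff(req, names(features))
  if (length(miss)) {
    stop("features table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- c("participant_id", "eye_role", "layer", "ring_distance_deg")
  base <- features |>
    dplyr::filter(.data$visit_month == 0) |>
    dplyr::select(dplyr::all_of(key), baseline_z = "mean_z")
  post <- dplyr::filter(features, .data$visit_month > 0)
  no_base <- dplyr::anti_join(post, base, by = key)
  if (nrow(no_base) > 0) {
    dropped <- unique(paste(no_base$participant_id, no_base$eye_role,
                            sep = "_"))
    warning(sprintf("dropping %d eye(s) without baseline: %s",
                    length(dropped),
                    paste(head(dropped, 5), collapse = ", ")),
            call. = FALSE)
  }
  post |>
    dplyr::inner_join(base, by = key) |>
    dplyr::mutate(change_z = .data$mean_z - .data$baseline_z) |>
    dplyr::select(-"mean_z")
}

#' Fit the change-from-baseline linear mixed model
#'
#' For one layer and one contour line, fits (by REML)
#' `change_z ~ arm * visit + baseline_z + (1 | participant_id)`
#' with visit categorical - fixed effects for treatment arm, visit, their
#' interaction and the same-ring baseline z-score, and a random intercept
#' per participant. Singular fits (zero random-intercept variance, common
#' when change scores carry little between-eye variance) are flagged, not
#' refit.
#'
#' @param change_table A [build_change_table()] result.
#' @param layer Layer to model; `NULL` if the table holds a single layer.
#' @param ring_distance_deg Contour line to model; `NULL` if unique.
#' @param df_method Denominator degrees-of-freedom approximation for the
#'   contrasts: `"satterthwaite"` (default) or `"kenward-roger"`.
#' @return An object of class `change_lmm` wrapping the `lmerModLmerTest`
#'   fit plus metadata (`layer`, `ring_distance_deg`, `singular`,
#'   `df_method`).
#' @export
fit_change_lmm <- function(change_table, layer = NULL,
                           ring_distance_deg = NULL,
                           df_method = c("satterthwaite", "kenward-roger")) {
  df_method <- match.arg(df_method)
  d <- change_table
  if (!is.null(layer)) d <- dplyr::filter(d, .data$layer == !!layer)
  if (!is.null(ring_distance_deg)) {
    d <- dplyr::filter(d, abs(.data$ring_distance_deg -
                                !!ring_distance_deg) < 1e-8)
  }
  if (nrow(d) == 0) stop("no rows for the requested layer/ring", call. = FALSE)
  if (dplyr::n_distinct(d$layer) > 1 ||
      dplyr::n_distinct(d$ring_distance_deg) > 1) {
    stop("change table spans several layers/rings; specify which to model",
         call. = FALSE)
  }
  arms_present <- intersect(ARM_LEVELS, unique(d$arm))
  if (length(arms_present) < 2) stop("need at least 2 arms", call. = FALSE)
  if (dplyr::n_distinct(d$visit_month) < 2) {
    stop("need at least 2 post-baseline visits", call. = FALSE)
  }
  d$arm <- factor(d$arm, levels = arms_present)
  d$visit <- factor(d$visit_month, levels = sort(unique(d$visit_month)))
  fit <- lmerTest::lmer(
    change_z ~ arm * visit + baseline_z + (1 | participant_id),
    data = d, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular) {
    message("random-intercept variance estimated at zero (singular fit); ",
            "estimates remain valid, flag recorded")
  }
  structure(list(fit = fit, layer = unique(d$layer),
                 ring_distance_deg = unique(d$ring_distance_deg),
                 visits = levels(d$visit), arms = arms_present,
                 singular = singular, df_method = df_method,
                 n_obs = nrow(d),
                 n_participants = dplyr::n_distinct(d$participant_id)),
            class = "change_lmm")
}

#' @export
print.change_lmm <- function(x, ...) {
  cat(sprintf(
    "Change-from-baseline LMM: layer %s, %g deg contour line\n",
    x$layer %||% "?", x$ring_distance_deg %||% NA))
  cat(sprintf("  %d observations, %d participants, arms %s%s\n",
              x$n_obs, x$n_participants, paste(x$arms, collapse = "/"),
              if (x$singular) " [singular]" else ""))
  invisible(x)
}

# Shared contrast engine for change_lmm and ga_progression fits.
contrast_engine <- function(fit, visit_month, df_method, adjust, level,
                            ci = TRUE) {
  visit_month <- as.character(visit_month)
  bad <- setdiff(visit_month, fit$visits)
  if (length(bad)) {
    stop("visit(s) not in the model: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(fit$arms) < 3) {
    warning("fewer than 3 arms; adjustment family resized to ",
            choose(length(fit$arms), 2), " contrast(s)", call. = FALSE)
  }
  em <- emmeans::emmeans(
    fit$fit, ~ arm | visit,
    at = list(visit = factor(visit_month, levels = fit$visits)),
    lmer.df = df_method)
  # The single-step multivariate-t integration is quasi-random; run it on a
  # locally fixed stream so reports are reproducible.
  pr <- with_fixed_rng(271828, summary(emmeans::contrast(
    em, method = "pairwise", adjust = adjust),
    infer = c(ci, TRUE), level = level))
  ls <- summary(em, infer = c(ci, FALSE), level = level)
  contrasts <- tibble::tibble(
    contrast = as.character(pr$contrast),
    visit_month = as.numeric(as.character(pr$visit)),
    estimate = pr$estimate, SE = pr$SE, approx_df = pr$df,
    ci_low = if (ci) pr$lower.CL else NA_real_,
    ci_high = if (ci) pr$upper.CL else NA_real_,
    t_ratio = pr$t.ratio, p_adjusted = pmin(pr$p.value, 1))
  lsmeans <- tibble::tibble(
    arm = as.character(ls$arm),
    visit_month = as.numeric(as.character(ls$visit)),
    lsmean = ls$emmean, SE = ls$SE, approx_df = ls$df,
    ci_low = if (ci) ls$lower.CL else NA_real_,
    ci_high = if (ci) ls$upper.CL else NA_real_)
  list(contrasts = contrasts, lsmeans = lsmeans)
}

#' Pairwise treatment-arm contrasts at a visit
#'
#' Computes the three pairwise arm contrasts (monthly - every-other-month,
#' monthly - sham, every-other-month - sham) of a fitted change model at
#' the requested visit(s), with denominator degrees of freedom from the
#' Satterthwaite or Kenward-Roger approximation and familywise adjustment
#' by the single-step multivariate-t method over the contrast correlation
#' matrix (the exact analogue of the Tukey procedure for a family of 3
#' estimates). Least-squares (adjusted) arm means are returned alongside.
#'
#' @param fit A [fit_change_lmm()] (or [fit_ga_progression()]) object.
#' @param visit_month Visit(s), e.g. `12`.
#' @param adjust Multiplicity adjustment passed to `emmeans` (default
#'   `"mvt"`, the single-step multivariate-t method).
#' @param level Confidence level.
#' @param ci Compute adjusted confidence limits (the equicoordinate
#'   quantile is the expensive part; disable in replicate-heavy
#'   simulations that only need p-values).
#' @return An object of class `contrast_result`: tibbles `contrasts`
#'   (estimate, SE, `approx_df`, adjusted CI and p-value) and `lsmeans`,
#'   plus metadata.
#' @export
arm_contrasts <- function(fit, visit_month, adjust = "mvt", level = 0.95,
                          ci = TRUE) {
  stopifnot(inherits(fit, c("change_lmm", "ga_progression")))
  res <- contrast_engine(fit, visit_month, fit$df_method, adjust, level, ci)
  structure(c(res, list(layer = fit$layer,
                        ring_distance_deg = fit$ring_distance_deg,
                        df_method = fit$df_method, adjust = adjust,
                        singular = fit$singular)),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("Pairwise arm contrasts (", x$df_method, " df, ", x$adjust,
      " adjustment)\n", sep = "")
  print(as.data.frame(x$contrasts), digits = 3)
  invisible(x)
}

#' Fit the square-root-area atrophy-progression model
#'
#' Models change from baseline in square-root-transformed lesion area (mm)
#' with fixed effects for arm, visit (categorical), their interaction,
#' baseline sqrt-area and its interaction with visit, and a random
#' intercept per participant. Reports per-arm adjusted mean change at month
#' 12 annualized to mm/year, sham-minus-treatment contrasts, and the
#' percentage growth reduction (contrast / sham rate) - both from the
#' month-12 categorical-visit model and from a companion linear-in-time
#' slope model, since either convention is common.
#'
#' @param areas Tibble with `participant_id`, `arm`, `visit_month`,
#'   `sqrt_area_mm` including baseline rows (visit 0).
#' @param df_method As in [fit_change_lmm()].
#' @return An object of class `ga_progression`: the lmer `fit`, tibbles
#'   `arm_rates` (mm/y), `reduction` (per treated arm: contrast vs sham in
#'   mm/y with SE and p, percentage reduction by both conventions) and the
#'   slope-model fit.
#' @export
fit_ga_progression <- function(areas,
                               df_method = c("satterthwaite", "kenward-roger")) {
  df_method <- match.arg(df_method)
  req <- c("participant_id", "arm", "visit_month", "sqrt_area_mm")
  miss <- setdiff(req, names(areas))
  if (length(miss)) stop("areas table lacks: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  base <- areas |>
    dplyr::filter(.data$visit_month == 0) |>
    dplyr::select("participant_id", baseline_sqrt = "sqrt_area_mm")
  d <- areas |>
    dplyr::filter(.data$visit_month > 0) |>
    dplyr::inner_join(base, by = "participant_id") |>
    dplyr::mutate(change_sqrt = .data$sqrt_area_mm - .data$baseline_sqrt)
  eyes_ok <- d |> dplyr::count(.data$participant_id)
  if (nrow(eyes_ok) < 3) {
    stop("need lesions measurable at >= 2 visits for >= 3 participants",
         call. = FALSE)
  }
  arms_present <- intersect(ARM_LEVELS, unique(d$arm))
  d$arm <- factor(d$arm, levels = arms_present)
  d$visit <- factor(d$visit_month, levels = sort(unique(d$visit_month)))
  fit <- lmerTest::lmer(
    change_sqrt ~ arm * visit + baseline_sqrt * visit + (1 | participant_id),
    data = d, REML = TRUE)
  singular <- lme4::isSingular(fit)

  obj <- structure(list(fit = fit, layer = NULL, ring_distance_deg = NULL,
                        visits = levels(d$visit), arms = arms_present,
                        singular = singular, df_method = df_method),
                   class = "ga_progression")
  # Per-arm adjusted change at month 12 (= mm/year since treatment spans
  # one year), sham-minus-treatment contrasts, percentage reduction.
  res <- contrast_engine(obj, 12, df_method, "mvt", 0.95)
  arm_rates <- res$lsmeans |>
    dplyr::mutate(rate_mm_per_year = .data$lsmean)
  sham_rate <- arm_rates$rate_mm_per_year[arm_rates$arm == "sham_pooled"]

  # Companion linear-in-time model: change ~ arm-specific slope in years.
  d$years <- d$visit_month / 12
  slope_fit <- lmerTest::lmer(
    change_sqrt ~ arm + arm:years + baseline_sqrt + (1 | participant_id),
    data = d, REML = TRUE)
  sl <- lme4::fixef(slope_fit)
  slope_by_arm <- vapply(arms_present, function(a)
    unname(sl[[paste0("arm", a, ":years")]]), numeric(1))
  sham_slope <- slope_by_arm[["sham_pooled"]]

  treated <- setdiff(arms_present, "sham_pooled")
  reduction <- dplyr::bind_rows(lapply(treated, function(a) {
    cn <- paste0(a, " - sham_pooled")
    row <- res$contrasts[res$contrasts$contrast == cn, ]
    est <- -row$estimate  # sham - treatment: positive when growth is slower
    tibble::tibble(
      arm = a,
      sham_minus_arm_mm_per_year = est,
      SE = row$SE, approx_df = row$approx_df,
      p_adjusted = row$p_adjusted,
      pct_reduction_month12 = 100 * est / sham_rate,
      pct_reduction_slope = 100 * (sham_slope - slope_by_arm[[a]]) / sham_slope)
  }))

  obj$contrasts <- res$contrasts
  obj$arm_rates <- arm_rates
  obj$reduction <- reduction
  obj$slope_by_arm <- slope_by_arm
  obj$slope_fit <- slope_fit
  obj
}

#' @export
print.ga_progression <- function(x, ...) {
  cat("Sqrt-area atrophy progression model\n")
  cat("  per-arm rate (mm/y, month-12 adjusted mean):\n")
  print(as.data.frame(x$arm_rates[, c("arm", "rate_mm_per_year")]),
        digits = 3, row.names = FALSE)
  cat("  growth reduction vs sham:\n")
  print(as.data.frame(x$reduction[, c("arm", "sham_minus_arm_mm_per_year",
                                      "pct_reduction_month12")]),
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between two paired measurement series: bias is the
#' mean difference `x - y`, its CI uses the t-distribution with n - 1
#' degrees of freedom, and the limits of agreement are
#' `bias +/- 1.96 * SD(x - y)`.
#'
#' @param x,y Paired numeric vectors of equal length >= 3.
#' @param conf Confidence level for the bias CI.
#' @return An object of class `bland_altman`: `bias`, `bias_ci`,
#'   `loa_lower`, `loa_upper`, `sd_diff`, `n`, `p_bias`.
#' @export
bland_altman <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  half <- qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
  p <- if (s == 0) {
    if (bias == 0) 1 else 0   # degenerate: identical differences
  } else {
    t.test(d)$p.value
  }
  structure(list(bias = bias, bias_ci = c(bias - half, bias + half),
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 sd_diff = s, n = n, p_bias = p),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.3f [%.3f, %.3f], LoA [%.3f, %.3f], n = %d, p = %.3g\n",
    x$bias, x$bias_ci[1], x$bias_ci[2], x$loa_lower, x$loa_upper, x$n,
    x$p_bias))
  invisible(x)
}
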