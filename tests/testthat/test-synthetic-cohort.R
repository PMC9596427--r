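# Synthetic-cohort generator: determinism, lesion kinetics, normative set.

test_that("same config and seed give byte-identical cohorts", {
  cfg <- small_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$masks, b$masks)
  expect_identical(a$maps, b$maps)
  expect_identical(a$normative$maps, b$normative$maps)
  c2 <- generate_cohort(small_config(seed = 12))
  expect_false(identical(a$maps[[1]][["0"]]$ONL, c2$maps[[1]][["0"]]$ONL))
})

test_that("config invariants are enforced", {
  expect_error(trial_config(visit_months = c(0, 6, 2, 12)), "increasing")
  expect_error(trial_config(visit_months = c(0, 2, 6)), "month 12")
  expect_error(trial_config(pixel_pitch_deg = 0), "positive")
  expect_error(trial_config(n_per_arm = 0), "positive")
  expect_error(trial_config(noise_sd = -1), ">= 0")
  expect_error(
    trial_config(treatment_growth_reduction = c(sham_pooled = 0,
                                                monthly = 1, eom = 0.2)),
    "\\[0, 1\\)")
})

test_that("lesion masks are nested and sqrt-area grows at configured rates", {
  cfg <- trial_config(n_per_arm = 10, pixel_pitch_deg = 0.2,
                      n_normative = 3, seed = 21)
  coh <- generate_cohort(cfg, include_maps = FALSE, include_fellow = FALSE)
  for (eid in names(coh$masks)) {
    months <- sort(as.numeric(names(coh$masks[[eid]])))
    for (i in seq_along(months)[-1]) {
      m_prev <- coh$masks[[eid]][[as.character(months[i - 1])]]
      m_cur <- coh$masks[[eid]][[as.character(months[i])]]
      expect_true(all(m_cur[m_prev]), label = "masks nested over time")
    }
  }
  # per-eye least-squares slope of sqrt-area on years recovers the rate
  areas <- cohort_lesion_areas(coh)
  slopes <- areas |>
    dplyr::group_by(eye_id, arm) |>
    dplyr::summarise(slope = coef(lm(sqrt_area_mm ~ I(visit_month / 12)))[2],
                     .groups = "drop")
  by_arm <- tapply(slopes$slope, slopes$arm, mean)
  expect_equal(unname(by_arm[["sham_pooled"]]), 0.30, tolerance = 0.05)
  expect_equal(unname(by_arm[["monthly"]]), 0.30 * 0.75, tolerance = 0.05)
  expect_equal(unname(by_arm[["eom"]]), 0.30 * 0.778, tolerance = 0.05)
  expect_lt(by_arm[["monthly"]], by_arm[["sham_pooled"]])
})

test_that("fellow-eye traveling-ring features have no longitudinal trend", {
  cfg <- trial_config(n_per_arm = 6, pixel_pitch_deg = 0.25,
                      n_normative = 15, seed = 31)
  coh <- generate_cohort(cfg)
  model <- fit_normative(coh$normative)
  feats <- suppressWarnings(
    extract_cohort_features(coh, model, n_rings = 6))
  fellow <- dplyr::filter(feats, eye_role == "fellow", layer == "ONL",
                          ring == 6)
  slope <- coef(lm(mean_z ~ I(visit_month / 12), data = fellow))[2]
  expect_lt(abs(slope), 0.1)
})

test_that("normative set: zero noise reproduces the mean surface exactly", {
  cfg <- small_config(normative_noise_scale = 0)
  ns <- generate_normative_set(cfg, seed = 5)
  n <- nrow(ns$maps[[1]]$ONL)
  for (i in c(1, 3)) {
    mu <- junctionzone:::layer_mean_surface("ONL", n, cfg$pixel_pitch_deg) +
      junctionzone:::layer_age_slope("ONL") * ns$ages[i]
    if (ns$lateralities[i] == "L") mu <- junctionzone:::mirror_horizontal(mu)
    expect_equal(ns$maps[[i]]$ONL, pmax(mu, 0), tolerance = 1e-12)
  }
})

test_that("normative set: per-pixel age regression recovers the slope", {
  cfg <- trial_config(n_per_arm = 2, pixel_pitch_deg = 0.5,
                      n_normative = 60, seed = 8)
  ns <- generate_normative_set(cfg, seed = 8)
  # independent per-pixel least squares on a handful of pixels
  px <- cbind(c(5, 10, 20, 30), c(7, 35, 20, 12))
  common <- lapply(seq_along(ns$maps), function(i) {
    g <- ns$maps[[i]]$ONL
    if (ns$lateralities[i] == "L") g <- junctionzone:::mirror_horizontal(g)
    g
  })
  for (j in seq_len(nrow(px))) {
    y <- vapply(common, function(g) g[px[j, 1], px[j, 2]], numeric(1))
    sl <- coef(lm(y ~ ns$ages))[2]
    # truth -0.25 um/y; noise SD 3 um over 60 eyes spanning ~40 y
    expect_lt(abs(unname(sl) - (-0.25)), 0.12)
  }
  expect_error(generate_normative_set(small_config(n_normative = 2)),
               "at least 3")
  s1 <- generate_normative_set(cfg, seed = 1)
  s2 <- generate_normative_set(cfg, seed = 2)
  expect_false(identical(s1$maps[[1]]$ONL, s2$maps[[1]]$ONL))
})

test_that("without deficit and drift, study maps match the normative population", {
  # two-sample location test on per-map pixel means, alpha = 0.01: the
  # rejection rate across seeds stays at the nominal level
  rejections <- 0
  n_seeds <- 15
  for (s in seq_len(n_seeds)) {
    cfg <- trial_config(n_per_arm = 3, pixel_pitch_deg = 0.5,
                        n_normative = 10, seed = 600 + s,
                        junctional_deficit_depth_z = 0,
                        macula_wide_drift = c(sham_pooled = 0, monthly = 0,
                                              eom = 0))
    coh <- generate_cohort(cfg, include_fellow = FALSE)
    base_maps <- lapply(names(coh$maps), function(eid)
      coh$maps[[eid]][["0"]]$ONL)
    ages <- coh$manifest$age[match(names(coh$maps), coh$manifest$eye_id)]
    adj <- function(m, age) mean(m) - junctionzone:::layer_age_slope("ONL") * age
    study_means <- mapply(adj, base_maps, ages)
    norm_means <- mapply(adj, lapply(coh$normative$maps, `[[`, "ONL"),
                         coh$normative$ages)
    p <- t.test(study_means, norm_means)$p.value
    rejections <- rejections + (p < 0.01)
  }
  expect_lte(rejections, 2)
})

test_that("ring-level simulator matches the generative marginal", {
  cfg <- trial_config(n_per_arm = 60)
  ft <- simulate_ring_features(cfg, ring_indices = c(6, 12), seed = 77)
  ch <- build_change_table(ft)
  m12 <- dplyr::filter(ch, visit_month == 12, ring == 12)
  means <- tapply(m12$change_z, m12$arm, mean)
  # expected change at month 12 is the arm drift (z/year) times one year
  expect_equal(unname(means[["sham_pooled"]]), -0.30, tolerance = 0.09)
  expect_equal(unname(means[["monthly"]]), 0, tolerance = 0.09)
  # deficit term cancels between rings in change scores, so ring 6 and 12
  # share the same expectation
  m12r6 <- dplyr::filter(ch, visit_month == 12, ring == 6)
  expect_equal(mean(m12r6$change_z[m12r6$arm == "sham_pooled"]),
               -0.30, tolerance = 0.09)
})
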