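# Change-from-baseline mixed models, contrasts, progression model,
# Bland-Altman.

test_that("change table equals a join-and-subtract oracle", {
  ft <- toy_features()
  ct <- build_change_table(ft)
  # direct oracle via merge
  base <- ft[ft$visit_month == 0, c("participant_id", "mean_z")]
  names(base)[2] <- "b"
  oracle <- merge(ft[ft$visit_month > 0, ], base, by = "participant_id")
  oracle$chg <- oracle$mean_z - oracle$b
  m <- merge(as.data.frame(ct), oracle,
             by = c("participant_id", "visit_month"))
  expect_equal(nrow(ct), sum(ft$visit_month > 0))
  expect_equal(m$change_z, m$chg)
  expect_equal(m$baseline_z, m$b)
  # an eye with constant z has zero change
  ft2 <- ft
  ft2$mean_z[ft2$participant_id == "P01"] <- 0.5
  ct2 <- build_change_table(ft2)
  expect_true(all(ct2$change_z[ct2$participant_id == "P01"] == 0))
  # worked pair: baseline 0.5, month 12 value 0.2 -> change -0.3
  ft3 <- ft
  ft3$mean_z[ft3$participant_id == "P02" & ft3$visit_month == 0] <- 0.5
  ft3$mean_z[ft3$participant_id == "P02" & ft3$visit_month == 12] <- 0.2
  ct3 <- build_change_table(ft3)
  expect_equal(ct3$change_z[ct3$participant_id == "P02" &
                              ct3$visit_month == 12], -0.3)
})

test_that("eyes without baseline are dropped with a warning", {
  ft <- toy_features()
  ft <- ft[!(ft$participant_id == "P03" & ft$visit_month == 0), ]
  expect_warning(ct <- build_change_table(ft), "without baseline")
  expect_false("P03" %in% ct$participant_id)
})

test_that("near-deterministic additive construction is recovered exactly", {
  arms <- c("monthly", "eom", "sham_pooled")
  d <- expand.grid(participant_id = sprintf("P%02d", 1:12),
                   visit_month = c(2, 12), stringsAsFactors = FALSE)
  d$arm <- arms[(match(d$participant_id, unique(d$participant_id)) - 1) %% 3 + 1]
  d$layer <- "ONL"; d$ring_distance_deg <- 5.16; d$eye_role <- "study"
  d$baseline_z <- seq(-0.5, 0.5, length.out = 12)[
    match(d$participant_id, unique(d$participant_id))]
  eff <- c(monthly = 0.3, eom = 0.1, sham_pooled = 0)
  set.seed(2)
  d$change_z <- eff[d$arm] * (d$visit_month / 12) + 0.4 * d$baseline_z +
    rnorm(nrow(d), 0, 1e-7)
  fit <- suppressMessages(fit_change_lmm(tibble::as_tibble(d)))
  fe <- lme4::fixef(fit$fit)
  expect_equal(unname(fe[["baseline_z"]]), 0.4, tolerance = 1e-6)
  res <- suppressWarnings(arm_contrasts(fit, 12))
  est <- res$contrasts$estimate
  names(est) <- res$contrasts$contrast
  expect_equal(unname(est[["monthly - sham_pooled"]]), 0.3,
               tolerance = 1e-6)
  expect_equal(unname(est[["eom - sham_pooled"]]), 0.1, tolerance = 1e-6)
})

test_that("fixed effects equal a generalized-least-squares oracle", {
  cfg <- trial_config(n_per_arm = 12)
  ft <- simulate_ring_features(cfg, ring_indices = 12, seed = 55)
  ct <- build_change_table(ft)
  fit <- suppressMessages(fit_change_lmm(ct))
  f <- fit$fit
  X <- lme4::getME(f, "X")
  Zt <- as.matrix(lme4::getME(f, "Zt"))
  y <- lme4::getME(f, "y")
  vc <- as.data.frame(lme4::VarCorr(f))
  tau2 <- vc$vcov[vc$grp == "participant_id"]
  sig2 <- vc$vcov[vc$grp == "Residual"]
  V <- sig2 * diag(length(y)) + tau2 * crossprod(Zt)
  beta <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y))
  expect_equal(unname(lme4::fixef(f)), as.vector(beta), tolerance = 1e-6)
})

test_that("contrast arithmetic and invariances hold", {
  cfg <- trial_config(n_per_arm = 10)
  ft <- simulate_ring_features(cfg, ring_indices = 12, seed = 66)
  ct <- build_change_table(ft)
  fit <- suppressMessages(fit_change_lmm(ct))
  res <- suppressWarnings(arm_contrasts(fit, c(6, 12)))
  for (v in c(6, 12)) {
    cc <- res$contrasts[res$contrasts$visit_month == v, ]
    est <- setNames(cc$estimate, cc$contrast)
    expect_equal(est[["monthly - sham_pooled"]],
                 est[["monthly - eom"]] + est[["eom - sham_pooled"]],
                 tolerance = 1e-10)
    expect_true(all(cc$ci_low <= cc$estimate & cc$estimate <= cc$ci_high))
    expect_true(all(cc$p_adjusted >= 0 & cc$p_adjusted <= 1))
    expect_equal(nrow(cc), 3)
  }
  # location invariance: shifting all change scores leaves contrasts alone
  ct2 <- dplyr::mutate(ct, change_z = change_z + 5)
  fit2 <- suppressMessages(fit_change_lmm(ct2))
  res2 <- suppressWarnings(arm_contrasts(fit2, 12))
  expect_equal(res2$contrasts$estimate,
               res$contrasts$estimate[res$contrasts$visit_month == 12],
               tolerance = 1e-6)
})

test_that("a family of one contrast needs no adjustment", {
  cfg <- trial_config(n_per_arm = 10, arms = c("sham_pooled", "monthly"),
                      treatment_growth_reduction = c(sham_pooled = 0,
                                                     monthly = 0.25),
                      macula_wide_drift = c(sham_pooled = -0.3, monthly = 0))
  ft <- simulate_ring_features(cfg, ring_indices = 12, seed = 44)
  ct <- build_change_table(ft)
  fit <- suppressMessages(fit_change_lmm(ct))
  expect_warning(res <- arm_contrasts(fit, 12), "fewer than 3 arms")
  cc <- res$contrasts
  expect_equal(nrow(cc), 1)
  p_raw <- 2 * pt(-abs(cc$t_ratio), cc$approx_df)
  expect_equal(cc$p_adjusted, p_raw, tolerance = 1e-6)
})

test_that("satterthwaite and kenward-roger df agree on balanced designs", {
  cfg <- trial_config(n_per_arm = 12)
  ft <- simulate_ring_features(cfg, ring_indices = 12, seed = 99)
  ct <- build_change_table(ft)
  f_sat <- suppressMessages(fit_change_lmm(ct, df_method = "satterthwaite"))
  f_kr <- suppressMessages(fit_change_lmm(ct, df_method = "kenward-roger"))
  r_sat <- suppressWarnings(arm_contrasts(f_sat, 12, ci = FALSE))
  r_kr <- suppressWarnings(arm_contrasts(f_kr, 12, ci = FALSE))
  expect_equal(r_sat$contrasts$estimate, r_kr$contrasts$estimate,
               tolerance = 1e-8)
  expect_equal(r_sat$contrasts$approx_df, r_kr$contrasts$approx_df,
               tolerance = 0.1)
})

test_that("uniform growth yields null progression contrasts", {
  d <- expand.grid(participant_id = sprintf("P%02d", 1:15),
                   visit_month = c(0, 2, 6, 12, 18),
                   stringsAsFactors = FALSE)
  d$arm <- c("monthly", "eom", "sham_pooled")[
    (match(d$participant_id, unique(d$participant_id)) - 1) %% 3 + 1]
  set.seed(1)
  b0 <- runif(15, 2, 3.5)
  d$sqrt_area_mm <- b0[match(d$participant_id, unique(d$participant_id))] +
    0.3 * d$visit_month / 12 + rnorm(nrow(d), 0, 1e-3)
  pr <- suppressMessages(fit_ga_progression(tibble::as_tibble(d)))
  expect_true(all(abs(pr$reduction$sham_minus_arm_mm_per_year) < 0.01))
  expect_true(all(abs(pr$reduction$pct_reduction_month12) < 5))
  expect_equal(unname(pr$slope_by_arm[["sham_pooled"]]), 0.3,
               tolerance = 0.01)
})

test_that("bland_altman matches its definition and a bootstrap oracle", {
  x <- c(1, 2, 3, 4.5)
  expect_identical(bland_altman(x, x)$bias, 0)
  expect_equal(bland_altman(x, x)$loa_lower, 0)
  ba <- bland_altman(x, x - 0.02)
  expect_equal(ba$bias, 0.02, tolerance = 1e-12)
  expect_error(bland_altman(1:4, 1:5), "equal length")
  expect_error(bland_altman(1:2, 2:3), "at least 3")

  set.seed(31)
  n <- 150
  xx <- rnorm(n, 2.8, 0.7)
  yy <- xx + rnorm(n, 0.02, 0.05)
  ba <- bland_altman(xx, yy)
  dd <- xx - yy
  boot <- replicate(2e4, mean(sample(dd, n, replace = TRUE)))
  bci <- quantile(boot, c(0.025, 0.975))
  half_t <- diff(ba$bias_ci) / 2
  half_b <- diff(bci) / 2
  expect_equal(ba$bias, mean(dd))
  expect_equal(unname(half_t), unname(half_b), tolerance = 0.1)
  expect_equal(mean(ba$bias_ci), mean(bci), tolerance = 0.005)
  # limits symmetric about the bias
  expect_equal(ba$loa_upper - ba$bias, ba$bias - ba$loa_lower,
               tolerance = 1e-12)
})
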