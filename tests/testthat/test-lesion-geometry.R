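# Contour-ring geometry: distance binning, traveling property, areas,
# unit conversion.

test_that("nominal ring distances follow k * 0.43 degrees", {
  m <- centered_disk(60, 0.2, 2)
  r <- compute_contour_rings(m, 0.2, n_rings = 12)
  expect_equal(r$ring_distance_deg[c(1, 6, 12)], c(0.43, 2.58, 5.16))
})

test_that("ring binning matches the brute-force distance oracle", {
  n <- 100; pitch <- 0.2
  mask <- centered_disk(n, pitch, 1.5)
  r <- compute_contour_rings(mask, pitch, ring_width_deg = 0.43,
                             n_rings = 8)
  d_oracle <- brute_force_distance(mask, pitch)
  for (k in c(1, 4, 8)) {
    px <- r$pixels[[k]]
    expect_gt(length(px), 0)
    expect_true(all(d_oracle[px] > (k - 1) * 0.43 + 1e-12))
    expect_true(all(d_oracle[px] <= k * 0.43 + 1e-12))
  }
  # union of rings 1..K = all exterior pixels within K * w of the lesion
  in_rings <- !is.na(r$ring_index)
  oracle_union <- d_oracle > 0 & d_oracle <= 8 * 0.43
  expect_identical(in_rings, oracle_union)
  # rings pairwise disjoint and outside the lesion
  expect_false(any(mask & in_rings))
  expect_equal(sum(r$n_pixels), sum(in_rings))
})

test_that("ring decomposition is rotation-equivariant", {
  mask <- matrix(FALSE, 40, 40)
  mask[8:15, 20:30] <- TRUE
  r1 <- compute_contour_rings(mask, 0.25, n_rings = 5)
  r2 <- compute_contour_rings(rot90(mask), 0.25, n_rings = 5)
  expect_identical(rot90(r1$ring_index), r2$ring_index)
})

test_that("rings travel with the lesion and never overlap the current mask", {
  cfg <- trial_config(n_per_arm = 2, pixel_pitch_deg = 0.25,
                      n_normative = 3, seed = 3)
  coh <- generate_cohort(cfg, include_maps = FALSE, include_fellow = FALSE)
  eid <- names(coh$masks)[1]
  months <- names(coh$masks[[eid]])
  areas <- numeric(length(months))
  for (i in seq_along(months)) {
    mask <- coh$masks[[eid]][[months[i]]]
    r <- suppressWarnings(compute_contour_rings(mask, 0.25, n_rings = 6))
    expect_false(any(mask[!is.na(r$ring_index)]))
    areas[i] <- lesion_area_mm2(mask, 0.25)
  }
  expect_true(all(diff(areas[order(as.numeric(months))]) >= 0))
  # the innermost ring at the last visit sits inside older rings' territory
  m_first <- coh$masks[[eid]][[months[1]]]
  m_last <- coh$masks[[eid]][[months[length(months)]]]
  r_last <- suppressWarnings(compute_contour_rings(m_last, 0.25, n_rings = 6))
  expect_false(any(m_last[!is.na(r_last$ring_index)]))
})

test_that("degenerate masks are rejected", {
  expect_error(compute_contour_rings(matrix(FALSE, 10, 10), 0.1), "empty")
  expect_error(compute_contour_rings(matrix(TRUE, 10, 10), 0.1),
               "whole frame")
  expect_error(lesion_distance_deg(matrix(0, 5, 5), 0.1), "empty")
})

test_that("frame-truncated rings are flagged and empty rings warn", {
  # lesion near the top edge (0.8 deg clearance): ring 1 fits, outer
  # rings run into the frame
  mask <- matrix(FALSE, 50, 50)
  mask[5:12, 22:30] <- TRUE
  r <- compute_contour_rings(mask, 0.2, n_rings = 6)
  expect_true(any(r$frame_clipped))
  expect_false(r$frame_clipped[1])
  # a mask filling all but a thin margin leaves outer rings empty
  mask2 <- matrix(TRUE, 30, 30)
  mask2[1:2, ] <- FALSE
  expect_warning(compute_contour_rings(mask2, 0.1, n_rings = 10),
                 "no pixels")
})

test_that("ring means equal oracle pixel-set means", {
  n <- 80; pitch <- 0.15
  mask <- centered_disk(n, pitch, 2)
  r <- compute_contour_rings(mask, pitch, n_rings = 6)
  d <- brute_force_distance(mask, pitch)
  z <- exp(-d / 2) + 0.1 * matrix(rnorm(n * n), n, n)  # radial ramp + noise
  ft <- extract_ring_means(z, r, metadata = list(participant_id = "P1"))
  for (k in ft$ring) {
    sel <- d > (k - 1) * 0.43 & d <= k * 0.43
    expect_equal(ft$mean_z[ft$ring == k], mean(z[sel]), tolerance = 1e-10)
    expect_equal(ft$n_pixels[ft$ring == k], sum(sel))
  }
  # constant map -> every ring mean equals the constant
  ftc <- extract_ring_means(matrix(1.7, n, n), r)
  expect_true(all(abs(ftc$mean_z - 1.7) < 1e-12))
})

test_that("clipped rings average over their available pixels", {
  n <- 60; pitch <- 0.2
  mask <- matrix(FALSE, n, n)
  mask[1:12, 25:35] <- TRUE  # lesion on the frame edge
  r <- compute_contour_rings(mask, pitch, n_rings = 4)
  d <- brute_force_distance(mask, pitch)
  z <- d * 0.5
  ft <- extract_ring_means(z, r)
  for (k in ft$ring) {
    sel <- d > (k - 1) * 0.43 & d <= k * 0.43
    expect_equal(ft$mean_z[ft$ring == k], mean(z[sel]), tolerance = 1e-10)
  }
})

test_that("dilation mode approximates the distance-transform partition", {
  n <- 70; pitch <- 0.2
  mask <- centered_disk(n, pitch, 1.5)
  r_edt <- compute_contour_rings(mask, pitch, n_rings = 4)
  r_dil <- compute_contour_rings(mask, pitch, n_rings = 4,
                                 method = "dilation")
  both <- !is.na(r_edt$ring_index) & !is.na(r_dil$ring_index)
  agree <- mean(r_edt$ring_index[both] == r_dil$ring_index[both])
  expect_gt(agree, 0.9)
  expect_false(any(mask[!is.na(r_dil$ring_index)]))
})

test_that("lesion area and sqrt-area behave as geometry dictates", {
  expect_equal(lesion_area_mm2(matrix(FALSE, 10, 10), 0.1), 0)
  # disk of radius 1 mm sampled at 10 um pixels -> area pi mm^2
  pitch_deg <- 0.010 / 0.291  # 10 um expressed in degrees
  n <- 250
  mask <- centered_disk(n, pitch_deg, 1 / 0.291)
  expect_equal(lesion_area_mm2(mask, pitch_deg), pi, tolerance = 0.01)
  expect_equal(lesion_sqrt_area_mm(mask, pitch_deg), sqrt(pi),
               tolerance = 0.005)
  expect_equal(sqrt(7.84), 2.80, tolerance = 1e-12)
})

test_that("degree-to-micron conversion uses the emmetropic scale", {
  expect_equal(deg_to_um(0), 0)
  expect_equal(deg_to_um(2), 582)
  expect_error(deg_to_um(-1), "non-negative")
  expect_error(deg_to_um("a"), "numeric")
})
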