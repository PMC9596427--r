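# Shared fixtures and oracles, all built in code.

# A small, fast trial configuration (50 x 50 grid).
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_per_arm = 3, pixel_pitch_deg = 0.4, n_normative = 8, seed = 11),
    list(...))
  do.call(trial_config, args)
}

# Centered disk lesion mask on an n x n grid (degrees).
centered_disk <- function(n, pitch, radius_deg, center_deg = c(0, 0)) {
  ax <- (seq_len(n) - (n + 1) / 2) * pitch
  dx <- ax - center_deg[1]
  dy <- ax - center_deg[2]
  sqrt(outer(dx^2, dy^2, "+")) <= radius_deg
}

# Brute-force nearest-lesion-pixel distance (degrees) for every pixel.
# The nearest lesion pixel to any exterior pixel is a lesion boundary pixel
# (an interior pixel always has a neighbour closer to the query), so the
# search runs over boundary pixels; distances are exact.
brute_force_distance <- function(mask, pitch) {
  mask <- mask != 0
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mask
  interior <- pad[1:n, 2:(m + 1)] & pad[3:(n + 2), 2:(m + 1)] &
    pad[2:(n + 1), 1:m] & pad[2:(n + 1), 3:(m + 2)]
  boundary <- which(mask & !interior, arr.ind = TRUE)
  d <- matrix(0, n, m)
  ext <- which(!mask, arr.ind = TRUE)
  if (nrow(ext) == 0) return(d)
  chunk <- 4000
  for (s in seq(1, nrow(ext), by = chunk)) {
    e <- min(s + chunk - 1, nrow(ext))
    blk <- ext[s:e, , drop = FALSE]
    d2 <- outer(blk[, 1], boundary[, 1], "-")^2 +
      outer(blk[, 2], boundary[, 2], "-")^2
    d[blk] <- sqrt(apply(d2, 1, min))
  }
  d * pitch
}

# Rotate a matrix by 90 degrees (counter-clockwise).
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Hand-built manifest exercising every population-filter rule.
fixture_manifest <- function() {
  row <- function(pid, role, arm, visits, rec, exp, exu = FALSE,
                  mnv = NA, farea = NA_real_) {
    tibble::tibble(
      participant_id = pid, eye_id = paste(pid, role, sep = "_"),
      eye_role = role, arm = arm, age = 79, sex = "F", laterality = "R",
      visit_month = visits, injections_received_to_month12 = rec,
      injections_expected = exp, exudation_ever = exu, fellow_mnv = mnv,
      fellow_baseline_area_mm2 = farea, faf_sqrt_area_mm = 2.8,
      ga_beyond_frame = FALSE)
  }
  dplyr::bind_rows(
    row("M9", "study", "monthly", c(0, 2, 12), 9L, 12L),
    row("M8", "study", "monthly", c(0, 2, 12), 8L, 12L),
    row("E4", "study", "eom", c(0, 2, 12), 4L, 6L),
    row("E3", "study", "eom", c(0, 2, 12), 3L, 6L),
    row("S1", "study", "sham_pooled", c(0, 2, 12), 12L, 12L, exu = TRUE),
    row("B0", "study", "monthly", 0, 12L, 12L),          # baseline only
    row("N0", "study", "eom", c(0, 2), 0L, 6L),          # never injected
    row("M9", "fellow", "monthly", c(0, 2, 12), 9L, 12L,
        mnv = FALSE, farea = 2.6),
    row("E4", "fellow", "eom", c(0, 2, 12), 4L, 6L,
        mnv = FALSE, farea = 2.4),
    row("S1", "fellow", "sham_pooled", c(0, 2, 12), 12L, 12L,
        mnv = TRUE, farea = 5.0)
  )
}

# Deterministic ring-feature table for join/contrast tests.
toy_features <- function() {
  grid <- expand.grid(participant_id = sprintf("P%02d", 1:6),
                      visit_month = c(0, 2, 12),
                      layer = "ONL", ring_distance_deg = 5.16,
                      stringsAsFactors = FALSE)
  grid$eye_role <- "study"
  grid$arm <- rep(c("monthly", "eom", "sham_pooled"), each = 2)[
    match(grid$participant_id, sprintf("P%02d", 1:6))]
  grid$mean_z <- round(seq(-0.5, 0.6, length.out = nrow(grid)), 2)
  grid$n_pixels <- 100L
  tibble::as_tibble(grid)
}
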