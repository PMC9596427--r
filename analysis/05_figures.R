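#!/usr/bin/env Rscript

# Step 5 - figures.
#
# Two summary figures from the tables written by steps 2-4: the junctional
# z profile by contour distance and visit (thinning gradient), and the
# least-squares mean change at the 5.16 deg contour line over time by arm
# (the dose- and time-dependent treatment effect).

suppressMessages({
  library(junctionzone)
  library(ggplot2)
})

dir.create("scratch/figures", recursive = TRUE, showWarnings = FALSE)

features <- utils::read.csv("scratch/ring_features.csv")
lsm <- utils::read.csv("results/main_grid/lsmeans.csv")

prof <- features |>
  dplyr::filter(eye_role == "study", layer == "ONL") |>
  dplyr::group_by(ring_distance_deg, visit_month, arm) |>
  dplyr::summarise(mean_z = mean(mean_z), .groups = "drop")

p1 <- ggplot(prof, aes(ring_distance_deg, mean_z, colour = arm)) +
  geom_line() +
  facet_wrap(~visit_month, labeller = label_both) +
  geom_vline(xintercept = c(0.43, 2.58, 5.16), linetype = "dashed",
             linewidth = 0.3) +
  labs(x = "distance to atrophy boundary (deg)",
       y = "mean ONL thickness (z-score)",
       title = "Junctional ONL thinning gradient by visit and arm") +
  theme_minimal()
ggsave("scratch/figures/junctional_profile.pdf", p1, width = 9, height = 6)

lsm12 <- dplyr::filter(lsm, population == "mITT",
                       abs(ring_distance_deg - 5.16) < 1e-8)
p2 <- ggplot(lsm12, aes(visit_month, lsmean, colour = arm)) +
  geom_pointrange(aes(ymin = ci_low, ymax = ci_high),
                  position = position_dodge(width = 1)) +
  geom_line(position = position_dodge(width = 1)) +
  facet_wrap(~layer) +
  geom_hline(yintercept = 0, linewidth = 0.3) +
  labs(x = "month", y = "adjusted mean change from baseline (z)",
       title = "Change along the 5.16 deg contour line (mITT)") +
  theme_minimal()
ggsave("scratch/figures/change_over_time.pdf", p2, width = 9, height = 4)

message("figures written to scratch/figures/")
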