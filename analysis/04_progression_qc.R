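#!/usr/bin/env Rscript

# Step 4 - atrophy progression and geometry quality control.
#
# Fits the sqrt-area progression model on study eyes whose lesion stays
# inside the image frame, reports per-arm growth rates and the percentage
# growth reduction under treatment, and checks mask-derived areas against
# the reference measurement by Bland-Altman.

suppressMessages(library(junctionzone))

cohort <- read_cohort("scratch/cohort")
manifest <- cohort$manifest

mitt <- apply_population_filter(manifest, "mITT")
in_frame <- mitt[!mitt$ga_beyond_frame, ]
areas <- cohort_lesion_areas(cohort)
areas <- areas[paste(areas$eye_id, areas$visit_month) %in%
                 paste(in_frame$eye_id, in_frame$visit_month), ]

prog <- fit_ga_progression(areas)
print(prog)
utils::write.csv(prog$reduction, "results/ga_progression.csv",
                 row.names = FALSE)

base <- areas[areas$visit_month == 0, ]
ref <- manifest$faf_sqrt_area_mm[match(base$eye_id, manifest$eye_id)]
qc <- geometry_qc(base$sqrt_area_mm, ref)
print(qc)
utils::write.csv(
  data.frame(bias = qc$bias, ci_low = qc$bias_ci[1], ci_high = qc$bias_ci[2],
             loa_lower = qc$loa_lower, loa_upper = qc$loa_upper, n = qc$n,
             p_bias = qc$p_bias),
  "results/geometry_qc.csv", row.names = FALSE)

message(sprintf(
  "Excluded from area QC (lesion beyond frame): %d of %d mITT study eyes",
  length(unique(mitt$eye_id)) - length(unique(in_frame$eye_id)),
  length(unique(mitt$eye_id))))
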