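#!/usr/bin/env Rscript
# Step 1 — generate the synthetic two-source MS cohort.
#
# Emulates a hospital EHR extract (source A, 2642 records) and its
# deidentified registry representation (source B, 2247 records = 85% of A,
# fresh ids), with known truth links. A second, corrupted variant (10%
# per-field error on the clinical identifiers) stands in for the messier
# real-world pairing used by steps 2-5.

suppressPackageStartupMessages(library(linkehr))

cfg_path <- system.file("extdata", "experiment.yaml", package = "linkehr")
cfg <- read_experiment_config(cfg_path)
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

clean_cfg <- do.call(cohort_config, cfg$cohort)
co <- generate_cohort(clean_cfg)
write_records(co$A, file.path(out, "A.csv"))
write_records(co$B, file.path(out, "B.csv"))
write_truth(co$truth, file.path(out, "truth.csv"))
cat(sprintf("clean cohort: |A| = %d, |B| = %d, |truth| = %d\n",
            nrow(co$A), nrow(co$B), nrow(co$truth)))

corrupt_cfg <- do.call(cohort_config, c(cfg$cohort, list(
  corruption = c(nationality = 0.1, coverage = 0.1, facility = 0.1,
                 ms_first_dx_date = 0.1, medications = 0.1, admissions = 0.1),
  missingness = c(nationality = 0.02, coverage = 0.02))))
cc <- generate_cohort(corrupt_cfg)
write_records(cc$A, file.path(out, "A_corrupt.csv"))
write_records(cc$B, file.path(out, "B_corrupt.csv"))
write_truth(cc$truth, file.path(out, "truth_corrupt.csv"))
cat(sprintf("corrupted cohort: |A| = %d, |B| = %d, |truth| = %d\n",
            nrow(cc$A), nrow(cc$B), nrow(cc$truth)))
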