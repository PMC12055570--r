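#!/usr/bin/env Rscript
# Preprocessing and enrichment curves.
#
# Reads the raw cohort peak areas from 01, runs internal-standard
# normalization, the 30% triplicate outlier rule, imputation and the
# isotope-ratio / enrichment computations, and writes the per-subject
# normalized %[15N] enrichment curves plus the control mean +/- SEM curves
# used for graphical comparison.

library(ureatrace)

cfg <- read_assay_config("results/assay_config.yaml")
records <- read_assay_csv("results/cohort_peak_areas.csv")
subjects <- read.csv("results/cohort_subjects.csv", stringsAsFactors = FALSE)

pl <- run_pipeline(records, subjects, cfg)

write_pipeline_csv(pl, curves_path = "results/enrichment_curves.csv")
write.csv(pl$reference$mean_curves, "results/control_mean_curves.csv",
          row.names = FALSE)

n_out <- sum(pl$results$n_outliers)
n_inv <- sum(pl$results$n_invalid_triplicates)
message(sprintf("processed %d assays: %d triplicate runs rejected by the 30%% rule, %d triplicates invalidated",
                nrow(pl$results), n_out, n_inv))

peak <- subset(pl$reference$mean_curves, time_min == 45)
message("control mean enrichment at 45 min (%):")
print(peak[order(-peak$mean_ie), c("metabolite", "mean_ie", "sem_ie")],
      row.names = FALSE, digits = 3)
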