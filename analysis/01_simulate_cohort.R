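#!/usr/bin/env Rscript
# Simulate the synthetic screening cohort that stands in for the clinical
# mammography dataset: 10,000 patients, entry ages ~ Normal(56.5, 12.7)
# truncated to the model horizon, mostly-low risk scores evolving by the
# shipped ground-truth kernel, 2-3 year exam gaps, single-exam patients,
# and a cancer detection rate calibrated to 9.7 per 1000 exams.

suppressPackageStartupMessages(library(biopsyMDP))

out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(n_patients = 10000L, seed = 1L)
cohort <- generate_cohort(cfg)

write_trajectories(cohort$trajectories, file.path(out_dir, "trajectories.csv"))
data.table::fwrite(cohort$outcomes, file.path(out_dir, "outcomes.csv"))
write_kernel(cohort$ground_truth$kernel, file.path(out_dir, "true_kernel.csv"))

tr <- cohort$trajectories
entry <- tr[, .(age = min(age), n = .N), by = finding_id]
cat(sprintf("patients: %d; exams: %d (%.2f per patient)\n",
            nrow(entry), nrow(tr), nrow(tr) / nrow(entry)))
cat(sprintf("entry age: mean %.1f, sd %.1f (clipped to [%g, %g])\n",
            mean(entry$age), sd(entry$age),
            cfg$age_range[1], cfg$age_range[2]))
cat(sprintf("single-exam patients (excluded from estimation): %d\n",
            sum(entry$n == 1L)))
cat(sprintf("cancer rate per exam: %.4f (target %.4f)\n",
            mean(cohort$outcomes$cancer), cfg$cancer_rate_per_exam))
cat("wrote", out_dir, "\n")
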