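#!/usr/bin/env Rscript
# Solve the base-case MDP (disutility 2 weeks at 40 doubling by 100, 75%
# invasive, treatment-effect factor 1.6) on the estimated kernel and
# extract the age-indexed optimal biopsy threshold.

suppressPackageStartupMessages(library(biopsyMDP))

kernel <- read_kernel("results/kernel.csv")
tables <- read_fixture_tables()

curve <- run_base_case(kernel, tables)
sol <- attr(curve, "solution")

data.table::fwrite(as.data.frame(curve), "results/threshold_curve.csv")
pol <- data.table::data.table(
  age = as.integer(rep(rownames(sol$policy), ncol(sol$policy))),
  risk_score = as.integer(rep(colnames(sol$policy), each = nrow(sol$policy))),
  action = as.vector(sol$policy))
data.table::setorder(pol, age, risk_score)
data.table::fwrite(pol, "results/policy.csv")

cat("optimal biopsy threshold (% risk) by age:\n")
print(as.data.frame(curve)[curve$age %in% c(40, 42, 50, 60, 70, 75, 80, 90, 99), ],
      row.names = FALSE)
cat(sprintf("control-limit structure at every age: %s\n",
            all(curve$control_limit)))
bands <- list("<42" = curve$threshold[curve$age < 42],
              "42-75" = curve$threshold[curve$age >= 42 & curve$age <= 75],
              ">75" = curve$threshold[curve$age > 75])
for (b in names(bands))
  cat(sprintf("ages %-6s threshold range %d..%d%%\n", b,
              min(bands[[b]]), max(bands[[b]])))
cat("wrote results/threshold_curve.csv, results/policy.csv\n")
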