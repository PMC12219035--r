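#!/usr/bin/env Rscript
# Step 3 — formula performance in the three study contexts.
#
# Runs the full study on the simulated cohorts: (1) the US-like cohort with
# shipped constants, (2) the South-Indian-like cohort with shipped constants,
# and (3) the South-Indian-like held-out test split after constant
# optimization, plus the before/after paired t-tests and the
# Friedman/Wilcoxon-Bonferroni battery.  Writes the report bundle under
# results/study/.

suppressPackageStartupMessages(library(iolpred))

cfg <- study_config(
  cohorts = list(list(file = "results/cohorts/aravind_like.csv"),
                 list(file = "results/cohorts/umich_like.csv")),
  roster = c("SRKT", "HofferQ", "Holladay1", "Haigis"),
  optimize_on = "aravind_like",
  split = list(train_fraction = 0.70, seed = 20260920L))

bundle <- run_study(cfg, out_dir = "results/study")

cat("performance summaries (MAE / ME / % within 0.5 D):\n")
s <- bundle$summaries
for (i in seq_len(nrow(s))) {
  cat(sprintf("  %-26s %-10s MAE %.3f  ME %+.3f  within0.5 %5.1f%%\n",
              s$cohort[i], s$formula[i], s$MAE_D[i], s$ME_D[i],
              s$pct_within_0.5[i]))
}
cat("\nbefore-vs-after paired t-tests on held-out absolute errors:\n")
print(as.data.frame(bundle$ttests), digits = 3)
cat("\n")
print(bundle$comparison)
cat("\nbundle written to results/study (audit: train/test disjoint = ",
    bundle$audit$train_test_disjoint, ")\n", sep = "")
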