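#!/usr/bin/env Rscript
# Step 2 — lens-constant optimization on the training split.
#
# Splits the simulated South-Indian-like cohort 70/30, re-optimizes each
# formula's lens constant to zero the training mean error, and writes the
# shipped-vs-optimized constants table to results/constants.csv.  The 30%
# split is never touched here; step 3 evaluates on it.

suppressPackageStartupMessages(library(iolpred))

split_seed <- 20260920L
co <- read_cohort("results/cohorts/aravind_like.csv")
sp <- split_cohort(co, train_fraction = 0.70, seed = split_seed)
cat(sprintf("split: %d train / %d test (seed %d)\n",
            nrow(sp$train), nrow(sp$test), split_seed))

scalar_field <- c(SRKT = "A_const", HofferQ = "pACD_mm",
                  Holladay1 = "SF_mm", Haigis = "haigis_a0")
rows <- list()
for (f in names(scalar_field)) {
  dflt <- default_constants(f)
  opt <- optimize_constant(f, sp$train)
  scalar <- scalar_field[[f]]
  me_before <- mean_error(f, sp$train, dflt)
  rows[[f]] <- data.frame(
    formula = f, constant = scalar,
    shipped = dflt[[scalar]], optimized = opt[[scalar]],
    train_ME_before = me_before,
    train_ME_after = attr(opt, "train_ME_D"))
  cat(sprintf("%-10s %s: %8.3f -> %8.3f   (train ME %+0.3f -> %+.1e D)\n",
              f, scalar, dflt[[scalar]], opt[[scalar]], me_before,
              attr(opt, "train_ME_D")))
}
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
utils::write.csv(tab, "results/constants.csv", row.names = FALSE)
cat("constants written to results/constants.csv\n")
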