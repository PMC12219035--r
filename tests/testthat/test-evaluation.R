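test_that("performance summary follows the metric definitions", {
  s <- summarize_performance(c(0.1, -0.3, 0.2))
  expect_equal(s$ME_D, 0)
  expect_equal(s$MAE_D, 0.2)
  expect_equal(s$MedAE_D, 0.2)
  expect_equal(s$RMSAE_D, sqrt(0.14 / 3))
  expect_equal(s$pct_within_0.25, 100 * 2 / 3)
  expect_equal(s$pct_within_0.5, 100)

  z <- summarize_performance(rep(0, 10))
  expect_equal(z$ME_D, 0)
  expect_equal(z$RMSAE_D, 0)
  expect_equal(z$SD_D, 0)
  expect_equal(z$pct_within_0.25, 100)

  # threshold is inclusive: |e| == t counts as within
  b <- summarize_performance(c(0.25, -0.25, 0.26))
  expect_equal(b$pct_within_0.25, 100 * 2 / 3)

  expect_error(summarize_performance(numeric(0)), class = "iol_domain_error")
})

test_that("summary metrics equal a brute-force loop on a large vector", {
  set.seed(402)
  e <- stats::rnorm(1000, 0.02, 0.4)
  s <- summarize_performance(e)
  acc_me <- 0; acc_mae <- 0; acc_sq <- 0; n_in <- 0
  for (x in e) {
    acc_me <- acc_me + x
    acc_mae <- acc_mae + abs(x)
    acc_sq <- acc_sq + x^2
    if (abs(x) <= 0.5) n_in <- n_in + 1
  }
  expect_equal(s$ME_D, acc_me / 1000, tolerance = 1e-12)
  expect_equal(s$MAE_D, acc_mae / 1000, tolerance = 1e-12)
  expect_equal(s$RMSAE_D, sqrt(acc_sq / 1000), tolerance = 1e-12)
  expect_equal(s$pct_within_0.5, 100 * n_in / 1000, tolerance = 1e-12)
})

test_that("metric identities hold on random error vectors", {
  set.seed(403)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    e <- stats::rnorm(n, stats::runif(1, -0.3, 0.3), stats::runif(1, 0.05, 1))
    s <- summarize_performance(e)
    expect_lte(s$MAE_D, s$RMSAE_D)
    expect_equal(s$RMSAE_D^2, s$ME_D^2 + s$SD_D^2 * (n - 1) / n,
                 tolerance = 1e-12)
    pct <- unlist(s[grep("pct_within", names(s))])
    expect_true(all(diff(pct) >= 0))
  }
})

test_that("signed-rank test reproduces reference values (Pratt zeros)", {
  # expected values frozen from an independent reference implementation of
  # the same pinned convention (zeros ranked then dropped, mid-ranks,
  # tie/zero-corrected normal approximation, continuity correction)
  x1 <- c(0.31, 0.12, 0.55, 0.29, 0.44, 0.18, 0.61, 0.07, 0.33, 0.25, 0.40, 0.52)
  y1 <- c(0.28, 0.15, 0.50, 0.29, 0.39, 0.22, 0.55, 0.10, 0.30, 0.25, 0.35, 0.47)
  w1 <- wilcoxon_signed_rank(x1, y1)
  expect_equal(w1$statistic, 16)
  expect_equal(w1$p.value, 0.0975270224376884, tolerance = 1e-10)

  # 30 concordant equal differences: maximal signed-rank signal
  w2 <- wilcoxon_signed_rank((1:30) / 4 + 0.25, (1:30) / 4)
  expect_equal(w2$statistic, 0)
  expect_equal(w2$p.value, 4.61742795690643e-08, tolerance = 1e-10)

  x3 <- c(1.0, 1.2, 1.2, 0.8, 0.8, 1.5, 1.1, 0.9, 1.3, 1.0, 1.0, 0.7)
  y3 <- c(1.1, 1.0, 1.2, 0.9, 0.7, 1.2, 1.1, 1.1, 1.0, 1.2, 0.8, 0.9)
  w3 <- wilcoxon_signed_rank(x3, y3)
  expect_equal(w3$statistic, 33.5)
  expect_equal(w3$p.value, 0.782259590036808, tolerance = 1e-10)

  x4 <- c(2.1, 1.9, 2.5, 2.2, 1.8, 2.4, 2.0, 2.6, 1.7, 2.3, 2.05, 2.15, 1.95, 2.45)
  y4 <- c(2.0, 2.0, 2.2, 2.1, 1.9, 2.1, 2.2, 2.3, 1.8, 2.0, 2.00, 2.30, 2.10, 2.20)
  w4 <- wilcoxon_signed_rank(x4, y4)
  expect_equal(w4$statistic, 35)
  expect_equal(w4$p.value, 0.284214692586307, tolerance = 1e-10)

  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$p.value, 1)
})

test_that("Friedman statistic matches a hand-rank computation", {
  set.seed(404)
  m <- matrix(stats::runif(36), nrow = 12, ncol = 3,
              dimnames = list(NULL, c("A", "B", "C")))
  # hand computation: within-row ranks, column rank sums, classic statistic
  R <- t(apply(m, 1, rank))
  Rj <- colSums(R)
  n <- 12; k <- 3
  chi_hand <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  rep <- compare_formulas(m)
  expect_equal(rep$friedman_stat, chi_hand, tolerance = 1e-10)
  expect_equal(rep$friedman_df, k - 1)
})

test_that("identical columns give a zero Friedman statistic and no flags", {
  set.seed(405)
  col <- abs(stats::rnorm(15, 0.3, 0.1))
  m <- cbind(A = col, B = col, C = col)
  rep <- compare_formulas(m)
  expect_equal(rep$friedman_stat, 0)
  expect_equal(rep$friedman_p, 1)
  expect_false(any(rep$significant, na.rm = TRUE))
})

test_that("Bonferroni adjustment and flags behave as a multiplicity control", {
  set.seed(406)
  m <- cbind(A = abs(stats::rnorm(40, 0.30, 0.1)),
             B = abs(stats::rnorm(40, 0.33, 0.1)),
             C = abs(stats::rnorm(40, 0.55, 0.1)),
             D = abs(stats::rnorm(40, 0.31, 0.1)))
  rep <- compare_formulas(m)
  off <- upper.tri(rep$p_raw)
  expect_true(all(rep$p_adj[off] >= rep$p_raw[off]))
  expect_true(all(rep$p_adj[off] <= 1))
  # Bonferroni-significant pairs are a subset of raw-significant pairs
  expect_true(all(rep$p_raw[rep$significant] < rep$alpha))
  expect_equal(rep$p_adj[off], pmin(1, rep$p_raw[off] * 6), tolerance = 1e-12)
  # symmetric matrices, invariant under eye (row) permutation
  expect_equal(rep$p_raw, t(rep$p_raw))
  perm <- sample(nrow(m))
  rep_p <- compare_formulas(m[perm, ])
  expect_equal(rep_p$p_raw, rep$p_raw, tolerance = 1e-12)
  expect_equal(rep_p$friedman_stat, rep$friedman_stat, tolerance = 1e-12)
})

test_that("compare_formulas rejects malformed inputs", {
  m <- matrix(stats::runif(40), ncol = 2)
  expect_error(compare_formulas(m), class = "iol_domain_error")
  m3 <- matrix(stats::runif(12), ncol = 3)
  expect_error(compare_formulas(m3), class = "iol_domain_error")
  m4 <- matrix(stats::runif(60), ncol = 3)
  m4[5, 2] <- NA
  expect_error(compare_formulas(m4), "intersection",
               class = "iol_domain_error")
})

test_that("paired absolute-error t-test handles degenerate inputs", {
  x <- abs(stats::rnorm(20, 0.3, 0.1))
  id <- paired_abs_error_ttest(x, x)
  expect_equal(id$t, 0)
  expect_equal(id$p.value, 1)
  expect_true(id$degenerate)

  expect_warning(res <- paired_abs_error_ttest(x + 0.1, x), "zero variance")
  expect_true(res$degenerate)
  expect_true(is.na(res$p.value))
  expect_equal(res$mean_diff, 0.1)

  expect_error(paired_abs_error_ttest(x, x[-1]), class = "iol_domain_error")
})

test_that("paired t-test rejection rate matches its nominal power", {
  # stated world: true mean |error| reduction 0.03 D, sd of differences 0.1 D,
  # n = 296 pairs; nominal power from the closed-form paired power function
  nominal <- stats::power.t.test(n = 296, delta = 0.03, sd = 0.1,
                                 sig.level = 0.05, type = "paired")$power
  set.seed(407)
  nrep <- 2000
  rejections <- 0
  for (r in seq_len(nrep)) {
    base <- abs(stats::rnorm(296, 0.5, 0.15)) + 0.5
    d <- stats::rnorm(296, 0.03, 0.1)
    if (paired_abs_error_ttest(base, base - d)$p.value < 0.05) {
      rejections <- rejections + 1
    }
  }
  expect_lt(abs(rejections / nrep - nominal), 0.01)
})

test_that("cohort self-comparison is the exact null", {
  co <- generate_cohort(builtin_profile("aravind_like"), 120, seed = 55)
  tab <- cohort_comparison(co, co)
  num <- tab[tab$variable != "prop_right_eye", ]
  expect_true(all(abs(num$mean_a - num$mean_b) < 1e-12))
  expect_true(all(num$p_between > 0.999))
  expect_true(all(tab$p_between[tab$variable == "prop_right_eye"] > 0.999))
})

test_that("variables absent from a cohort are omitted with a note", {
  co <- generate_cohort(builtin_profile("aravind_like"), 60, seed = 56)
  cb <- co
  cb$LT_mm <- NA_real_
  tab <- cohort_comparison(co, cb)
  expect_false("LT_mm" %in% tab$variable)
  expect_true("LT_mm" %in% attr(tab, "omitted"))
})
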