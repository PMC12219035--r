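#' Summarize refraction prediction errors for one formula on one cohort
#'
#' Computes the standard refractive-outcome metrics from per-eye prediction
#' errors e = predicted - measured: mean error ME, mean absolute error MAE,
#' median absolute error MedAE, root mean square absolute error
#' RMSAE = sqrt(mean(e^2)), the sample standard deviation SD (n - 1
#' denominator), and the percentage of eyes with |e| within each threshold
#' (inclusive, `<=`).
#'
#' @param errors non-empty numeric vector of prediction errors, diopters.
#' @param thresholds absolute-error thresholds in diopters.
#' @param formula,cohort optional labels carried into the output.
#' @return one-row tibble with columns `formula`, `cohort`, `n`, `ME_D`,
#'   `MAE_D`, `MedAE_D`, `RMSAE_D`, `SD_D`, and `pct_within_<t>` per
#'   threshold.
#' @export
summarize_performance <- function(errors, thresholds = c(0.25, 0.5, 0.75, 1.0),
                                  formula = NA_character_,
                                  cohort = NA_character_) {
  if (!length(errors) || any(!is.finite(errors))) {
    stop_iol("errors must be a non-empty finite numeric vector",
             class = "iol_domain_error")
  }
  n <- length(errors)
  out <- tibble::tibble(
    formula = formula, cohort = cohort, n = n,
    ME_D = mean(errors),
    MAE_D = mean(abs(errors)),
    MedAE_D = stats::median(abs(errors)),
    RMSAE_D = sqrt(mean(errors^2)),
    SD_D = if (n > 1) stats::sd(errors) else 0
  )
  for (t in thresholds) {
    out[[sprintf("pct_within_%g", t)]] <- 100 * mean(abs(errors) <= t)
  }
  out
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Paired two-sided signed-rank test in the Pratt variant: zero differences
#' are included when ranking absolute differences and their ranks are then
#' dropped from the rank sums; ties receive mid-ranks.  The p-value uses the
#' normal approximation with the zero and tie variance corrections and a
#' continuity correction (the convention of scipy's
#' `wilcoxon(zero_method = "pratt", correction = TRUE, method = "approx")`,
#' pinned here because statistical packages differ in their zero handling).
#'
#' @param x,y paired numeric vectors.
#' @return list with `statistic` (min of the positive/negative rank sums),
#'   `z`, and two-sided `p.value`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) {
    stop_iol("paired vectors differ in length", class = "iol_domain_error")
  }
  d <- x - y
  n <- length(d)
  r <- rank(abs(d))                 # zeros participate in ranking (Pratt)
  r_plus <- sum(r[d > 0])
  r_minus <- sum(r[d < 0])
  W <- min(r_plus, r_minus)
  n_zero <- sum(d == 0)
  if (n_zero == n) {
    return(list(statistic = W, z = 0, p.value = 1))
  }
  mn <- n * (n + 1) / 4 - n_zero * (n_zero + 1) / 4
  se2 <- n * (n + 1) * (2 * n + 1) - n_zero * (n_zero + 1) * (2 * n_zero + 1)
  reps <- table(r[d != 0])  # zero differences do not enter the tie correction
  reps <- reps[reps > 1]
  if (length(reps)) se2 <- se2 - 0.5 * sum(as.numeric(reps)^3 - as.numeric(reps))
  se <- sqrt(se2 / 24)
  if (se == 0) return(list(statistic = W, z = 0, p.value = 1))
  corr <- 0.5 * sign(W - mn)
  z <- (W - mn - corr) / se
  list(statistic = W, z = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' Compare formulas on a shared eye set
#'
#' Runs the paired nonparametric battery on a matrix of absolute prediction
#' errors (rows = eyes, columns = formulas, same eyes in every column):
#' a Friedman test across formulas, then all pairwise two-sided Wilcoxon
#' signed-rank tests ([wilcoxon_signed_rank()]) with Bonferroni adjustment
#' over the number of pairs, flagging pairs with adjusted p < `alpha`.
#'
#' @param abs_errors numeric matrix of absolute errors with at least 3
#'   named columns (formulas) and 10 rows (eyes); no missing cells.
#' @param alpha significance level for the flags (default 0.05).
#' @return list of class `comparison_report`: `formulas`, `n_eyes`,
#'   `friedman_stat`, `friedman_df`, `friedman_p`, symmetric matrices
#'   `p_raw` and `p_adj`, logical matrix `significant`, and `alpha`.
#' @export
compare_formulas <- function(abs_errors, alpha = 0.05) {
  abs_errors <- as.matrix(abs_errors)
  if (ncol(abs_errors) < 3) {
    stop_iol("need at least 3 formulas to compare", class = "iol_domain_error")
  }
  if (nrow(abs_errors) < 10) {
    stop_iol("need at least 10 eyes", class = "iol_domain_error")
  }
  if (anyNA(abs_errors)) {
    stop_iol("missing cells in the error matrix; restrict to the ",
             "intersection of eyes covered by every formula upstream",
             class = "iol_domain_error")
  }
  forms <- colnames(abs_errors) %||% paste0("F", seq_len(ncol(abs_errors)))
  colnames(abs_errors) <- forms
  k <- length(forms)
  fr <- stats::friedman.test(abs_errors)
  if (!is.finite(fr$statistic)) {
    # degenerate no-signal case (every row fully tied): statistic 0, p = 1
    fr$statistic <- 0
    fr$p.value <- 1
  }
  m <- k * (k - 1) / 2
  p_raw <- matrix(NA_real_, k, k, dimnames = list(forms, forms))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      w <- wilcoxon_signed_rank(abs_errors[, i], abs_errors[, j])
      p_raw[i, j] <- p_raw[j, i] <- w$p.value
    }
  }
  p_adj <- p_raw * m
  p_adj[!is.na(p_adj) & p_adj > 1] <- 1
  list_out <- list(formulas = forms, n_eyes = nrow(abs_errors),
                   friedman_stat = unname(fr$statistic),
                   friedman_df = unname(fr$parameter),
                   friedman_p = fr$p.value,
                   p_raw = p_raw, p_adj = p_adj,
                   significant = !is.na(p_adj) & p_adj < alpha,
                   alpha = alpha)
  class(list_out) <- "comparison_report"
  list_out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", length(x$formulas), " formulas, ",
      x$n_eyes, " eyes\n", sep = "")
  cat(sprintf("Friedman chi-squared = %.4g (df = %d), p = %.3g\n",
              x$friedman_stat, x$friedman_df, x$friedman_p))
  sig <- which(x$significant & upper.tri(x$significant), arr.ind = TRUE)
  if (nrow(sig)) {
    cat("Bonferroni-significant pairs (alpha =", x$alpha, "):\n")
    for (i in seq_len(nrow(sig))) {
      cat("  ", x$formulas[sig[i, 1]], "vs", x$formulas[sig[i, 2]],
          sprintf("(adj p = %.3g)\n", x$p_adj[sig[i, 1], sig[i, 2]]))
    }
  } else cat("No Bonferroni-significant pairs at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Paired t-test on absolute errors under two constant settings
#'
#' Two-sided paired Student t-test comparing per-eye absolute errors of the
#' same formula on the same eyes under two lens-constant settings (e.g.
#' shipped vs population-optimized).  Zero variance of the differences is
#' degenerate: identical vectors return t = 0, p = 1 by convention; a
#' constant nonzero difference returns `p = NA` with a warning.
#'
#' @param abs_a,abs_b paired vectors of absolute errors, diopters.
#' @return list with `t`, `df`, `p.value`, `mean_diff` (a - b), `degenerate`.
#' @export
paired_abs_error_ttest <- function(abs_a, abs_b) {
  if (length(abs_a) != length(abs_b)) {
    stop_iol("paired vectors differ in length", class = "iol_domain_error")
  }
  if (length(abs_a) < 3) {
    stop_iol("need at least 3 pairs", class = "iol_domain_error")
  }
  d <- abs_a - abs_b
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    if (all(d == 0)) {
      return(list(t = 0, df = length(d) - 1, p.value = 1,
                  mean_diff = 0, degenerate = TRUE))
    }
    warning("zero variance of paired differences; p-value undefined")
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p.value = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(abs_a, abs_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Demographic and biometric comparison of two cohorts
#'
#' For each variable: group means by sex and overall in both cohorts, the
#' within-cohort sex difference (two-sided Student t-test, equal variances),
#' and the between-cohort difference on all eyes (two-sided Student t-test).
#' Laterality, a count variable, is compared as the proportion of right eyes
#' with two-proportion z-tests (a t-test is ill-posed for a 2x2 count).
#'
#' @param a,b `iol_cohort`s.
#' @param variables numeric variables to compare; derived Km and astigmatism
#'   are always included when keratometry is present.  Variables absent (all
#'   missing) in either cohort are omitted and listed in the `omitted`
#'   attribute.
#' @return tibble with one row per variable: means by sex/overall per cohort,
#'   `p_sex_a`, `p_sex_b`, `p_between`.
#' @export
cohort_comparison <- function(a, b,
                              variables = c("age_years", "iol_power_D",
                                            "postop_ref_D", "ACD_mm", "AL_mm",
                                            "CCT_um", "K1_D", "K2_D", "LT_mm",
                                            "WTW_mm")) {
  aug <- function(ch) {
    df <- tibble::as_tibble(ch)
    if (all(c("K1_D", "K2_D") %in% names(df))) {
      feats <- derive_features(df)
      df$Km_D <- feats$Km_D
      df$astigmatism_D <- feats$astigmatism_D
    }
    df
  }
  da <- aug(a); db <- aug(b)
  vars <- c(variables, intersect(c("Km_D", "astigmatism_D"), names(da)))
  student_p <- function(x, y) {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    if (stats::sd(c(x, y)) == 0) return(1)
    stats::t.test(x, y, var.equal = TRUE)$p.value
  }
  omitted <- character(0)
  rows <- list()
  for (v in vars) {
    if (!v %in% names(da) || !v %in% names(db) ||
        all(!is.finite(da[[v]])) || all(!is.finite(db[[v]]))) {
      omitted <- c(omitted, v)
      next
    }
    xa <- da[[v]]; xb <- db[[v]]
    rows[[v]] <- tibble::tibble(
      variable = v,
      mean_a_F = mean(xa[da$sex %in% "F"], na.rm = TRUE),
      mean_a_M = mean(xa[da$sex %in% "M"], na.rm = TRUE),
      mean_a = mean(xa, na.rm = TRUE),
      p_sex_a = student_p(xa[da$sex %in% "F"], xa[da$sex %in% "M"]),
      mean_b_F = mean(xb[db$sex %in% "F"], na.rm = TRUE),
      mean_b_M = mean(xb[db$sex %in% "M"], na.rm = TRUE),
      mean_b = mean(xb, na.rm = TRUE),
      p_sex_b = student_p(xb[db$sex %in% "F"], xb[db$sex %in% "M"]),
      p_between = student_p(xa[is.finite(xa)], xb[is.finite(xb)])
    )
  }
  out <- do.call(rbind, rows)
  # laterality as proportions of right eyes
  if (any(!is.na(da$eye)) && any(!is.na(db$eye))) {
    pr <- function(e) c(r = sum(e %in% "right"), n = sum(e %in% c("right", "left")))
    two_prop_p <- function(c1, c2) {
      if (c1[["n"]] == 0 || c2[["n"]] == 0) return(NA_real_)
      p1 <- c1[["r"]] / c1[["n"]]; p2 <- c2[["r"]] / c2[["n"]]
      p <- (c1[["r"]] + c2[["r"]]) / (c1[["n"]] + c2[["n"]])
      se <- sqrt(p * (1 - p) * (1 / c1[["n"]] + 1 / c2[["n"]]))
      if (se == 0) return(1)
      2 * stats::pnorm(-abs((p1 - p2) / se))
    }
    aF <- pr(da$eye[da$sex %in% "F"]); aM <- pr(da$eye[da$sex %in% "M"])
    bF <- pr(db$eye[db$sex %in% "F"]); bM <- pr(db$eye[db$sex %in% "M"])
    aAll <- pr(da$eye); bAll <- pr(db$eye)
    lat <- tibble::tibble(
      variable = "prop_right_eye",
      mean_a_F = aF[["r"]] / max(aF[["n"]], 1),
      mean_a_M = aM[["r"]] / max(aM[["n"]], 1),
      mean_a = aAll[["r"]] / max(aAll[["n"]], 1),
      p_sex_a = two_prop_p(aF, aM),
      mean_b_F = bF[["r"]] / max(bF[["n"]], 1),
      mean_b_M = bM[["r"]] / max(bM[["n"]], 1),
      mean_b = bAll[["r"]] / max(bAll[["n"]], 1),
      p_sex_b = two_prop_p(bF, bM),
      p_between = two_prop_p(aAll, bAll)
    )
    out <- rbind(out, lat)
  }
  attr(out, "omitted") <- omitted
  attr(out, "labels") <- c(a = cohort_label(a), b = cohort_label(b))
  out
}
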