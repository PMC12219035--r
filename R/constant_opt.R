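#' Deterministic train/test split of a cohort
#'
#' Splits a cohort into a training and a held-out test partition by a uniform
#' permutation drawn under a private RNG stream seeded with `seed`; the same
#' `(cohort order, seed)` always yields the same membership, and the global
#' RNG state is left untouched.  Sizes are `round(n * train_fraction)` and
#' the remainder.
#'
#' @param cohort an `iol_cohort` with at least 10 records.
#' @param train_fraction proportion in the training set, in (0, 1);
#'   default 0.70.
#' @param seed integer seed (recorded on both partitions).
#' @return list with `train` and `test` cohorts (each keeps original row
#'   order and carries `split_seed` / `train_fraction` attributes).
#' @export
split_cohort <- function(cohort, train_fraction = 0.70, seed) {
  if (nrow(cohort) < 10) {
    stop_iol("cohort must have at least 10 records to split",
             class = "iol_domain_error")
  }
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop_iol("train_fraction must lie in (0, 1)", class = "iol_config_error")
  }
  n <- nrow(cohort)
  n_train <- round(n * train_fraction)
  perm <- with_private_seed(seed, sample.int(n))
  idx_train <- sort(perm[seq_len(n_train)])
  idx_test <- sort(perm[-seq_len(n_train)])
  subset_keep <- function(idx, tag) {
    out <- cohort[idx, , drop = FALSE]
    attr(out, "label") <- paste0(cohort_label(cohort), "_", tag)
    attr(out, "split_seed") <- seed
    attr(out, "train_fraction") <- train_fraction
    class(out) <- unique(c("iol_cohort", class(out)))
    out
  }
  list(train = subset_keep(idx_train, "train"),
       test = subset_keep(idx_test, "test"))
}

#' Per-eye refraction prediction errors
#'
#' Error sign convention: predicted minus measured postoperative refraction
#' (a positive error means the formula predicted a more hyperopic outcome
#' than observed).
#'
#' @inheritParams predict_refraction
#' @return numeric vector of errors in diopters, named by `patient_id`.
#' @export
prediction_errors <- function(formula, cohort, constants = NULL,
                              vertex_mm = 12, keratometric_index = 1.3375) {
  pred <- predict_refraction(formula, cohort, constants, vertex_mm,
                             keratometric_index)
  stats::setNames(pred$predicted_ref_D - cohort$postop_ref_D,
                  cohort$patient_id)
}

#' Mean prediction error of a formula on a cohort
#'
#' @inheritParams prediction_errors
#' @return mean of (predicted - measured) over eyes, diopters.
#' @export
mean_error <- function(formula, cohort, constants = NULL, vertex_mm = 12,
                       keratometric_index = 1.3375) {
  mean(prediction_errors(formula, cohort, constants, vertex_mm,
                         keratometric_index))
}

scalar_constant_field <- function(formula) {
  switch(formula, SRKT = "A_const", HofferQ = "pACD_mm",
         Holladay1 = "SF_mm", Haigis = "haigis_a0", External = "offset_D",
         stop_iol("unknown formula: ", formula, class = "iol_config_error"))
}

default_bracket <- function(formula) {
  switch(formula, SRKT = c(110, 125), HofferQ = c(2, 9),
         Holladay1 = c(-2, 5), Haigis = c(-3, 3))
}

#' Optimize a formula's lens constant to zero the training mean error
#'
#' Empirical lens-constant optimization: the formula's scalar constant
#' (A-constant for SRK/T, pACD for Hoffer Q, surgeon factor for Holladay 1,
#' a0 for Haigis) is adjusted until the mean prediction error on the training
#' cohort is zero.  The mean error is strictly monotone in the constant, so
#' the zero is found by bracketed root finding ([stats::uniroot]); endpoints
#' are checked for a sign change and a coarse grid for monotonicity before
#' solving.
#'
#' @inheritParams prediction_errors
#' @param train training cohort (the held-out split must not be passed here).
#' @param bracket `c(lo, hi)` search interval for the constant; defaults:
#'   A in [110, 125], pACD in [2, 9] mm, SF in [-2, 5] mm, a0 in [-3, 3] mm.
#' @param tol tolerance on the training mean error, diopters (default 1e-6).
#' @return a [lens_constants()] object with the optimized scalar (other
#'   fields unchanged) and attributes `train_ME_D`, `n_train`, `train_ids`.
#' @export
optimize_constant <- function(formula, train, constants = NULL,
                              bracket = NULL, tol = 1e-6, vertex_mm = 12,
                              keratometric_index = 1.3375) {
  formula <- match.arg(formula, setdiff(iol_formula_ids(), "External"))
  constants <- constants %||% default_constants(formula)
  bracket <- bracket %||% default_bracket(formula)
  field <- scalar_constant_field(formula)
  me_at <- function(c0) {
    cst <- constants
    cst[[field]] <- c0
    mean_error(formula, train, cst, vertex_mm, keratometric_index)
  }
  me_safe <- function(c0) {
    tryCatch(me_at(c0), iol_numeric_error = function(e) NA_real_)
  }
  # the nominal bracket can push the ELP of extreme eyes outside (0, AL);
  # shrink an invalid endpoint towards the centre until the chain is valid
  shrink_endpoint <- function(from, towards) {
    val <- me_safe(from)
    tries <- 0L
    while (is.na(val) && tries < 40L) {
      from <- from + 0.05 * (towards - from)
      val <- me_safe(from)
      tries <- tries + 1L
    }
    if (is.na(val)) {
      stop_iol("no valid ", field, " endpoint found near the bracket for ",
               formula, class = "iol_bracket_error")
    }
    list(x = from, f = val)
  }
  mid <- mean(bracket)
  lo <- shrink_endpoint(bracket[1], mid)
  hi <- shrink_endpoint(bracket[2], mid)
  bracket <- c(lo$x, hi$x)
  f_lo <- lo$f
  f_hi <- hi$f
  if (sign(f_lo) == sign(f_hi)) {
    stop_iol("mean error does not change sign over bracket [",
             bracket[1], ", ", bracket[2], "] (ME = ", signif(f_lo, 4), " / ",
             signif(f_hi, 4), "); widen the bracket",
             class = "iol_bracket_error")
  }
  grid <- seq(bracket[1], bracket[2], length.out = 7)
  me_grid <- vapply(grid, me_safe, numeric(1))
  d <- diff(me_grid[!is.na(me_grid)])
  if (!(all(d > 0) || all(d < 0))) {
    stop_iol("mean error is not monotone in the ", field,
             " over the bracket; cannot guarantee a unique root",
             class = "iol_monotonicity_error")
  }
  root <- stats::uniroot(me_at, interval = bracket, tol = 1e-10,
                         maxiter = 2000)
  out <- constants
  out[[field]] <- root$root
  achieved <- me_at(root$root)
  if (abs(achieved) >= tol) {
    stop_iol("optimization left |training ME| = ", signif(abs(achieved), 4),
             " >= tol", class = "iol_numeric_error")
  }
  attr(out, "train_ME_D") <- achieved
  attr(out, "n_train") <- nrow(train)
  attr(out, "train_ids") <- train$patient_id
  out
}

#' Offset calibration for externally computed predictions
#'
#' Simulates a lens constant for a closed-source formula: the mean training
#' error (predicted - measured) is subtracted from every prediction, which
#' zeroes the training mean error exactly; the same offset is then applied
#' unchanged to held-out predictions.
#'
#' @param train_predictions predicted refractions on the training eyes, D.
#' @param train_measured measured refractions on the same eyes, D.
#' @return the offset in diopters (`offset_D`); subtract it from predictions.
#' @export
offset_calibrate <- function(train_predictions, train_measured) {
  if (length(train_predictions) != length(train_measured)) {
    stop_iol("prediction and measurement vectors differ in length",
             class = "iol_domain_error")
  }
  if (!length(train_predictions)) {
    stop_iol("empty training vectors", class = "iol_domain_error")
  }
  mean(train_predictions - train_measured)
}
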