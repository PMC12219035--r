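#' Population profile for synthetic cohort generation
#'
#' A stated generative world for one cataract-surgery population: marginal
#' means and SDs for age and the biometry variables, a correlation matrix
#' over them, the sex ratio, a refraction-target policy (what the surgeons
#' aimed for), a ground-truth formula with its constants, measurement noise,
#' and the implantable IOL power grid.
#'
#' @param label profile label.
#' @param means,sds named numeric vectors over
#'   `c("age_years","AL_mm","ACD_mm","LT_mm","CCT_um","WTW_mm","K1_D","K2_D")`.
#' @param corr correlation matrix over the same variables (symmetric,
#'   positive definite, unit diagonal).
#' @param sex_ratio_female proportion of female patients.
#' @param right_eye_ratio proportion of right eyes.
#' @param target_mean_D,target_sd_D refraction-target policy (spherical
#'   equivalent, diopters).
#' @param truth_formula,truth_constants ground-truth formula generating the
#'   measured refractions.
#' @param noise_sd_D SD of the Gaussian measurement/biological noise added to
#'   the truth-formula refraction, diopters.
#' @param iol_power_grid implantable powers, diopters.
#' @return a `population_profile` list.
#' @export
population_profile <- function(label, means, sds, corr,
                               sex_ratio_female = 0.5,
                               right_eye_ratio = 0.5,
                               target_mean_D = 0, target_sd_D = 0.33,
                               truth_formula = "SRKT",
                               truth_constants = NULL,
                               noise_sd_D = 0.3,
                               iol_power_grid = seq(6, 30, by = 0.5)) {
  vars <- c("age_years", "AL_mm", "ACD_mm", "LT_mm", "CCT_um", "WTW_mm",
            "K1_D", "K2_D")
  if (!all(vars %in% names(means)) || !all(vars %in% names(sds))) {
    stop_iol("means and sds must be named over: ", paste(vars, collapse = ", "),
             class = "iol_config_error")
  }
  if (any(sds[vars] <= 0)) {
    stop_iol("all SDs must be positive", class = "iol_config_error")
  }
  corr <- as.matrix(corr)
  if (!isTRUE(all.equal(corr, t(corr))) || any(diag(corr) != 1)) {
    stop_iol("correlation matrix must be symmetric with unit diagonal",
             class = "iol_config_error")
  }
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop_iol("correlation matrix must be positive definite",
             class = "iol_config_error")
  }
  if (noise_sd_D < 0 || target_sd_D <= 0) {
    stop_iol("noise_sd_D must be >= 0 and target_sd_D > 0",
             class = "iol_config_error")
  }
  truth_formula <- match.arg(truth_formula,
                             setdiff(iol_formula_ids(), "External"))
  structure(list(label = label, vars = vars,
                 means = means[vars], sds = sds[vars],
                 corr = corr,
                 sex_ratio_female = sex_ratio_female,
                 right_eye_ratio = right_eye_ratio,
                 target_mean_D = target_mean_D, target_sd_D = target_sd_D,
                 truth_formula = truth_formula,
                 truth_constants = truth_constants %||%
                   default_constants(truth_formula),
                 noise_sd_D = noise_sd_D,
                 iol_power_grid = sort(iol_power_grid)),
            class = "population_profile")
}

default_biometry_corr <- function() {
  vars <- c("age_years", "AL_mm", "ACD_mm", "LT_mm", "CCT_um", "WTW_mm",
            "K1_D", "K2_D")
  corr <- diag(8)
  dimnames(corr) <- list(vars, vars)
  set_c <- function(a, b, v) {
    corr[a, b] <<- v
    corr[b, a] <<- v
  }
  set_c("AL_mm", "ACD_mm", 0.45)
  set_c("AL_mm", "K1_D", -0.35)
  set_c("AL_mm", "K2_D", -0.35)
  set_c("AL_mm", "LT_mm", -0.20)
  set_c("K1_D", "K2_D", 0.90)
  corr
}

#' Built-in population profiles
#'
#' Two shipped profiles emulating the published summary statistics of a
#' South Indian (`"aravind_like"`) and a Midwestern US (`"umich_like"`)
#' SN60WF cataract-surgery cohort.  Marginal means: aravind_like age 60.52 y,
#' AL 23.19 mm, ACD 3.28 mm, LT 4.24 mm, CCT 526.13 um, WTW 11.89 mm,
#' K1 44.20 D, K2 44.86 D; umich_like age 70.73, AL 24.15, ACD 3.25, LT 4.53,
#' CCT 552.58, WTW 12.09, K1 43.44, K2 44.32.  AL SDs are 0.94 / 1.35 mm and
#' the refraction-target policies 0.10 (SD 0.33) / -0.59 (SD 0.93) D; the
#' aravind_like policy encodes the near-emmetropia practice pattern, the
#' umich_like policy the wider myopic-target spread.  SDs not published (age
#' 9.5 y; ACD 0.35, LT 0.40 mm, CCT 33 um, WTW 0.45 mm, K 1.5 D) and the
#' correlation structure (AL-ACD +0.45, AL-K -0.35, AL-LT -0.2, K1-K2 +0.9)
#' are documented simulator defaults, not estimates from the study data.
#'
#' @param population_id `"aravind_like"` or `"umich_like"`.
#' @return a [population_profile()].
#' @export
builtin_profile <- function(population_id = c("aravind_like", "umich_like")) {
  population_id <- match.arg(population_id)
  vars <- c("age_years", "AL_mm", "ACD_mm", "LT_mm", "CCT_um", "WTW_mm",
            "K1_D", "K2_D")
  sds <- stats::setNames(c(9.5, NA, 0.35, 0.40, 33, 0.45, 1.5, 1.5), vars)
  if (population_id == "aravind_like") {
    means <- stats::setNames(c(60.52, 23.19, 3.28, 4.24, 526.13, 11.89,
                               44.20, 44.86), vars)
    sds[["AL_mm"]] <- 0.94
    population_profile("aravind_like", means, sds, default_biometry_corr(),
                       sex_ratio_female = 417 / 985,
                       right_eye_ratio = 556 / 985,
                       target_mean_D = 0.10, target_sd_D = 0.33)
  } else {
    means <- stats::setNames(c(70.73, 24.15, 3.25, 4.53, 552.58, 12.09,
                               43.44, 44.32), vars)
    sds[["AL_mm"]] <- 1.35
    population_profile("umich_like", means, sds, default_biometry_corr(),
                       sex_ratio_female = 570 / 1003,
                       right_eye_ratio = 512 / 1003,
                       target_mean_D = -0.59, target_sd_D = 0.93)
  }
}

#' Generate a synthetic cohort from a population profile
#'
#' Draws correlated biometry from a joint normal truncated to the
#' plausibility bounds (rejection sampling), draws a per-eye refraction
#' target from the profile's policy, implants the grid IOL power whose
#' truth-formula predicted refraction is closest to the target (ties to the
#' lower power), and sets the measured 1-month refraction to the
#' truth-formula prediction plus Gaussian noise.  Sex, laterality and ids are
#' filled deterministically from the seed; the same `(profile, n, seed)`
#' yields an identical cohort and the global RNG state is untouched.
#'
#' @param profile a [population_profile()].
#' @param n number of eyes (one eye per synthetic patient).
#' @param seed integer seed.
#' @param bounds plausibility bounds for truncation; defaults to the
#'   eligibility bounds of [eligibility_config()].
#' @param vertex_mm,keratometric_index optics settings for the truth formula.
#' @param max_rounds rejection-sampling retry cap.
#' @return an `iol_cohort` with attributes `profile` and `seed`.
#' @export
generate_cohort <- function(profile, n, seed,
                            bounds = eligibility_config()$bounds,
                            vertex_mm = 12, keratometric_index = 1.3375,
                            max_rounds = 50L) {
  stopifnot(inherits(profile, "population_profile"), n >= 1)
  vars <- profile$vars
  Sigma <- diag(profile$sds) %*% profile$corr %*% diag(profile$sds)
  within_bounds <- function(m) {
    ok <- rep(TRUE, nrow(m))
    chk <- list(AL_mm = "AL_mm", ACD_mm = "ACD_mm", LT_mm = "LT_mm",
                CCT_um = "CCT_um", WTW_mm = "WTW_mm",
                K1_D = "K1_D", K2_D = "K2_D")
    for (v in names(chk)) {
      if (!v %in% names(bounds)) next
      b <- bounds[[v]]
      ok <- ok & m[, v] >= b[1] & m[, v] <= b[2]
    }
    ok & m[, "age_years"] >= 18 & m[, "age_years"] <= 105
  }
  with_private_seed(seed, {
    draws <- matrix(numeric(0), 0, length(vars))
    rounds <- 0L
    while (nrow(draws) < n) {
      rounds <- rounds + 1L
      if (rounds > max_rounds) {
        stop_iol("truncation rejection cap exceeded; widen the bounds",
                 class = "iol_domain_error")
      }
      m <- MASS::mvrnorm(2 * n, mu = profile$means, Sigma = Sigma)
      colnames(m) <- vars
      draws <- rbind(draws, m[within_bounds(m), , drop = FALSE])
    }
    draws <- draws[seq_len(n), , drop = FALSE]

    ch <- tibble::as_tibble(as.data.frame(draws))
    # canonical keratometry: K1 flat, K2 steep
    swap <- ch$K1_D > ch$K2_D
    if (any(swap)) {
      tmp <- ch$K1_D[swap]
      ch$K1_D[swap] <- ch$K2_D[swap]
      ch$K2_D[swap] <- tmp
    }
    ch$patient_id <- sprintf("%s-%05d", profile$label, seq_len(n))
    ch$sex <- ifelse(stats::runif(n) < profile$sex_ratio_female, "F", "M")
    ch$eye <- ifelse(stats::runif(n) < profile$right_eye_ratio,
                     "right", "left")
    ch$lens_model <- "SN60WF"
    ch$bscva_at_least_20_40 <- TRUE

    target <- stats::rnorm(n, profile$target_mean_D, profile$target_sd_D)
    grid <- profile$iol_power_grid
    ch$iol_power_D <- NA_real_  # filled after power selection below
    pred <- matrix(NA_real_, n, length(grid))
    base <- as_cohort(ch, label = profile$label)
    for (j in seq_along(grid)) {
      pred[, j] <- predict_refraction(profile$truth_formula, base,
                                      profile$truth_constants,
                                      vertex_mm, keratometric_index,
                                      iol_power_D = grid[j])$predicted_ref_D
    }
    pick <- apply(abs(pred - target), 1L, which.min)  # first = lower power
    ch$iol_power_D <- grid[pick]
    truth_ref <- pred[cbind(seq_len(n), pick)]
    ch$postop_ref_D <- truth_ref + stats::rnorm(n, 0, profile$noise_sd_D)

    out <- as_cohort(ch, label = profile$label)
    attr(out, "profile") <- profile
    attr(out, "seed") <- seed
    out
  })
}

#' Write the generating-profile sidecar for a synthetic cohort
#'
#' Emits a JSON provenance record (profile parameters and seed) next to a
#' cohort CSV written by [write_cohort()].
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(cohort, path) {
  pr <- attr(cohort, "profile")
  if (is.null(pr)) stop_iol("cohort has no generating profile",
                            class = "iol_domain_error")
  rec <- list(label = pr$label, means = as.list(pr$means),
              sds = as.list(pr$sds), corr = pr$corr,
              sex_ratio_female = pr$sex_ratio_female,
              right_eye_ratio = pr$right_eye_ratio,
              target_mean_D = pr$target_mean_D, target_sd_D = pr$target_sd_D,
              truth_formula = pr$truth_formula,
              truth_constants = unclass(pr$truth_constants),
              noise_sd_D = pr$noise_sd_D,
              iol_power_grid = pr$iol_power_grid,
              seed = attr(cohort, "seed"), n = nrow(cohort))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
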