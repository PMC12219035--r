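#' Lens-constant sets for the supported formulas
#'
#' Each vergence formula personalizes its effective-lens-position (ELP) model
#' through a single empirical constant: the A-constant (SRK/T), the
#' personalized ACD (Hoffer Q), the surgeon factor (Holladay 1), or the
#' Haigis intercept a0 (used here with fixed slopes a1, a2 on preoperative
#' ACD and axial length).  Externally computed formulas (closed-source online
#' calculators or learned models) are represented by a scalar dioptric offset
#' subtracted from their predictions.
#'
#' @param formula one of `"SRKT"`, `"HofferQ"`, `"Holladay1"`, `"Haigis"`,
#'   `"External"`.
#' @param A_const SRK/T A-constant (dimensionless, typically 110-125).
#' @param pACD_mm Hoffer Q personalized ACD in mm.
#' @param SF_mm Holladay 1 surgeon factor in mm.
#' @param haigis_a0,haigis_a1,haigis_a2 Haigis ELP coefficients:
#'   ELP = a0 + a1 * ACD + a2 * AL (a0 in mm, a1 and a2 dimensionless).
#' @param offset_D dioptric offset for externally computed predictions.
#' @return an object of class `lens_constants`.
#' @seealso [default_constants()] for the shipped SN60WF defaults,
#'   [convert_a_constant()] to seed the other constants from one A-constant.
#' @export
lens_constants <- function(formula,
                           A_const = NULL, pACD_mm = NULL, SF_mm = NULL,
                           haigis_a0 = NULL, haigis_a1 = NULL, haigis_a2 = NULL,
                           offset_D = NULL) {
  formula <- match.arg(formula, iol_formula_ids())
  fields <- switch(formula,
    SRKT      = list(A_const = A_const),
    HofferQ   = list(pACD_mm = pACD_mm),
    Holladay1 = list(SF_mm = SF_mm),
    Haigis    = list(haigis_a0 = haigis_a0, haigis_a1 = haigis_a1,
                     haigis_a2 = haigis_a2),
    External  = list(offset_D = offset_D %||% 0)
  )
  missing_f <- names(fields)[vapply(fields, is.null, logical(1))]
  if (length(missing_f)) {
    stop_iol("lens_constants for ", formula, " requires: ",
             paste(missing_f, collapse = ", "), class = "iol_config_error")
  }
  bad <- names(fields)[!vapply(fields, function(x) is.numeric(x) && is.finite(x),
                               logical(1))]
  if (length(bad)) {
    stop_iol("non-finite constant field(s): ", paste(bad, collapse = ", "),
             class = "iol_config_error")
  }
  structure(c(list(formula = formula), fields), class = "lens_constants")
}

#' @export
print.lens_constants <- function(x, ...) {
  vals <- unlist(x[setdiff(names(x), "formula")])
  cat("<lens_constants> ", x$formula, ": ",
      paste(names(vals), signif(vals, 6), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Formula identifiers supported natively
#' @return character vector of formula ids; `"External"` marks predictions
#'   supplied from outside (offset-calibrated only).
#' @export
iol_formula_ids <- function() c("SRKT", "HofferQ", "Holladay1", "Haigis", "External")

#' Shipped default lens constants for the Acrysof SN60WF
#'
#' Defaults are population-optimized SN60WF constants: SRK/T A = 119.082,
#' Hoffer Q pACD = 5.727, Holladay 1 SF = 1.860, Haigis a0 = -0.739.  The
#' Haigis slopes default to a1 = 0.4, a2 = 0.1 with only a0 subject to
#' optimization; a shipped a0 paired with other slopes is only a starting
#' point that constant optimization moves.
#'
#' @param formula formula id, see [iol_formula_ids()].
#' @return a [lens_constants()] object.
#' @export
default_constants <- function(formula) {
  formula <- match.arg(formula, iol_formula_ids())
  switch(formula,
    SRKT      = lens_constants("SRKT", A_const = 119.082),
    HofferQ   = lens_constants("HofferQ", pACD_mm = 5.727),
    Holladay1 = lens_constants("Holladay1", SF_mm = 1.860),
    Haigis    = lens_constants("Haigis", haigis_a0 = -0.739,
                               haigis_a1 = 0.4, haigis_a2 = 0.1),
    External  = lens_constants("External", offset_D = 0)
  )
}

#' Convert an SRK/T-style A-constant to another formula's constant
#'
#' Standard published linear transfers between lens-constant scales, so one
#' configured A-constant can seed every formula before optimization:
#' pACD = 0.58357 A - 63.896, SF = 0.5663 A - 65.60, and (for the Haigis
#' intercept with slopes a1 = 0.4, a2 = 0.1) a0 = 0.62467 A - 72.434.  These
#' transfers are nominal; empirically optimized constants need not agree with
#' them exactly.
#'
#' @param A A-constant, must lie in `[110, 125]`.
#' @param target `"pACD"`, `"SF"`, or `"haigis_a0"`.
#' @param coef optional `c(slope, intercept)` override for the conversion.
#' @return constant on the target scale, mm.
#' @export
convert_a_constant <- function(A, target = c("pACD", "SF", "haigis_a0"),
                               coef = NULL) {
  target <- match.arg(target)
  if (!is.numeric(A) || any(!is.finite(A)) || any(A < 110) || any(A > 125)) {
    stop_iol("A-constant must be finite and within [110, 125]",
             class = "iol_domain_error")
  }
  coef <- coef %||% switch(target,
    pACD      = c(0.58357, -63.896),
    SF        = c(0.5663, -65.60),
    haigis_a0 = c(0.62467, -72.434)
  )
  coef[1] * A + coef[2]
}

# ---- effective lens position models ----------------------------------------

# SRK/T: Fyodorov corneal height with the published corrected-axial-length
# polynomial for long eyes and the corneal-width clamp, plus the
# A-constant-to-ACD-constant conversion.
elp_srkt <- function(AL, Km, A, keratometric_index = 1.3375) {
  r <- 1000 * (keratometric_index - 1) / Km
  LCOR <- ifelse(AL > 24.2, -3.446 + 1.715 * AL - 0.0237 * AL^2, AL)
  Cw <- -5.41 + 0.58412 * LCOR + 0.098 * Km
  disc <- pmax(r^2 - Cw^2 / 4, 0)  # published clamp: corneal width capped at 2r
  H <- r - sqrt(disc)
  ACDconst <- 0.62467 * A - 68.747
  H + ACDconst - 3.336
}

# Hoffer Q: personalized-ACD model with degree-based tangent terms and the
# published short/long-eye branches; axial length is clamped to [18.5, 31] mm
# inside the ELP model only.
elp_hofferq <- function(AL, Km, pACD) {
  CAL <- clamp(AL, 18.5, 31)
  M <- ifelse(CAL <= 23, 1, -1)
  G <- ifelse(CAL <= 23, 28, 23.5)
  pACD + 0.3 * (CAL - 23.5) + tan_deg(Km)^2 +
    0.1 * M * (23.5 - CAL)^2 * tan_deg(0.1 * (G - CAL)^2) - 0.99166
}

# Holladay 1: anatomical ACD from corneal height on a scaled corneal diameter
# (capped at 13.5 mm), plus the surgeon factor.
elp_holladay1 <- function(AL, Km, SF, keratometric_index = 1.3375) {
  r <- 1000 * (keratometric_index - 1) / Km
  AG <- pmin(12.5 * AL / 23.45, 13.5)
  aACD <- 0.56 + r - sqrt(pmax(r^2 - AG^2 / 4, 0))
  aACD + SF
}

# Haigis: linear model on preoperative anatomical ACD and axial length.
elp_haigis <- function(AL, ACD, a0, a1, a2) a0 + a1 * ACD + a2 * AL

# ---- vergence chains --------------------------------------------------------

# Holladay/SRK-T refraction-for-power vergence formula (all lengths mm):
# predicted spectacle refraction for implanted power P, optical axial length
# L, ELP C, corneal radius r, vertex V, aqueous index na and the formula's
# (corneal index - 1) term ncm1.  With V = 0 this is the corneal-plane value.
vergence_refraction <- function(P, r, L, C, V, na, ncm1) {
  num <- 1000 * na * (na * r - ncm1 * L) - P * (L - C) * (na * r - ncm1 * C)
  den <- na * (V * (na * r - ncm1 * L) + L * r) -
    0.001 * P * (L - C) * (V * (na * r - ncm1 * C) + C * r)
  num / den
}

# refraction transfer corneal plane -> spectacle plane over vertex (mm)
corneal_to_spectacle <- function(Rc, vertex_mm) Rc / (1 + Rc * vertex_mm / 1000)

#' Predict postoperative refraction for an implanted IOL power
#'
#' Runs one formula's published equation chain for every eye of a cohort:
#' the formula-specific ELP model followed by a thin-lens vergence chain from
#' the cornea through the ELP to the retina, with the result expressed as a
#' spectacle-plane spherical equivalent over the given vertex distance.
#'
#' Formula inputs: SRK/T uses AL, Km and the A-constant (with its published
#' corrected-axial-length and corneal-height clamp rules and a retinal
#' thickness term); Hoffer Q uses AL, Km and pACD (tangent terms, short/long
#' eye branches); Holladay 1 uses AL, Km and the surgeon factor (corneal
#' height ELP, +0.2 mm retinal thickness); Haigis uses AL and preoperative
#' ACD with ELP = a0 + a1*ACD + a2*AL and its own corneal index (1.3315).
#'
#' @param formula formula id (`"SRKT"`, `"HofferQ"`, `"Holladay1"`, `"Haigis"`).
#' @param cohort an `iol_cohort` (or any data frame with the biometry columns
#'   `AL_mm`, `K1_D`, `K2_D`, `ACD_mm`, `iol_power_D`, `patient_id`).
#' @param constants a [lens_constants()] object matching `formula`; defaults
#'   to [default_constants()].
#' @param vertex_mm spectacle vertex distance in mm, in `[0, 20]`; 0 returns
#'   corneal-plane refraction.
#' @param keratometric_index index used to convert keratometric diopters to
#'   corneal radius (Lenstar convention 1.3375).
#' @param iol_power_D optional vector overriding the cohort's implanted
#'   powers (recycled to the number of eyes).
#' @return a [tibble::tibble] with columns `patient_id`, `formula`,
#'   `predicted_ref_D`, `elp_mm`.
#' @export
predict_refraction <- function(formula, cohort, constants = NULL,
                               vertex_mm = 12, keratometric_index = 1.3375,
                               iol_power_D = NULL) {
  formula <- match.arg(formula, setdiff(iol_formula_ids(), "External"))
  constants <- constants %||% default_constants(formula)
  if (!inherits(constants, "lens_constants") || constants$formula != formula) {
    stop_iol("constants do not match formula '", formula, "'",
             class = "iol_config_error")
  }
  if (!is.numeric(vertex_mm) || vertex_mm < 0 || vertex_mm > 20) {
    stop_iol("vertex_mm must lie in [0, 20]", class = "iol_domain_error")
  }
  AL <- cohort$AL_mm
  Km <- (cohort$K1_D + cohort$K2_D) / 2
  ACD <- cohort$ACD_mm
  P <- iol_power_D %||% cohort$iol_power_D
  if (length(P) == 1L) P <- rep(P, length(AL))

  elp <- switch(formula,
    SRKT      = elp_srkt(AL, Km, constants$A_const, keratometric_index),
    HofferQ   = elp_hofferq(AL, Km, constants$pACD_mm),
    Holladay1 = elp_holladay1(AL, Km, constants$SF_mm, keratometric_index),
    Haigis    = elp_haigis(AL, ACD, constants$haigis_a0, constants$haigis_a1,
                           constants$haigis_a2)
  )
  bad <- which(!(elp > 0 & elp < AL))
  if (length(bad)) {
    stop_iol("ELP outside (0, AL) for record(s): ",
             paste(cohort$patient_id[bad], collapse = ", "),
             class = "iol_numeric_error")
  }

  ref <- switch(formula,
    SRKT = {
      r <- 1000 * (keratometric_index - 1) / Km
      LOPT <- AL + (0.65696 - 0.02029 * AL)  # retinal thickness term
      vergence_refraction(P, r, LOPT, elp, vertex_mm, na = 1.336, ncm1 = 0.333)
    },
    Holladay1 = {
      r <- 1000 * (keratometric_index - 1) / Km
      vergence_refraction(P, r, AL + 0.2, elp, vertex_mm,
                          na = 1.336, ncm1 = 1 / 3)
    },
    HofferQ = {
      # invert P = 1336/(AL - ELP - 0.05) - 1.336/(1.336/(K + Rc) - (ELP+0.05)/1000)
      Q <- 1336 / (AL - elp - 0.05) - P
      Rc <- 1.336 / (1.336 / Q + (elp + 0.05) / 1000) - Km
      corneal_to_spectacle(Rc, vertex_mm)
    },
    Haigis = {
      RC_m <- (keratometric_index - 1) / Km        # corneal radius, m
      DC <- (1.3315 - 1) / RC_m                    # Haigis corneal power
      n <- 1.336
      L_m <- AL / 1000
      d_m <- elp / 1000
      z <- n / (d_m + n / (n / (L_m - d_m) - P))
      corneal_to_spectacle(z - DC, vertex_mm)
    }
  )
  if (any(!is.finite(ref))) {
    stop_iol("non-finite predicted refraction for record(s): ",
             paste(cohort$patient_id[!is.finite(ref)], collapse = ", "),
             class = "iol_numeric_error")
  }
  tibble::tibble(patient_id = cohort$patient_id, formula = formula,
                 predicted_ref_D = ref, elp_mm = elp)
}

#' Load externally computed per-eye refraction predictions
#'
#' Closed-source formulas (online calculators, trained models) cannot be run
#' in-process; their predictions enter the pipeline as a delimited file with
#' columns `patient_id` and `predicted_ref_D`, one file per formula, and are
#' calibrated only by a mean-error offset.
#'
#' @param path delimited text file (comma or tab separated) with a header.
#' @param formula_label label to attach to the predictions.
#' @param cohort optional cohort; eyes of the cohort missing from the file are
#'   reported in the `missing` attribute so downstream evaluation can restrict
#'   to the intersection of coverage.
#' @return tibble `patient_id`, `formula`, `predicted_ref_D`, with attributes
#'   `rejects` (unparseable rows) and `missing` (uncovered cohort eyes).
#' @export
load_external_predictions <- function(path, formula_label, cohort = NULL) {
  if (!file.exists(path)) {
    stop_iol("file not found: ", path, class = "iol_io_error")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("patient_id", "predicted_ref_D")
  if (!all(need %in% names(raw))) {
    stop_iol("external prediction file must have columns patient_id, ",
             "predicted_ref_D", class = "iol_schema_error")
  }
  val <- suppressWarnings(as.numeric(raw$predicted_ref_D))
  rejects <- raw$patient_id[is.na(val) & !is.na(raw$predicted_ref_D) &
                              nzchar(raw$predicted_ref_D)]
  keep <- is.finite(val)
  out <- tibble::tibble(patient_id = raw$patient_id[keep],
                        formula = formula_label,
                        predicted_ref_D = val[keep])
  if (anyDuplicated(out$patient_id)) {
    stop_iol("duplicate patient_id in external predictions: ",
             paste(unique(out$patient_id[duplicated(out$patient_id)]),
                   collapse = ", "), class = "iol_schema_error")
  }
  missing_ids <- character(0)
  if (!is.null(cohort)) {
    missing_ids <- setdiff(cohort$patient_id, out$patient_id)
  }
  attr(out, "rejects") <- rejects
  attr(out, "missing") <- missing_ids
  out
}
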