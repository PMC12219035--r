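#' Eligibility configuration
#'
#' Per-variable plausibility bounds plus the study's record-level rules:
#' a required lens model, exclusion of eyes with postoperative
#' best-spectacle-corrected visual acuity worse than 20/40, and one eye per
#' patient (to avoid inter-eye correlation).  Default bounds cover the
#' validity ranges of the implemented formulas: AL 18-35 mm, ACD 1.5-5 mm,
#' K 35-52 D, LT 2.5-6.5 mm, CCT 400-700 um, WTW 9-14 mm, IOL power 0-40 D.
#'
#' @param bounds named list of `c(min, max)` per variable; partial overrides
#'   are merged into the defaults.
#' @param require_lens_model lens model required for inclusion (`NULL` to
#'   disable); default `"SN60WF"`.
#' @param drop_bscva_failures drop eyes with `bscva_at_least_20_40 == FALSE`.
#' @param one_eye_per_patient keep a single eye per `patient_id`.
#' @param tie_break which eligible eye to keep for a duplicated patient:
#'   `"first"` keeps the earlier row in file order (deterministic, auditable).
#' @return an `eligibility_config` list.
#' @export
eligibility_config <- function(bounds = list(),
                               require_lens_model = "SN60WF",
                               drop_bscva_failures = TRUE,
                               one_eye_per_patient = TRUE,
                               tie_break = c("first", "last")) {
  defaults <- list(AL_mm = c(18, 35), ACD_mm = c(1.5, 5.0),
                   K1_D = c(35, 52), K2_D = c(35, 52),
                   LT_mm = c(2.5, 6.5), CCT_um = c(400, 700),
                   WTW_mm = c(9, 14), iol_power_D = c(0, 40))
  defaults[names(bounds)] <- bounds
  for (v in names(defaults)) {
    b <- defaults[[v]]
    if (length(b) != 2 || any(!is.finite(b)) || b[1] >= b[2]) {
      stop_iol("bounds for ", v, " must be finite with min < max",
               class = "iol_config_error")
    }
  }
  structure(list(bounds = defaults,
                 require_lens_model = require_lens_model,
                 drop_bscva_failures = isTRUE(drop_bscva_failures),
                 one_eye_per_patient = isTRUE(one_eye_per_patient),
                 tie_break = match.arg(tie_break)),
            class = "eligibility_config")
}

#' Apply inclusion/exclusion criteria to a cohort
#'
#' Removes records with (a) a missing or out-of-bounds field needed by any
#' formula, (b) a failed 20/40 visual-acuity flag, (c) the wrong lens model,
#' and (d) a second eye of a patient already included.  Each removed record
#' is logged once with the first matching reason, checked in that order.
#' Missing sex or laterality never excludes a record (no formula uses them);
#' such records are listed in the `notes` attribute instead.
#'
#' @param cohort an `iol_cohort`.
#' @param config an [eligibility_config()].
#' @return list with elements `cohort` (kept records, original order) and
#'   `log` (tibble `patient_id`, `eye`, `reason`); the kept cohort carries a
#'   `notes` attribute.  Idempotent: reapplying to the kept cohort removes
#'   nothing.
#' @export
apply_eligibility <- function(cohort, config = eligibility_config()) {
  if (nrow(cohort) == 0) stop_iol("empty cohort", class = "iol_domain_error")
  n <- nrow(cohort)
  reason <- rep(NA_character_, n)

  # (a) missing / out-of-bounds formula inputs
  postop_needed <- "postop_ref_D"
  for (v in c(names(config$bounds), postop_needed)) {
    x <- cohort[[v]]
    if (v %in% names(config$bounds)) {
      b <- config$bounds[[v]]
      bad <- is.na(x) | !is.finite(x) | x < b[1] | x > b[2]
      why <- ifelse(is.na(x), paste0("missing ", v),
                    paste0("out-of-bounds ", v))
    } else {
      bad <- is.na(x) | !is.finite(x)
      why <- rep(paste0("missing ", v), n)
    }
    new <- is.na(reason) & bad
    reason[new] <- why[new]
  }
  # (b) visual acuity
  if (config$drop_bscva_failures) {
    bad <- !is.na(cohort$bscva_at_least_20_40) & !cohort$bscva_at_least_20_40
    reason[is.na(reason) & bad] <- "BSCVA worse than 20/40"
  }
  # (c) lens model
  if (!is.null(config$require_lens_model)) {
    bad <- is.na(cohort$lens_model) |
      cohort$lens_model != config$require_lens_model
    reason[is.na(reason) & bad] <- paste0("lens model not ",
                                          config$require_lens_model)
  }
  # (d) second eye of an already-included patient, among survivors of (a)-(c)
  if (config$one_eye_per_patient) {
    alive <- which(is.na(reason))
    ord <- if (config$tie_break == "first") alive else rev(alive)
    dup <- ord[duplicated(cohort$patient_id[ord])]
    reason[dup] <- "second eye excluded"
  }

  kept <- is.na(reason)
  log <- tibble::tibble(patient_id = cohort$patient_id[!kept],
                        eye = cohort$eye[!kept],
                        reason = reason[!kept])
  out <- cohort[kept, , drop = FALSE]
  attr(out, "label") <- cohort_label(cohort)
  class(out) <- unique(c("iol_cohort", class(out)))
  notes <- character(0)
  if (any(is.na(out$sex))) {
    notes <- c(notes, paste0("missing sex: ",
                             sum(is.na(out$sex)), " record(s)"))
  }
  if (any(is.na(out$eye))) {
    notes <- c(notes, paste0("missing laterality: ",
                             sum(is.na(out$eye)), " record(s)"))
  }
  attr(out, "notes") <- notes
  if (nrow(out) == 0) warning("eligibility filtering removed every record")
  list(cohort = out, log = log)
}

#' Write an exclusion log
#' @param log exclusion-log tibble from [apply_eligibility()].
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path) {
  utils::write.table(as.data.frame(log), path, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
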