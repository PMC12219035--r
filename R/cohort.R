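#' Per-eye cohort container
#'
#' A cohort is a tibble of one row per eye with the biometry, surgery and
#' outcome fields used by the formulas, carrying a `label` attribute.
#' Keratometry is canonicalized so that `K2_D >= K1_D` (values swapped when
#' the input violates this).
#'
#' Columns: `patient_id`, `eye` ("right"/"left"), `age_years`, `sex`
#' ("F"/"M"), `AL_mm`, `ACD_mm`, `LT_mm`, `CCT_um`, `WTW_mm`, `K1_D`, `K2_D`,
#' `iol_power_D`, `postop_ref_D` (1-month spherical equivalent), `lens_model`,
#' `bscva_at_least_20_40`.
#'
#' @param records data frame with the columns above (missing non-essential
#'   columns are filled with `NA`).
#' @param label cohort label.
#' @return an `iol_cohort` tibble.
#' @export
as_cohort <- function(records, label = "cohort") {
  req <- c("patient_id", "AL_mm", "ACD_mm", "K1_D", "K2_D", "iol_power_D")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop_iol("cohort is missing required column(s): ",
             paste(miss, collapse = ", "), class = "iol_schema_error")
  }
  out <- tibble::as_tibble(records)
  for (col in setdiff(cohort_fields(), names(out))) {
    out[[col]] <- if (col %in% cohort_character_fields()) NA_character_
                  else if (col == "bscva_at_least_20_40") NA
                  else NA_real_
  }
  out <- out[cohort_fields()]
  out$patient_id <- as.character(out$patient_id)
  for (col in cohort_numeric_fields()) out[[col]] <- as.numeric(out[[col]])
  swap <- !is.na(out$K1_D) & !is.na(out$K2_D) & out$K1_D > out$K2_D
  if (any(swap)) {
    tmp <- out$K1_D[swap]
    out$K1_D[swap] <- out$K2_D[swap]
    out$K2_D[swap] <- tmp
  }
  attr(out, "label") <- label
  class(out) <- c("iol_cohort", class(out))
  out
}

cohort_fields <- function() {
  c("patient_id", "eye", "age_years", "sex", "AL_mm", "ACD_mm", "LT_mm",
    "CCT_um", "WTW_mm", "K1_D", "K2_D", "iol_power_D", "postop_ref_D",
    "lens_model", "bscva_at_least_20_40")
}
cohort_character_fields <- function() c("patient_id", "eye", "sex", "lens_model")
cohort_numeric_fields <- function() {
  c("age_years", "AL_mm", "ACD_mm", "LT_mm", "CCT_um", "WTW_mm", "K1_D",
    "K2_D", "iol_power_D", "postop_ref_D")
}

#' @export
#' @rdname as_cohort
#' @param x object to query.
cohort_label <- function(x) attr(x, "label") %||% "cohort"

#' Read a cohort from a delimited text file
#'
#' Reads a CSV (or TSV) with a header row into an [as_cohort()] tibble.
#' Blank cells become explicit `NA`s, never zeros.  Rows whose mapped numeric
#' cells cannot be parsed are excluded and collected in the `rejects`
#' attribute rather than silently coerced.
#'
#' @param path file path.
#' @param schema optional named character vector mapping cohort field names to
#'   file column names, e.g. `c(AL_mm = "AxialLength")`; unmapped fields are
#'   taken from identically named columns.
#' @param sep field separator; defaults to `","`, or `"\t"` when the file
#'   extension is `.tsv`.
#' @return an `iol_cohort` labeled with the file stem; attribute `rejects`
#'   holds a tibble of excluded rows (row number and offending column).
#' @export
read_cohort <- function(path, schema = NULL, sep = NULL) {
  if (!file.exists(path)) stop_iol("file not found: ", path,
                                   class = "iol_io_error")
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", ""),
                           quote = "\"", comment.char = "")
  cols <- stats::setNames(cohort_fields(), cohort_fields())
  if (!is.null(schema)) cols[names(schema)] <- schema
  req <- c("patient_id", "AL_mm", "ACD_mm", "K1_D", "K2_D", "iol_power_D")
  miss <- setdiff(req, names(cols)[cols %in% names(raw)])
  miss <- req[!cols[req] %in% names(raw)]
  if (length(miss)) {
    stop_iol("required column(s) not found in file (after schema mapping): ",
             paste(cols[miss], collapse = ", "), class = "iol_schema_error")
  }
  n <- nrow(raw)
  out <- list()
  reject_row <- integer(0); reject_col <- character(0)
  for (field in cohort_fields()) {
    src <- cols[[field]]
    if (!src %in% names(raw)) {
      out[[field]] <- rep(NA_character_, n)
      next
    }
    cell <- raw[[src]]
    if (field %in% cohort_numeric_fields()) {
      num <- suppressWarnings(as.numeric(cell))
      bad <- which(!is.na(cell) & is.na(num))
      if (length(bad)) {
        reject_row <- c(reject_row, bad)
        reject_col <- c(reject_col, rep(src, length(bad)))
      }
      out[[field]] <- num
    } else if (field == "bscva_at_least_20_40") {
      out[[field]] <- cell %in% c("TRUE", "true", "T", "1", "yes")
      out[[field]][is.na(cell)] <- NA
    } else {
      out[[field]] <- cell
    }
  }
  out <- tibble::as_tibble(out)
  rejects <- tibble::tibble(row = reject_row, column = reject_col)
  if (nrow(rejects)) out <- out[-unique(reject_row), , drop = FALSE]
  cohort <- as_cohort(out, label = tools::file_path_sans_ext(basename(path)))
  attr(cohort, "rejects") <- rejects
  cohort
}

#' Write a cohort to a delimited text file
#'
#' Numeric fields are written with full double precision (15 significant
#' digits) so a write/read round trip is the identity well past 6 significant
#' digits.
#'
#' @param cohort an `iol_cohort`.
#' @param path output path; `.tsv` extension selects tab separation.
#' @param sep optional explicit separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(cohort)[cohort_fields()]
  for (col in cohort_numeric_fields()) {
    df[[col]] <- ifelse(is.na(df[[col]]), NA,
                        formatC(df[[col]], digits = 15, format = "g"))
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Derived keratometric features
#'
#' Mean keratometry Km = (K1 + K2)/2, corneal astigmatism K2 - K1 (>= 0 after
#' canonicalization), and corneal radius of curvature
#' r = 1000 (n_k - 1)/Km with the keratometric index n_k (Lenstar convention
#' 1.3375).
#'
#' @param cohort an `iol_cohort` or data frame with `K1_D`, `K2_D`.
#' @param keratometric_index keratometric index, default 1.3375.
#' @return tibble with `Km_D`, `astigmatism_D`, `r_mm`.
#' @export
derive_features <- function(cohort, keratometric_index = 1.3375) {
  K1 <- cohort$K1_D
  K2 <- cohort$K2_D
  if (any(!is.na(K1) & K1 <= 0) || any(!is.na(K2) & K2 <= 0)) {
    stop_iol("keratometry must be positive", class = "iol_domain_error")
  }
  Km <- (K1 + K2) / 2
  tibble::tibble(Km_D = Km,
                 astigmatism_D = K2 - K1,
                 r_mm = 1000 * (keratometric_index - 1) / Km)
}
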