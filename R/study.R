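#' Study configuration
#'
#' Declarative description of a full comparative study: where each cohort
#' comes from (a delimited file or a simulator profile), which formulas are
#' compared, which cohort (if any) has its constants re-optimized on a
#' training split, and the optics/reporting settings.
#'
#' @param cohorts list of cohort sources; each element is either
#'   `list(file = "path.csv")` or
#'   `list(profile = "aravind_like", n = 985, seed = 11)` (profile may also
#'   be a [population_profile()] object).
#' @param roster formulas to compare (native ids; externally predicted
#'   formulas are added through `external_predictions`).
#' @param constants optional named list of [lens_constants()] overriding the
#'   shipped defaults per roster formula.
#' @param external_predictions named list (formula label -> prediction file)
#'   of externally computed predictions, offset-calibrated when optimization
#'   is enabled.
#' @param optimize_on label of the cohort whose constants are optimized on a
#'   training split (`NULL` disables the optimized context).
#' @param split `list(train_fraction =, seed =)` for the optimization split.
#' @param vertex_mm,keratometric_index optics settings.
#' @param thresholds absolute-error thresholds for the percentage bins.
#' @param eligibility an [eligibility_config()].
#' @return a `study_config` list.
#' @export
study_config <- function(cohorts, roster = c("SRKT", "HofferQ", "Holladay1",
                                             "Haigis"),
                         constants = NULL, external_predictions = NULL,
                         optimize_on = NULL,
                         split = list(train_fraction = 0.70, seed = 1L),
                         vertex_mm = 12, keratometric_index = 1.3375,
                         thresholds = c(0.25, 0.5, 0.75, 1.0),
                         eligibility = eligibility_config()) {
  roster <- match.arg(roster, setdiff(iol_formula_ids(), "External"),
                      several.ok = TRUE)
  if (!is.null(constants)) {
    bad <- setdiff(names(constants), roster)
    if (length(bad)) {
      stop_iol("constants supplied for formulas not in the roster: ",
               paste(bad, collapse = ", "), class = "iol_config_error")
    }
  }
  if (!is.null(optimize_on) && is.null(split$seed)) {
    stop_iol("a split seed is required when optimization is enabled",
             class = "iol_config_error")
  }
  structure(list(cohorts = cohorts, roster = roster, constants = constants,
                 external_predictions = external_predictions,
                 optimize_on = optimize_on, split = split,
                 vertex_mm = vertex_mm,
                 keratometric_index = keratometric_index,
                 thresholds = thresholds, eligibility = eligibility),
            class = "study_config")
}

resolve_cohort <- function(src) {
  if (!is.null(src$file)) return(read_cohort(src$file))
  if (!is.null(src$profile)) {
    pr <- if (inherits(src$profile, "population_profile")) src$profile
          else builtin_profile(src$profile)
    return(generate_cohort(pr, n = src$n, seed = src$seed))
  }
  stop_iol("cohort source must name a file or a profile",
           class = "iol_config_error")
}

constants_for <- function(config, formula) {
  (config$constants[[formula]] %||% default_constants(formula))
}

# per-eye error matrix (eyes x formulas) for one constants setting; external
# predictions restrict the evaluated eyes to the intersection of coverage
context_errors <- function(cohort, config, constants_list,
                           external = NULL, external_offsets = NULL) {
  errs <- list()
  for (f in config$roster) {
    errs[[f]] <- prediction_errors(f, cohort, constants_list[[f]],
                                   config$vertex_mm,
                                   config$keratometric_index)
  }
  ids <- cohort$patient_id
  if (length(external)) {
    for (lbl in names(external)) {
      ext <- external[[lbl]]
      hit <- match(ids, ext$patient_id)
      pred <- ext$predicted_ref_D[hit] -
        (external_offsets[[lbl]] %||% 0)
      errs[[lbl]] <- stats::setNames(pred - cohort$postop_ref_D, ids)
    }
  }
  mat <- do.call(cbind, errs)
  rownames(mat) <- ids
  mat[stats::complete.cases(mat), , drop = FALSE]
}

summaries_from_errors <- function(err_mat, context, thresholds) {
  do.call(rbind, lapply(colnames(err_mat), function(f) {
    summarize_performance(err_mat[, f], thresholds, formula = f,
                          cohort = context)
  }))
}

#' Run a full comparative study
#'
#' Executes the whole pipeline described by a [study_config()]:
#' read/generate cohorts, apply eligibility, compare cohort demographics,
#' evaluate every rostered formula with its shipped/provided constants on
#' each cohort, and — when `optimize_on` names a cohort — split that cohort,
#' re-optimize every native formula's constant on the training split
#' (offset-calibrating external predictions), and evaluate the before/after
#' contexts strictly on the held-out test split, with per-formula paired
#' t-tests on absolute errors and the Friedman/Wilcoxon battery on the
#' optimized context.
#'
#' The bundle is a pure function of `(config, input files)`: all randomness
#' is seeded from the config, and an audit block verifies that no held-out
#' eye influenced optimization.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, the bundle is written as
#'   deterministic delimited tables plus a JSON report via
#'   [write_report_bundle()].
#' @return a `report_bundle` list: `summaries`, `constants_table`,
#'   `comparison` (or `NULL`), `ttests`, `cohort_table`, `exclusions`,
#'   `audit`, `meta`.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_iol("stage '", name, "' failed: ", conditionMessage(e),
               class = "iol_stage_error")
    })
  }

  cohorts <- stage("ingest", lapply(config$cohorts, resolve_cohort))
  elig <- stage("eligibility", lapply(cohorts, apply_eligibility,
                                      config = config$eligibility))
  cohorts <- lapply(elig, `[[`, "cohort")
  labels <- vapply(cohorts, cohort_label, character(1))
  names(cohorts) <- labels
  exclusions <- stats::setNames(lapply(elig, `[[`, "log"), labels)

  cohort_table <- NULL
  if (length(cohorts) >= 2) {
    cohort_table <- stage("cohort_comparison",
                          cohort_comparison(cohorts[[1]], cohorts[[2]]))
  }

  external <- NULL
  if (length(config$external_predictions)) {
    external <- stage("external", lapply(config$external_predictions,
                                         load_external_predictions,
                                         formula_label = "external"))
    for (lbl in names(external)) external[[lbl]]$formula <- lbl
  }

  base_constants <- stats::setNames(
    lapply(config$roster, constants_for, config = config), config$roster)

  summaries <- list()
  constants_rows <- list()
  comparison <- NULL
  ttests <- NULL
  audit <- list()

  for (lbl in labels) {
    err <- stage(paste0("evaluate_", lbl),
                 context_errors(cohorts[[lbl]], config, base_constants,
                                external))
    summaries[[paste0(lbl, "_default")]] <-
      summaries_from_errors(err, paste0(lbl, "_default"), config$thresholds)
  }
  for (f in config$roster) {
    constants_rows[[paste0(f, "_default")]] <- tibble::tibble(
      formula = f, setting = "default",
      constant = scalar_constant_field(f),
      value = base_constants[[f]][[scalar_constant_field(f)]])
  }

  if (!is.null(config$optimize_on)) {
    lbl <- config$optimize_on
    if (!lbl %in% labels) {
      stop_iol("optimize_on cohort '", lbl, "' not found among: ",
               paste(labels, collapse = ", "), class = "iol_config_error")
    }
    sp <- stage("split", split_cohort(cohorts[[lbl]],
                                      config$split$train_fraction %||% 0.70,
                                      config$split$seed))
    opt_constants <- base_constants
    for (f in config$roster) {
      opt_constants[[f]] <- stage(
        paste0("optimize_", f),
        optimize_constant(f, sp$train, base_constants[[f]],
                          vertex_mm = config$vertex_mm,
                          keratometric_index = config$keratometric_index))
      constants_rows[[paste0(f, "_optimized")]] <- tibble::tibble(
        formula = f, setting = "optimized",
        constant = scalar_constant_field(f),
        value = opt_constants[[f]][[scalar_constant_field(f)]])
    }
    offsets <- NULL
    if (length(external)) {
      offsets <- lapply(external, function(ext) {
        hit <- match(sp$train$patient_id, ext$patient_id)
        ok <- !is.na(hit)
        offset_calibrate(ext$predicted_ref_D[hit[ok]],
                         sp$train$postop_ref_D[ok])
      })
      for (lbl_e in names(offsets)) {
        constants_rows[[paste0(lbl_e, "_optimized")]] <- tibble::tibble(
          formula = lbl_e, setting = "optimized (offset-calibrated)",
          constant = "offset_D", value = offsets[[lbl_e]])
      }
    }

    err_before <- stage("evaluate_test_before",
                        context_errors(sp$test, config, base_constants,
                                       external))
    err_after <- stage("evaluate_test_after",
                       context_errors(sp$test, config, opt_constants,
                                      external, offsets))
    summaries[[paste0(lbl, "_test_before")]] <-
      summaries_from_errors(err_before, paste0(lbl, "_test_before"),
                            config$thresholds)
    summaries[[paste0(lbl, "_test_after")]] <-
      summaries_from_errors(err_after, paste0(lbl, "_test_after"),
                            config$thresholds)

    shared <- intersect(rownames(err_before), rownames(err_after))
    ttests <- do.call(rbind, lapply(colnames(err_after), function(f) {
      tt <- paired_abs_error_ttest(abs(err_before[shared, f]),
                                   abs(err_after[shared, f]))
      tibble::tibble(formula = f, t = tt$t, df = tt$df, p = tt$p.value,
                     mean_abs_diff = tt$mean_diff,
                     degenerate = tt$degenerate)
    }))
    if (ncol(err_after) >= 3 && nrow(err_after) >= 10) {
      comparison <- stage("compare_formulas",
                          compare_formulas(abs(err_after)))
    }

    # leakage audit: optimization must have consumed only training eyes
    for (f in config$roster) {
      train_ids <- attr(opt_constants[[f]], "train_ids")
      if (length(intersect(train_ids, sp$test$patient_id))) {
        stop_iol("test-set leakage detected for ", f,
                 class = "iol_leakage_error")
      }
    }
    audit <- list(
      optimized_cohort = lbl,
      n_train = nrow(sp$train), n_test = nrow(sp$test),
      split_seed = config$split$seed,
      train_test_disjoint = length(intersect(sp$train$patient_id,
                                             sp$test$patient_id)) == 0,
      n_intersection = nrow(err_after))
  }

  bundle <- list(
    summaries = do.call(rbind, summaries),
    constants_table = do.call(rbind, constants_rows),
    comparison = comparison,
    ttests = ttests,
    cohort_table = cohort_table,
    exclusions = exclusions,
    audit = audit,
    meta = list(labels = labels,
                n_eyes = vapply(cohorts, nrow, integer(1)),
                roster = config$roster,
                external = names(config$external_predictions),
                vertex_mm = config$vertex_mm,
                keratometric_index = config$keratometric_index,
                split = config$split,
                config_hash = config_hash(config)))
  class(bundle) <- "report_bundle"
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::serializeJSON(unclass(config))), tf)
  unname(tools::md5sum(tf))
}

#' Write a report bundle as deterministic text tables
#'
#' Emits `summaries.csv`, `constants.csv`, `ttests.csv`, `cohort_table.csv`,
#' `exclusions_<label>.csv`, `comparison.csv` (pairwise adjusted p-values)
#' and `report.json` under `dir`.  Output is byte-identical for identical
#' bundles.  Human-readable tables round diopters and percentages to 2
#' decimals; `report.json` keeps full precision.
#'
#' @param bundle a `report_bundle` from [run_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file, digits = 2) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1)) &
      !names(df) %in% c("n", "df")
    df[num] <- lapply(df[num], function(x) formatC(round(x, digits),
                                                   format = "f",
                                                   digits = digits))
    utils::write.table(df, file.path(dir, file), sep = ",",
                       row.names = FALSE, quote = FALSE, na = "")
  }
  w(bundle$summaries, "summaries.csv")
  w(bundle$constants_table, "constants.csv", digits = 6)
  if (!is.null(bundle$ttests)) w(bundle$ttests, "ttests.csv", digits = 6)
  if (!is.null(bundle$cohort_table)) {
    w(bundle$cohort_table, "cohort_table.csv", digits = 4)
  }
  for (lbl in names(bundle$exclusions)) {
    utils::write.table(as.data.frame(bundle$exclusions[[lbl]]),
                       file.path(dir, paste0("exclusions_", lbl, ".csv")),
                       sep = ",", row.names = FALSE, quote = FALSE, na = "")
  }
  if (!is.null(bundle$comparison)) {
    cm <- bundle$comparison
    df <- as.data.frame(cm$p_adj)
    df <- cbind(formula = rownames(cm$p_adj), df)
    utils::write.table(format(df, digits = 6),
                       file.path(dir, "comparison.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE, na = "")
  }
  json <- list(summaries = bundle$summaries,
               constants = bundle$constants_table,
               ttests = bundle$ttests,
               friedman = if (!is.null(bundle$comparison)) {
                 list(stat = bundle$comparison$friedman_stat,
                      df = bundle$comparison$friedman_df,
                      p = bundle$comparison$friedman_p)
               },
               audit = bundle$audit, meta = bundle$meta)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
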