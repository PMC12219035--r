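test_that("read_cohort parses a well-formed file and propagates missingness", {
  df <- tiny_records()[1:3, ]
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(df), f, row.names = FALSE, quote = FALSE)
  co <- read_cohort(f)
  expect_s3_class(co, "iol_cohort")
  expect_equal(nrow(co), 3)
  expect_equal(co$AL_mm, df$AL_mm)
  expect_equal(co$patient_id, df$patient_id)
  expect_equal(cohort_label(co), tools::file_path_sans_ext(basename(f)))

  # blank K1 cell in row 2 becomes an explicit NA, not a zero
  df2 <- df
  df2$K1_D <- as.character(df2$K1_D)
  df2$K1_D[2] <- ""
  utils::write.csv(as.data.frame(df2), f, row.names = FALSE, quote = FALSE)
  co2 <- read_cohort(f)
  expect_equal(nrow(co2), 3)
  expect_true(is.na(co2$K1_D[2]))
  expect_false(any(co2$K1_D[c(1, 3)] == 0))
})

test_that("unparseable numeric cells exclude the row into the rejects report", {
  df <- tiny_records()[1:3, ]
  df$AL_mm <- as.character(df$AL_mm)
  df$AL_mm[2] <- "twenty-four"
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(df), f, row.names = FALSE, quote = FALSE)
  co <- read_cohort(f)
  expect_equal(nrow(co), 2)
  rej <- attr(co, "rejects")
  expect_equal(rej$row, 2)
  expect_equal(rej$column, "AL_mm")
})

test_that("read_cohort errors when a required column is unmapped", {
  df <- tiny_records()[1:2, ]
  names(df)[names(df) == "AL_mm"] <- "axial"
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(df), f, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(f), class = "iol_schema_error")
  co <- read_cohort(f, schema = c(AL_mm = "axial"))
  expect_equal(co$AL_mm, c(23.1, 24.0))
})

test_that("write/read round trip is the identity on a generated cohort", {
  co <- generate_cohort(builtin_profile("aravind_like"), 50, seed = 301)
  for (ext in c(".csv", ".tsv")) {
    f <- withr::local_tempfile(fileext = ext)
    write_cohort(co, f)
    back <- read_cohort(f)
    for (col in c("AL_mm", "ACD_mm", "LT_mm", "CCT_um", "WTW_mm", "K1_D",
                  "K2_D", "iol_power_D", "postop_ref_D", "age_years")) {
      expect_equal(back[[col]], co[[col]], tolerance = 1e-12, info = col)
    }
    expect_identical(back$patient_id, co$patient_id)
    expect_identical(back$sex, co$sex)
    expect_identical(back$eye, co$eye)
  }
})

test_that("keratometry is canonicalized so K2 >= K1", {
  df <- tiny_records()[1:2, ]
  df$K1_D <- c(45.0, 43.0)
  df$K2_D <- c(44.0, 44.0)   # first row violates the convention
  co <- as_cohort(df)
  expect_equal(co$K1_D, c(44.0, 43.0))
  expect_equal(co$K2_D, c(45.0, 44.0))
})

test_that("eligibility excludes by bounds, acuity, lens model and second eyes", {
  df <- tiny_records()
  df$AL_mm[2] <- 14.0                       # under AL bounds
  co <- as_cohort(df)
  res <- apply_eligibility(co, eligibility_config())
  expect_equal(nrow(res$cohort), 3)
  expect_equal(res$log$reason, "out-of-bounds AL_mm")
  expect_equal(res$log$patient_id, "p2")

  df <- tiny_records()
  df$patient_id[2] <- "p1"                  # second eye of p1
  res <- apply_eligibility(as_cohort(df), eligibility_config())
  expect_equal(nrow(res$cohort), 3)
  expect_equal(res$log$reason, "second eye excluded")
  expect_equal(res$cohort$eye[res$cohort$patient_id == "p1"], "right")

  df <- tiny_records()
  df$bscva_at_least_20_40[3] <- FALSE
  df$lens_model[4] <- "ZCB00"
  res <- apply_eligibility(as_cohort(df), eligibility_config())
  expect_setequal(res$log$reason,
                  c("BSCVA worse than 20/40", "lens model not SN60WF"))

  # all-passing cohort: unchanged, empty log
  res <- apply_eligibility(as_cohort(tiny_records()), eligibility_config())
  expect_equal(nrow(res$cohort), 4)
  expect_equal(nrow(res$log), 0)
})

test_that("eligibility is idempotent and partitions the input", {
  co <- generate_cohort(builtin_profile("umich_like"), 200, seed = 77)
  # corrupt a few records to exercise every rule
  co$AL_mm[5] <- 40
  co$ACD_mm[10] <- NA
  co$lens_model[15] <- "other"
  co$bscva_at_least_20_40[20] <- FALSE
  co$patient_id[25] <- co$patient_id[24]
  res1 <- apply_eligibility(co, eligibility_config())
  expect_equal(nrow(res1$cohort) + nrow(res1$log), nrow(co))
  res2 <- apply_eligibility(res1$cohort, eligibility_config())
  expect_equal(nrow(res2$log), 0)
  expect_equal(res2$cohort$patient_id, res1$cohort$patient_id)
  # reasons are assigned in rule order: bounds checked before duplicates
  expect_equal(sort(unique(res1$log$reason)),
               sort(c("out-of-bounds AL_mm", "missing ACD_mm",
                      "lens model not SN60WF", "BSCVA worse than 20/40",
                      "second eye excluded")))
})

test_that("derived keratometric features follow their definitions", {
  feats <- derive_features(tibble::tibble(K1_D = 44, K2_D = 46))
  expect_equal(feats$Km_D, 45)
  expect_equal(feats$astigmatism_D, 2)
  expect_equal(feats$r_mm, 337.5 / 45)   # = 7.5 mm

  flat <- derive_features(tibble::tibble(K1_D = 43, K2_D = 43))
  expect_equal(flat$astigmatism_D, 0)
  expect_equal(flat$Km_D, 43)

  # profile means reproduce the published mean keratometry
  pr <- builtin_profile("aravind_like")
  km <- derive_features(tibble::tibble(K1_D = pr$means[["K1_D"]],
                                       K2_D = pr$means[["K2_D"]]))$Km_D
  expect_equal(km, 44.53)

  expect_error(derive_features(tibble::tibble(K1_D = -1, K2_D = 44)),
               class = "iol_domain_error")
})
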