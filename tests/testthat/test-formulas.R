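test_that("all four formulas match independent hand-computed chains", {
  co <- panel_cohort()
  dflt <- list(SRKT = default_constants("SRKT"),
               HofferQ = default_constants("HofferQ"),
               Holladay1 = default_constants("Holladay1"),
               Haigis = default_constants("Haigis"))
  Km <- (co$K1_D + co$K2_D) / 2
  for (i in seq_len(nrow(co))) {
    expected <- c(
      SRKT = oracle_srkt(co$AL_mm[i], Km[i], dflt$SRKT$A_const,
                         co$iol_power_D[i]),
      HofferQ = oracle_hofferq(co$AL_mm[i], Km[i], dflt$HofferQ$pACD_mm,
                               co$iol_power_D[i]),
      Holladay1 = oracle_holladay1(co$AL_mm[i], Km[i], dflt$Holladay1$SF_mm,
                                   co$iol_power_D[i]),
      Haigis = oracle_haigis(co$AL_mm[i], co$ACD_mm[i], Km[i],
                             dflt$Haigis$haigis_a0, dflt$Haigis$haigis_a1,
                             dflt$Haigis$haigis_a2, co$iol_power_D[i])
    )
    for (f in names(expected)) {
      got <- predict_refraction(f, co[i, ], dflt[[f]])$predicted_ref_D
      expect_equal(got, unname(expected[f]), tolerance = 0.01,
                   info = paste(f, "eye", i))
    }
  }
})

test_that("Haigis ELP degenerates to a0 when a1 = a2 = 0", {
  co <- panel_cohort()
  cst <- lens_constants("Haigis", haigis_a0 = 5.1, haigis_a1 = 0,
                        haigis_a2 = 0)
  pr <- predict_refraction("Haigis", co, cst)
  expect_equal(pr$elp_mm, rep(5.1, nrow(co)))
})

test_that("predicted refraction is strictly decreasing in IOL power", {
  co <- panel_cohort()
  grid <- seq(6, 34, by = 0.5)
  for (f in c("SRKT", "HofferQ", "Holladay1", "Haigis")) {
    for (i in seq_len(nrow(co))) {
      refs <- vapply(grid, function(p) {
        predict_refraction(f, co[i, ], iol_power_D = p)$predicted_ref_D
      }, numeric(1))
      expect_true(all(diff(refs) < 0), info = paste(f, "eye", i))
    }
  }
})

test_that("predicted refraction is strictly monotone in the lens constant", {
  co <- panel_cohort()[3, ]
  # direction: raising any ELP-increasing constant makes the eye effectively
  # longer-optics, shifting the prediction hyperopic (more positive)
  sweep_refs <- function(f, field, values) {
    vapply(values, function(v) {
      cst <- default_constants(f)
      cst[[field]] <- v
      predict_refraction(f, co, cst)$predicted_ref_D
    }, numeric(1))
  }
  expect_true(all(diff(sweep_refs("SRKT", "A_const",
                                  seq(113, 125, 0.5))) > 0))
  expect_true(all(diff(sweep_refs("HofferQ", "pACD_mm", seq(2, 9, 0.25))) > 0))
  expect_true(all(diff(sweep_refs("Holladay1", "SF_mm",
                                  seq(-2, 5, 0.25))) > 0))
  expect_true(all(diff(sweep_refs("Haigis", "haigis_a0",
                                  seq(-1, 3, 0.25))) > 0))
})

test_that("vertex 0 gives the corneal-plane refraction for every formula", {
  co <- panel_cohort()
  for (f in c("SRKT", "HofferQ", "Holladay1", "Haigis")) {
    r0 <- predict_refraction(f, co, vertex_mm = 0)$predicted_ref_D
    r12 <- predict_refraction(f, co, vertex_mm = 12)$predicted_ref_D
    # corneal -> spectacle transfer applied by hand to the corneal value
    expect_equal(r12, r0 / (1 + r0 * 12 / 1000), tolerance = 1e-9,
                 info = f)
  }
})

test_that("constants are validated against the formula", {
  co <- panel_cohort()[1, ]
  expect_error(lens_constants("SRKT"), class = "iol_config_error")
  expect_error(lens_constants("Haigis", haigis_a0 = 1), class = "iol_config_error")
  expect_error(predict_refraction("SRKT", co,
                                  lens_constants("HofferQ", pACD_mm = 5.7)),
               class = "iol_config_error")
  # ELP domain violations name the record
  bad <- lens_constants("Haigis", haigis_a0 = -9, haigis_a1 = 0,
                        haigis_a2 = 0)
  expect_error(predict_refraction("Haigis", co, bad), "panel-1",
               class = "iol_numeric_error")
})

test_that("A-constant conversions are consistent, deterministic, increasing", {
  expect_lt(abs(convert_a_constant(119.082, "pACD") - 5.727), 0.5)
  expect_lt(abs(convert_a_constant(119.082, "SF") - 1.860), 0.5)
  expect_identical(convert_a_constant(118.4, "pACD"),
                   convert_a_constant(118.4, "pACD"))
  grid <- seq(110, 125, by = 0.5)
  for (target in c("pACD", "SF", "haigis_a0")) {
    expect_true(all(diff(convert_a_constant(grid, target)) > 0))
  }
  expect_error(convert_a_constant(130, "pACD"), class = "iol_domain_error")
})

test_that("external predictions load, flag coverage, and match in-process path", {
  co <- generate_cohort(builtin_profile("aravind_like"), 40, seed = 88)
  pred <- predict_refraction("SRKT", co)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(
    data.frame(patient_id = pred$patient_id,
               predicted_ref_D = sprintf("%.15g", pred$predicted_ref_D)),
    f, row.names = FALSE, quote = FALSE)
  ext <- load_external_predictions(f, "SRKT_ext", cohort = co)
  expect_equal(nrow(ext), 40)
  expect_length(attr(ext, "missing"), 0)
  # round-tripped external predictions give identical downstream errors
  err_native <- prediction_errors("SRKT", co)
  err_ext <- ext$predicted_ref_D[match(co$patient_id, ext$patient_id)] -
    co$postop_ref_D
  expect_equal(unname(err_native), err_ext, tolerance = 1e-12)

  # missing eye is reported; duplicate id errors; bad cell is rejected
  utils::write.csv(data.frame(patient_id = pred$patient_id[-1],
                              predicted_ref_D = pred$predicted_ref_D[-1]),
                   f, row.names = FALSE, quote = FALSE)
  ext2 <- load_external_predictions(f, "x", cohort = co)
  expect_equal(attr(ext2, "missing"), co$patient_id[1])
  utils::write.csv(data.frame(patient_id = c("a", "a"),
                              predicted_ref_D = c(0.1, 0.2)),
                   f, row.names = FALSE, quote = FALSE)
  expect_error(load_external_predictions(f, "x"), class = "iol_schema_error")
  utils::write.csv(data.frame(patient_id = c("a", "b"),
                              predicted_ref_D = c("0.1", "oops")),
                   f, row.names = FALSE, quote = FALSE)
  ext3 <- load_external_predictions(f, "x")
  expect_equal(nrow(ext3), 1)
  expect_equal(attr(ext3, "rejects"), "b")
})
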