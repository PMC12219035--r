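# Fixture builders shared across test files.  All cohorts are generated in
# code under fixed seeds; nothing is read from disk except round-trip temps.

panel_cohort <- function() as_cohort(oracle_panel(), label = "panel")

# small hand-built cohort for the io/eligibility tests
tiny_records <- function() {
  tibble::tibble(
    patient_id = c("p1", "p2", "p3", "p4"),
    eye = c("right", "left", "right", "left"),
    age_years = c(61, 58, 70, 66),
    sex = c("F", "M", "F", "M"),
    AL_mm = c(23.1, 24.0, 22.5, 25.2),
    ACD_mm = c(3.2, 3.4, 3.0, 3.6),
    LT_mm = c(4.3, 4.1, 4.5, 4.2),
    CCT_um = c(520, 545, 510, 560),
    WTW_mm = c(11.8, 12.1, 11.5, 12.3),
    K1_D = c(44.0, 43.2, 45.1, 42.5),
    K2_D = c(44.8, 43.9, 45.9, 43.3),
    iol_power_D = c(21.5, 20.0, 23.0, 18.5),
    postop_ref_D = c(0.05, -0.25, 0.12, -0.50),
    lens_model = "SN60WF",
    bscva_at_least_20_40 = TRUE
  )
}

# SRK/T-truth profile with a chosen A-constant and noise level
srkt_truth_profile <- function(A = 119.082, noise_sd = 0.3,
                               base = "aravind_like") {
  pr <- builtin_profile(base)
  population_profile(paste0("srkt_truth_A", A), pr$means, pr$sds, pr$corr,
                     sex_ratio_female = pr$sex_ratio_female,
                     right_eye_ratio = pr$right_eye_ratio,
                     target_mean_D = pr$target_mean_D,
                     target_sd_D = pr$target_sd_D,
                     truth_formula = "SRKT",
                     truth_constants = lens_constants("SRKT", A_const = A),
                     noise_sd_D = noise_sd)
}

haigis_truth_profile <- function(a0 = -0.70, a1 = 0.4, a2 = 0.1,
                                 noise_sd = 0.3) {
  pr <- builtin_profile("aravind_like")
  population_profile("haigis_truth", pr$means, pr$sds, pr$corr,
                     sex_ratio_female = pr$sex_ratio_female,
                     right_eye_ratio = pr$right_eye_ratio,
                     target_mean_D = pr$target_mean_D,
                     target_sd_D = pr$target_sd_D,
                     truth_formula = "Haigis",
                     truth_constants = lens_constants(
                       "Haigis", haigis_a0 = a0, haigis_a1 = a1,
                       haigis_a2 = a2),
                     noise_sd_D = noise_sd)
}
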