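# Independent step-by-step evaluations of the published formula chains.
#
# Deliberately written on a different path from the package: each oracle
# computes the published "power for desired refraction" form scalar-by-scalar
# and solves that forward equation for the refraction numerically, whereas
# the package uses the closed-form refraction-for-power inversions.

oracle_ref <- function(pow_fun, P) {
  stats::uniroot(function(Rx) pow_fun(Rx) - P, c(-40, 40), tol = 1e-12)$root
}

oracle_srkt <- function(AL, Km, A, P, V = 12) {
  r <- 337.5 / Km
  LC <- if (AL > 24.2) -3.446 + 1.715 * AL - 0.0237 * AL^2 else AL
  Cw <- -5.41 + 0.58412 * LC + 0.098 * Km
  H <- r - sqrt(max(r^2 - (Cw / 2)^2, 0))
  ACDc <- 0.62467 * A - 68.747
  elp <- H + ACDc - 3.336
  Lo <- AL + 0.65696 - 0.02029 * AL
  na <- 1.336; ncm1 <- 0.333
  pow <- function(Rx) {
    XL <- na * r - ncm1 * Lo
    XC <- na * r - ncm1 * elp
    (1000 * na * (XL - 0.001 * Rx * (V * XL + Lo * r))) /
      ((Lo - elp) * (XC - 0.001 * Rx * (V * XC + elp * r)))
  }
  oracle_ref(pow, P)
}

oracle_holladay1 <- function(AL, Km, SF, P, V = 12) {
  r <- 337.5 / Km
  AG <- min(12.5 * AL / 23.45, 13.5)
  elp <- 0.56 + r - sqrt(max(r^2 - (AG / 2)^2, 0)) + SF
  Lo <- AL + 0.2
  na <- 1.336; ncm1 <- 1 / 3
  pow <- function(Rx) {
    XL <- na * r - ncm1 * Lo
    XC <- na * r - ncm1 * elp
    (1000 * na * (XL - 0.001 * Rx * (V * XL + Lo * r))) /
      ((Lo - elp) * (XC - 0.001 * Rx * (V * XC + elp * r)))
  }
  oracle_ref(pow, P)
}

oracle_hofferq <- function(AL, Km, pACD, P, V = 12) {
  CAL <- min(max(AL, 18.5), 31)
  M <- if (CAL <= 23) 1 else -1
  G <- if (CAL <= 23) 28 else 23.5
  elp <- pACD + 0.3 * (CAL - 23.5) + tan(Km * pi / 180)^2 +
    0.1 * M * (23.5 - CAL)^2 * tan(0.1 * (G - CAL)^2 * pi / 180) - 0.99166
  pow <- function(Rx) {
    Rc <- Rx / (1 - Rx * V / 1000)
    1336 / (AL - elp - 0.05) -
      1.336 / (1.336 / (Km + Rc) - (elp + 0.05) / 1000)
  }
  oracle_ref(pow, P)
}

oracle_haigis <- function(AL, ACD, Km, a0, a1, a2, P, V = 12) {
  d <- a0 + a1 * ACD + a2 * AL
  RC <- (1.3375 - 1) / Km           # corneal radius, m
  DC <- (1.3315 - 1) / RC
  n <- 1.336; L <- AL / 1000; dm <- d / 1000; dx <- V / 1000
  pow <- function(Rx) {
    Rc <- Rx / (1 - Rx * dx)
    z <- DC + Rc
    n / (L - dm) - n / (n / z - dm)
  }
  oracle_ref(pow, P)
}

# fixture panel spanning short, average and long eyes
oracle_panel <- function() {
  tibble::tibble(
    patient_id = paste0("panel-", 1:5),
    AL_mm = c(21.0, 22.5, 23.5, 25.0, 26.5),
    K1_D = c(45.5, 44.0, 43.5, 42.0, 41.0),
    K2_D = c(46.5, 45.0, 43.5, 43.0, 42.0),
    ACD_mm = c(2.8, 3.0, 3.2, 3.5, 3.8),
    iol_power_D = c(28.0, 24.0, 21.0, 18.0, 15.0),
    postop_ref_D = 0
  )
}
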