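---
title: "Benchmarking IOL power formulas with population-specific constant optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking IOL power formulas with population-specific constant optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iolpred)
```

## The model

An IOL power formula predicts the postoperative spherical-equivalent
refraction of a pseudophakic eye from preoperative biometry and the
implanted power. All four formulas implemented here (SRK/T, Hoffer Q,
Holladay 1, Haigis) share the same two-stage architecture:

1. **Effective lens position (ELP).** A formula-specific empirical model
   predicts the postoperative axial depth of the IOL's principal plane from
   AL and keratometry (SRK/T, Hoffer Q, Holladay 1) or AL and preoperative
   ACD (Haigis). Each model is personalized by one scalar constant: the
   A-constant (SRK/T), personalized ACD (Hoffer Q), surgeon factor
   (Holladay 1), or the intercept a0 of the Haigis linear model
   `ELP = a0 + a1·ACD + a2·AL`.
2. **Vergence chain.** Light is propagated through a thin-lens model —
   cornea of power K (from the measured radius), IOL of power P at the ELP,
   image on the retina at the (formula-specific) optical axial length — and
   the refraction that closes the chain is reported at the spectacle plane
   over a vertex distance v, using `R_x = R_c / (1 + R_c·v)`.

The exact published variants (clamp rules, corrected axial length, corneal
indices) are listed in `inst/formula-provenance.md`. Prediction error is
pinned to **predicted − measured**: a positive error means the formula
expected a more hyperopic outcome than observed. The prediction chains are
implemented as closed-form inversions of the published power-for-refraction
equations; the test suite checks them against independently coded
step-by-step evaluations that invert the forward equations numerically, so
the two routes share no code path.

## Constant optimization and offset calibration

The mean prediction error ME(c) is strictly monotone in each formula's
scalar constant (raising any ELP-raising constant shifts every prediction
hyperopically), so the "empirical optimization" of a lens constant is
exactly a root-finding problem. `optimize_constant()` brackets the root
(defaults: A ∈ [110, 125], pACD ∈ [2, 9] mm, SF ∈ [−2, 5] mm,
a0 ∈ [−3, 3] mm), verifies a sign change and monotonicity on a coarse grid,
and solves with `stats::uniroot` to |ME| < 1e−6 D. Two numerical details:

- At extreme bracket endpoints the ELP of unusual eyes can leave the valid
  domain (0, AL); endpoints are then shrunk toward the bracket centre in 5%
  steps until the chain is valid, keeping the nominal bracket as the search
  frame rather than failing outright.
- Only the Haigis intercept a0 is optimized, with slopes fixed at a1 = 0.4,
  a2 = 0.1. Published Haigis constants are usually triples fitted jointly
  per lens; a single published a0 taken into this convention is therefore
  only a starting point, and can be grossly mis-centred until optimized —
  the pipeline treats that as a feature (it is exactly the
  constant-transfer problem the analysis studies) rather than silently
  re-fitting slopes.

Closed-source formulas enter as per-eye prediction files and are calibrated
by **offset subtraction**: the training-set ME is subtracted from every
prediction, which zeroes the training ME exactly and is locally equivalent
to a constant shift because ME is locally linear in the constant (the test
suite verifies the equivalence to 0.02 D on held-out MAE). Evaluation always
restricts to the intersection of eyes covered by every compared formula.

All optimized-context metrics are computed **only on the held-out 30%
split**. The split is a seeded uniform permutation with sizes
`round(n·0.7)` / remainder; `run_study()` carries an audit block proving
that the ids consumed by optimization are disjoint from the test ids.

## Statistical conventions

Where the literature leaves a choice open, this package pins one and tests
its boundary behavior:

- *Threshold bins* use inclusive |e| ≤ t, the common convention in
  refractive-outcome reporting.
- *SD of error* uses the n − 1 denominator; the identity
  RMSAE² = ME² + SD²·(n−1)/n is asserted to 1e−12.
- *Between-group and sex-difference tests* are two-sided Student t-tests
  (equal variances); laterality, being a count, uses a two-proportion
  z-test instead.
- *Pairwise formula comparison* uses the Wilcoxon signed-rank test with
  **Pratt** zero handling (zeros ranked, then dropped from the rank sums),
  mid-ranks for ties, and the zero/tie-corrected normal approximation with
  continuity correction. Software defaults differ here (base R discards
  zeros), so the convention is pinned and the implementation is verified
  against reference values of the same convention.
- *Multiplicity* over formula pairs is Bonferroni: p_adj = min(1, m·p_raw),
  flags at adjusted p < 0.05; flags are provably a subset of raw-significant
  pairs.
- Degenerate inputs are defined, not crashed: identical paired vectors give
  t = 0, p = 1; constant nonzero differences warn and return p = NA; a
  fully tied Friedman matrix reports statistic 0, p = 1.

## The synthetic populations

No per-eye clinical data ship with the package; the generator provides a
stated world in which every pipeline stage is testable.

- **Marginals.** Each profile fixes means for age, AL, ACD, LT, CCT, WTW,
  K1, K2 and the published dispersions where available (AL SD 0.94 mm for
  the South-Indian-like profile, 1.35 mm for the US-like one; age SD 9.5 y).
  SDs not published anywhere (ACD 0.35, LT 0.40 mm, CCT 33 µm, WTW 0.45 mm,
  K 1.5 D) are simulator defaults chosen from typical biometry series, not
  estimates of the study cohorts.
- **Correlations** (AL–ACD +0.45, AL–K −0.35, AL–LT −0.20, K1–K2 +0.90,
  others 0) are stipulated: longer eyes have deeper chambers and flatter
  corneas, the two meridians track each other. A joint normal truncated to
  the eligibility bounds is used instead of a copula for transparency;
  truncation is negligible at these means (> 4 SD from every bound).
- **Practice patterns.** Each eye draws a target refraction from the
  profile's policy — near-emmetropic and tight (0.10 ± 0.33 D) for the
  South-Indian-like profile, myopic and wide (−0.59 ± 0.93 D) for the
  US-like profile — and implants the 0.5 D-grid power whose truth-formula
  prediction is closest to the target (ties to the lower power, the
  convention that avoids unintended hyperopia).
- **Outcomes.** Measured refraction = truth-formula prediction + N(0, σ)
  with σ = 0.3 D by default, the typical short-term refraction
  measurement/biological noise scale; σ = 0 produces an exact closed loop
  in which the truth formula scores zero error everywhere.
- The truth formula defaults to SRK/T at A = 119.082 so the generator
  exercises the same code path the tests probe — an intentional closed
  loop; a Haigis-truth profile is used in the tests to exercise
  cross-formula optimization.

**What a green test does and does not establish.** The generator reproduces
the direction pattern of the two populations (shorter, younger,
thinner-corneal South Indian eyes; flatter, longer, more myopically
targeted US eyes) and realistic error scales, so tests establish that the
pipeline's machinery — eligibility, splitting, optimization, calibration,
metrics, statistics — is correct and leak-free. They do not establish the
published cohort-level performance numbers: real within-cohort
correlations, the long-eye tail, formula-specific population misfit and
measurement artifacts are not modeled, so only directional and
property-level agreement is claimed.

## Defaults that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| vertex distance | 12 | mm | common refraction-lane convention; 0 gives corneal-plane values |
| keratometric index | 1.3375 | — | Lenstar convention, matches the biometer class the profiles emulate |
| Haigis slopes a1, a2 | 0.4, 0.1 | — | classical single-constant convention; only a0 is optimized |
| optimization tolerance | 1e−6 | D on ME | far below clinical resolution; cheap with root finding |
| train fraction | 0.70 | — | the study design being emulated |
| noise σ | 0.3 | D | typical 1-month refraction noise scale |
| IOL grid | 6–30 by 0.5 | D | commercially available SN60WF-like range |
| eligibility bounds | AL 18–35 mm, ACD 1.5–5, K 35–52 D, LT 2.5–6.5, CCT 400–700 µm, WTW 9–14, power 0–40 D | | cover published formula validity ranges; config-overridable |

## Known limitations

- Barrett Universal II, Pearl-DGS and learned models are handled only as
  external prediction files with offset calibration; their internals (and
  transfer learning of learned models) are out of scope.
- Astigmatism is carried as a descriptive feature only; predictions are
  spherical equivalent.
- Joint (a0, a1, a2) Haigis optimization, per-surgeon constants and
  bootstrap confidence intervals on constants are not implemented.
- The eligibility tie-break for two eligible eyes of one patient keeps the
  earlier row in file order — deterministic and auditable, but a stipulated
  rule, not a clinical one.
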