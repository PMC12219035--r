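# Formula provenance

Which published variant of each equation chain `predict_refraction()`
implements, and the constants plumbing around them. All four formulas end in
a thin-lens vergence chain evaluated at the corneal plane and transferred to
the spectacle plane over the configured vertex distance (default 12 mm).
Keratometric diopters are converted to corneal radius with the keratometric
index 1.3375 (Lenstar convention) unless stated otherwise.

## SRK/T

Retzlaff–Sanders–Kraff theoretical formula with the published corrections:

- corrected axial length for long eyes:
  `LCOR = -3.446 + 1.715·AL - 0.0237·AL²` when `AL > 24.2`, else `AL`;
- computed corneal width `Cw = -5.41 + 0.58412·LCOR + 0.098·K`;
- Fyodorov corneal height with the square-root clamp
  (`r² - Cw²/4` floored at 0);
- ACD-constant from the A-constant: `ACDconst = 0.62467·A - 68.747`,
  ELP = H + ACDconst - 3.336;
- retinal thickness `0.65696 - 0.02029·AL` added to the optical axial
  length;
- refraction-for-power vergence equation with `na = 1.336`, `nc - 1 = 0.333`.

## Hoffer Q

1993 personalized-ACD formula with the published errata behavior:

- axial length clamped to `[18.5, 31]` mm inside the ELP model;
- short-eye branch `M = +1, G = 28` for `AL ≤ 23`, long-eye branch
  `M = -1, G = 23.5` otherwise;
- degree-based tangent terms
  `+ tan²(K)` and `+ 0.1·M·(23.5 - AL)²·tan(0.1·(G - AL)²) - 0.99166`;
- power formula `P = 1336/(AL - ACD - 0.05) - 1.336/(1.336/(K + R) -
  (ACD + 0.05)/1000)` inverted in closed form for the predicted refraction.

## Holladay 1

1988 three-part formula:

- scaled corneal diameter `AG = 12.5·AL/23.45` capped at 13.5 mm;
- anatomical ACD `0.56 + r - sqrt(r² - AG²/4)` plus the surgeon factor;
- optical axial length `AL + 0.2` mm;
- same vergence equation as SRK/T but with Holladay's `nc = 4/3`
  (`nc - 1 = 1/3`).

## Haigis

- ELP `d = a0 + a1·ACD + a2·AL` on the preoperative anatomical ACD;
- corneal power recomputed from the measured radius with Haigis's corneal
  index `nc = 1.3315`;
- thin-lens chain `P = n/(L - d) - n/(n/z - d)` with `n = 1.336`, distances
  in meters, `z = D_cornea + R_corneal-plane`, inverted in closed form.
- This package fixes `a1 = 0.4`, `a2 = 0.1` and optimizes `a0` only;
  published a0 values paired with lens-specific (a1, a2) triples are not
  interchangeable with this convention, so a shipped a0 is only a starting
  point for optimization.

## Constant transfers

Nominal linear transfers used to seed the other constants from one
A-constant (`convert_a_constant()`): `pACD = 0.58357·A - 63.896`,
`SF = 0.5663·A - 65.60`, `a0 = 0.62467·A - 72.434` (the last valid for the
`a1 = 0.4, a2 = 0.1` convention). Empirically optimized constants need not
match these transfers exactly.
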