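---
title: "Methods: models, calibration and design decisions in pedree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design decisions in pedree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedree)
```

## The problem

Resting energy expenditure (REE, kcal/d) is the dominant component of a
child's daily energy requirement. The reference measurement is indirect
calorimetry; in routine practice REE is instead predicted from
anthropometry with published linear equations. Every equation was fitted
in a specific population, and validating it elsewhere means quantifying,
subject by subject, how far predictions fall from calorimetry. `pedree`
implements that validation workflow — prediction, agreement statistics,
stratification by weight status and sex, and the regression procedure used
to derive new equations — together with a calibrated simulator so the
whole pipeline is testable end to end without patient data.

## The prediction equations

The registry (`ree_equations()`) holds 14 equations. Each is stored
exactly as published: native energy unit (kcal/d, kJ/d or MJ/d), height in
cm or m as the source used it, and the source's own 0/1 sex coding. Three
conventions deserve attention because they are classic sources of silent
error:

* **Sex codings differ per equation.** Molnar and both Müller forms code
  male = 0, female = 1; Tverskaya and both Lazzer forms code male = 1,
  female = 0. The registry applies each equation's own coding internally;
  data files always say `"male"`/`"female"` and numeric codes never appear
  outside an equation's definition. We note that the Müller coding as
  printed in our source differs from the original 2004 publication
  (male = 1); we implement what our source prints and flag it here rather
  than silently "correcting" either way. Similarly the Kim equation is
  carried with its printed 4–11-year range and coefficients, and
  Derumeaux-Burel as a single sex-free FFM equation, as printed.
* **Units.** kJ/d and MJ/d equations are converted to kcal/d with the
  thermochemical calorie, 1 kcal = 4.184 kJ. The factor is an argument
  (`kj_per_kcal`) everywhere it is used, so its sensitivity can be probed;
  round trips are exact.
* **Age dispatch.** Equations published with 3–10 and 10–18 year bands
  (WHO, Schofield, Henry) dispatch with the child band as [3, 10) and the
  adolescent band as [10, 18]: ages ≥ 10 use the adolescent variant, making
  the bands a partition. Ages outside an equation's stated range are still
  evaluated — validation tables in this literature report every equation on
  the whole cohort, including, say, 17-year-olds under the Kim (4–11) or
  Schmelzle (4–15) equations — but the prediction carries an
  `out_of_stated_range` flag, and `strict_age_range = TRUE` turns the flag
  into a refusal.

Coefficients are never re-derived or extended in precision, and each
equation is pinned by three hand-computed fixture points (with the
arithmetic recorded next to the expected value) that must match to
0.01 kcal/d.

## Agreement statistics

For paired predictions and measurements the suite computes, per equation
and per stratum, always from raw pairs (never by aggregating aggregates):

* mean difference, predicted − measured (kcal/d);
* **accurate-prediction %**: share of subjects with
  0.90 ≤ predicted/measured ≤ 1.10. The band is closed at both ends by
  default (a prediction at exactly 90 % counts); `inclusive = FALSE` flips
  the convention, since sources rarely state it;
* **bias %**: mean of 100·(predicted − measured)/measured — the
  denominator is the reference measurement, per subject, averaged after;
* **RMSE**: √(mean((predicted − measured)²)), plain 1/n denominator. With
  that convention RMSE² = (mean difference)² + population variance of the
  differences, an identity the tests verify numerically;
* **Bland–Altman**: per-subject points (mean of the two values,
  difference), limits of agreement at mean ± 2·SD of the differences
  (sample SD, n − 1). The multiplier is 2 exactly — not 1.96 — matching
  the convention of the validation literature this package follows; it is
  an argument for users who prefer 1.96. For Gaussian differences the ±2 SD
  band should contain ≈ 95.4 % of points, which the tests check at n = 10⁴.

Stratified reports cover every equation × {overall, normal, overweight,
obese} × {both, male, female}; empty strata are emitted with `NA`
statistics and inapplicable predictions (missing body-composition fields)
are counted separately, never silently dropped.

## Equation development

`cmd_develop()` reproduces the standard derivation workflow:

1. univariate OLS of measured REE on each candidate (sex as male = 1,
   age, weight, height, BMI, FFM, FM), intercept always included, 95 % CIs
   from the t distribution, two-sided p-values;
2. screening: keep candidates with univariate p ≤ α (α = 0.05, inclusive);
3. backward stepwise: fit all screened candidates, repeatedly remove the
   single predictor with the largest p > α and refit, until all retained
   p ≤ α; an empty model is reported as intercept-only;
4. packaging: the final fit becomes a first-class equation spec that
   `predict_ree()` evaluates, reproducing the fitted values exactly — which
   is why resubstitution validation of a freshly fitted equation always
   shows a mean difference of 0 kcal/d (the OLS residual identity).

Bioimpedance decompositions make weight = FFM + FM *exactly*, so the
screened design matrix is rank-deficient. Before elimination begins the QR
rank is inspected and, within an aliased group, the predictor with the
weakest univariate R² is dropped (deterministically, and recorded in
`dropped_for_collinearity`). Any stepwise run on such data must implicitly
make some such choice; this one is explicit and reproducible.

There is no multiple-testing correction and no train/test split:
"internal validation" in this literature is resubstitution on the fitting
sample, and that is what is reproduced.

### A note on "FFM is the only variable left"

On cohorts where REE truly depends on FFM alone, every other screened
candidate has a zero partial effect given FFM, so each survives the final
refit with probability ≈ α. With four or five spurious candidates the
probability that backward elimination at α = 0.05 ends with FFM alone is
about 0.95⁴–0.95⁵ ≈ 0.77–0.81 — a large majority of runs, but not nearly
all. A validation expectation that the FFM-only outcome occurs in ≥ 90 % of
simulated cohorts is therefore inconsistent with the procedure's own
significance level; the package keeps the honest procedure rather than
tuning α to force the headline outcome, and the corresponding acceptance
test documents this and is expected to fail.

## Weight-status classification

BMI-for-age z-scores use the LMS transform
z = ((x/M)^L − 1)/(L·S) (the L = 0 limit is log(x/M)/S), with L, M, S
linearly interpolated in age within sex and no extrapolation outside the
table. Cut-offs follow the WHO-2007 school-age convention: obese above
+2 SD, overweight above +1 SD, thin below −2 SD, with boundary values going
to the lower category. The package deliberately does **not** bundle the
WHO reference as authoritative data: any LMS CSV can be supplied, and the
shipped `synthetic_lms_bmi.csv` is a smooth made-up curve set (clearly
labelled synthetic) that exists only so the classification code path runs
without a download.

## The synthetic cohort generator

No subject-level data accompany the validation study this package's test
targets come from, so the generator constructs cohorts with the published
statistical structure:

* marginals: age 11.8 ± 3.19 y, height 153.0 ± 17.11 cm, FFM
  41.6 ± 14.01 kg, FM 15.2 ± 9.58 kg; n = 275 with 148 boys;
* generative REE model: REE = 505.412 + 24.383·FFM + ε. The noise SD is
  not a free knob: the variance identity σ²_REE = (b·σ_FFM)² + σ²_ε with
  the published σ_REE = 423.69 forces σ_ε = 250.64 kcal/d
  (`derive_noise_sd()`), consistent with the published adjusted R² of
  0.649;
* correlations: since REE depends on the block only through FFM, each
  published univariate R² factors as r(REE, x) = ρ(FFM, x)·k with
  k = b·σ_FFM/σ_REE = 0.806. Back-solving gives ρ(FFM, age) = 0.760,
  ρ(FFM, height) = 0.927, and the weight-variance identity
  σ²_W = σ²_FFM + σ²_FM + 2ρσ_FFMσ_FM with σ_W = 20.71 gives
  ρ(FFM, FM) = 0.525. The remaining entries (age–height 0.85, age–FM 0.35,
  height–FM 0.40) are free, chosen once for plausibility and positive
  definiteness; a test perturbs them ±0.05 and confirms no calibrated
  target moves;
* weight = FFM + FM exactly (as a bioimpedance device reports it), BMI
  derived, sex an independent Bernoulli draw (the generative REE model is
  sex-free, so sex-linked body composition is not needed for any target
  and is available only via explicit configuration).

**What gaussian mode does not emulate.** The default draw is an
untruncated multivariate normal, because the recovery targets are moment
and R² recoveries and truncation would bias them. The price is honesty
about tails: at the default calibration ≈ 5–7 % of FM draws are negative
(reported by the generator as `fm_negative_fraction`) and roughly 0.3 % of
subjects get non-positive weight. Cohort physical-range validation is
therefore switched off for generator output, and group assignment uses an
unguarded BMI computation. A green moment-recovery test establishes that
the simulator reproduces the published second-order structure — it does
not establish that individual synthetic subjects are physiologically
plausible, nor anything about the real cohort's literature-equation error
structure, which is unidentifiable from published summary tables.
`mode = "realistic"` clips FM ≥ 0.5 kg, FFM ≥ 10 kg, height ≥ 100 cm and
resamples ages into [6, 18] for demonstration data; it is excluded from
all calibration tests by design.

BMI groups on synthetic cohorts are assigned by ranking age-adjusted BMI
(residual of BMI on age) and labelling the top 118 obese, next 52
overweight, remainder normal — plumbing that reproduces the published
stratum sizes for report shapes, with ties broken by subject id so row
order never matters. The labels feed no numeric target.

## Numerical and interface choices

* OLS is delegated to `stats::lm` behind the package's own fit container;
  tests verify it against an explicit normal-equations solve at 1e-8.
* Degenerate inputs: zero-variance predictors, empty cohorts, n < 2
  Bland–Altman, infeasible noise calibrations and non-positive-definite
  correlation matrices are refused with specific messages; an all-noise
  stepwise collapses to intercept-only rather than erroring.
* In the σ_ε → 0 limit the generative coefficients are recovered to
  machine precision, but p-values on null predictors become numerically
  meaningless (residual variance ~1e-24), so exact-recovery tests assert
  coefficients, not model membership.
* Presentation rounding (one decimal, as validation tables are printed) is
  applied only when writing report CSVs; all returned objects keep full
  precision.
* Reproducibility: a seed is mandatory for generation; identical
  configurations produce byte-identical cohort CSVs, and the CSV carries a
  provenance digest of the configuration in a `#` header line.

## Known limitations

* The 14 equations are transcribed from a single secondary tabulation;
  where that tabulation disagrees with an original publication (Müller sex
  coding, Kim's year/age range, Derumeaux-Burel's missing sex split) the
  tabulation wins, by design, and the discrepancy is documented above.
* The generator reproduces second-order structure only; per-BMI-group
  error distributions of the literature equations in any real cohort are
  out of reach of this calibration and no test claims otherwise.
* Adult equations (Harris–Benedict, Mifflin-St Jeor, Owen, Liu) and
  TEE/activity components are out of scope; the package predicts REE only.
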