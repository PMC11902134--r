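---
title: "Recalibrating BMI cut-offs against a body-fat reference: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recalibrating BMI cut-offs against a body-fat reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmirecal)
```

## The problem

Body-mass index is the workhorse surrogate for adiposity, but it cannot
separate fat from lean mass.  In athletes — who carry unusually high lean
mass at a given body size — the generic adult thresholds (overweight at
BMI ≥ 25 kg/m², obesity at ≥ 30) flag many subjects whose DXA-measured body
fat is entirely normal.  The standard remedy is to *recalibrate*: treat the
body-fat-percentage (BF%) classification as the reference, model the
BMI–BF% relation in the population of interest, and read new BMI thresholds
off the model at the BF% band edges.

`bmirecal` implements that workflow end to end:

1. classify each athlete by BF% (Gallagher bands for young adult males:
   overweight ≥ 21 %, obesity ≥ 26 %) and by BMI;
2. quantify agreement between the two systems — unweighted Cohen's κ,
   Pearson χ² without continuity correction, capture and false-positive
   rates, Landis–Koch verbal bands;
3. test the BMI–BF% relation for linearity (residual CUSUM with a
   Monte-Carlo null);
4. fit `ln BMI = c0 + c1·BF% + c2·BF%² + ε` by least squares, choosing the
   polynomial degree by adjusted R²;
5. validate the back-transformed predictions (slope-of-1 F test, paired
   *t*, Pearson *r*, CUSUM of measured on predicted);
6. derive recalibrated cut-offs `exp(poly(21))` and `exp(poly(26))` and
   re-assess agreement.

All thresholds are inclusive upward (a value exactly on a cut-off goes to
the higher category), matching the "≥" convention of both the WHO and the
Gallagher classifications.

## The model and its assumptions

The log transform serves two purposes: it stabilises the right-skewed BMI
distribution so that residuals are plausibly normal, and it guarantees
positive predictions under the back-transform `pBMI = exp(·)`.  The model
assumes

* a smooth, low-order polynomial dependence of `ln BMI` on BF% — no
  covariates (age, sport discipline) enter;
* homoscedastic normal errors on the log scale;
* that the BF% reference classification is itself correct (DXA measurement
  error is not modelled).

Degree selection needs care: plain R² is monotone in degree, so "pick the
best R²" alone would always choose the largest candidate.  Selection
therefore uses *adjusted* R² over degrees 1–3, while the plain R² of the
winner is what gets reported, as is conventional in this literature.

Back-transforming the conditional mean of a log-scale model understates the
raw-scale conditional mean by the factor `exp(σ²/2)` (here σ ≈ 0.06, a
bias of ~0.2 %, about 0.04 kg/m²).  No smearing correction is applied: the
derivation convention for cut-offs is the plain antilog, and the validation
suite shows the paired *t*-test does not detect the residual bias at this σ
and n.

## The CUSUM linearity test

The test statistic is the maximum absolute standardized cumulative sum of
the straight-line residuals taken in ascending-predictor order,
`max_k |Σ_{i≤k} r_(i)| / (sd(r)·√n)`.  Under a correct linear model the
path behaves like a Brownian bridge; curvature produces a systematic bow
and a large excursion.

Critical values come from a permutation null: null responses are rebuilt as
`fitted + permuted residuals`, the line is *refit* to each, and the
statistic recomputed; the threshold is the empirical `1 − α` quantile of
`n_sims` such draws (default 2000, seeded).  The refit is essential — OLS
residuals are orthogonal to the predictor, so their ordered path is tied
down more tightly than a raw permutation of them, and skipping the refit
collapses the type-I error to ~0 (we measured 0.000 without the refit,
0.047 with it, target 0.05).  All `n_sims` refits reduce to one QR
residualization of a permutation matrix, so the test is O(n·n_sims).

The statistic is invariant under affine rescaling of the response, and an
exactly linear input short-circuits to statistic 0 / no rejection.

## The synthetic cohort generator

No athlete-level DXA dataset is distributable with the package, so all
tests run against a seeded generator that emulates a reference population
of n = 622 young adult male athletes:

| quantity | default | rationale |
|---|---|---|
| BF% marginal | shifted gamma, origin 5 %, mean 13.1, SD 3.4, redrawn outside [5, 35] | BF% is bounded below and right-skewed in lean athletes; the shift to the physiological floor reproduces the observed ~2.5 % prevalence above the 21 % band where an unshifted gamma gives ~2.0 % |
| `ln_coeffs` | (3.257519, −0.021741, 0.001221) | solved (once, `scripts/calibration.R`) so the curve passes through BMI 24.1 at BF% 13.1, 28.2 at 21, 33.7 at 26 — the three anchors the recalibration is expected to reproduce |
| `resid_sd` | 0.057 ln-units | calibrated by `uniroot` so the mean refitted quadratic R² is 0.4447 |
| height | N(182.8, 9.2) cm | reference cohort moments |
| age | N(25.7, 4.7) y, redrawn below 20 | inclusion criterion age ≥ 20 |
| lean fraction | N(0.828, 0.032), truncated above at `1 − BF%/100` | lean + fat must fit inside body weight; the remainder is bone mineral |
| inclusion | BMI ≥ 20, redrawn | avoids a boundary spike that clipping would create |

The truncated lean-fraction draw uses the inverse-CDF method: at high BF%
the admissible upper tail is tiny and rejection sampling would effectively
never terminate.

**What a green test does and does not establish.**  The generator
reproduces the *relational* structure of real cohorts — the curvilinear
log-scale association, its R², the BF% moments and category mix, and the
qualitative failure of generic BMI cut-offs — so green tests establish that
the pipeline recovers generating truths from data with that structure.
They do not establish performance under features the generator omits:
sport-discipline mixtures, DXA measurement error, non-Caucasian or female
physiology, or age trends in adiposity.

**A documented impossibility.**  The published summary moments of the
reference cohort are mutually inconsistent with its published model: a
curve anchored at (13.1, 24.1), (21, 28.2), (26, 33.7) has slope only
≈ 0.25 kg/m² per BF point at the BF% mass, so with the residual SD
calibrated to R² = 0.4447 the implied BMI SD is ≈ 1.97 and the implied mean
≈ 24.5 — the reported 2.6 ± and 24.2 cannot be reached simultaneously with
the reported R² and anchor points (reaching SD 2.6 would force R² down to
≈ 0.22).  The package keeps the two prescribed calibrations (anchors and
R²) and leaves the BMI-moment check in the acceptance suite honestly red,
rather than quietly satisfying one target by breaking another.  The same
internal inconsistency is why the generating coefficients are solved from
the anchors instead of taken from the published equation, whose printed
coefficients evaluate to BMI ≈ 6.6 at BF% 21.

## Numerical choices

* **Rounding**: published-style outputs (cut-offs, rates) round half away
  from zero (`round_half_up()`), not banker's rounding; full precision is
  kept internally and in report provenance.
* **Exact fits**: zero-residual inputs short-circuit the CUSUM, the
  slope-of-1 test and the paired *t* (p = 1 on the null value, 0
  otherwise) instead of dividing rounding noise by rounding noise.
* **Degenerate tables**: κ returns `NA` with a warning when chance
  agreement is 1; `cross_tabulate()` drops categories absent from both
  classifiers before the χ² and reports `NA` when nothing is left to test;
  the standalone `chi_squared_independence()` keeps its hard error on empty
  margins.
* **Extrapolation**: predictions outside the fitted BF% range warn, and
  beyond a 2-point guard warn more loudly, but never error — the obesity
  band (26 %) legitimately exceeds the observed BF% maximum in a
  non-negligible fraction of cohorts of this size, and the derivation must
  still proceed, as it does in practice.
* **Quadratic inversion** (`bmi_to_bf()`): the root inside the fitted range
  is used; when both roots qualify, the one on the rising limb
  (derivative > 0) is chosen — adiposity cut-offs live where BMI increases
  with BF%.
* **Ties in degree selection** go to the lower degree.

## Worked example

```{r example, eval = FALSE}
coh <- generate_cohort(cohort_config(seed = 42))
rep <- run_full_analysis(coh, seed = 42)
rep$cutoffs
rep$contingency_incumbent$kappa
rep$contingency_derived$kappa
```

On default cohorts the incumbent WHO cut-offs yield κ around 0.07–0.17
against the BF% reference while the recalibrated cut-offs yield κ around
0.45–0.6; the improvement holds on every seed we tested (100/100 in the
acceptance suite).

## Known limitations

* Single-population generator: male, young adult, one ethnicity — by
  construction, mirroring the reference cohort's own scope.
* The permutation-null CUSUM is asymptotically calibrated but slightly
  discrete at small `n_sims`; use ≥ 400 draws for decisions at α = 0.05.
* `bmi_to_bf()` is implemented for degrees ≤ 2; cubic fits (rarely
  selected) cannot be inverted analytically here.
* Kappa confidence intervals, weighted kappa, and ROC-style cut-off
  optimisation are out of scope; the derivation method is threshold
  substitution only.
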