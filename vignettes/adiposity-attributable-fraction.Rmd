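---
title: "Methods: adiposity scales, agreement, and attributable fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adiposity scales, agreement, and attributable fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipofrac)
```

## The problem

BMI is the universal screening measure for obesity, but at a fixed BMI a
woman carries roughly ten percentage points more body fat than a man, and
an older adult more than a younger one. Any analysis that classifies
obesity by a single BMI cut-off therefore misclassifies systematically by
sex and age, and that misclassification propagates into everything built
on the classification: prevalence estimates, odds ratios per category, and
ultimately the population attributable fraction (AFp) — the share of a
disease's case load that would disappear if everyone carried the
reference-level exposure. This package implements the complete comparison
of BMI against the CUN-BAE percent-body-fat estimator as exposure scales
for hypertension (AHT) and type 2 diabetes (DM).

## The adiposity model

`cun_bae(age, sex, bmi)` evaluates the nine-term polynomial (sex coded
0 = male, 1 = female) exactly, with no internal rounding:

$$\%BF = -44.988 + 0.503\,a + 10.689\,s + 3.172\,b - 0.026\,b^2
 + 0.181\,bs - 0.02\,ab - 0.005\,b^2 s + 0.00021\,ab^2$$

Useful closed forms that the tests exploit:

* the female–male gap at fixed $(a, b)$ is $10.689 + 0.181 b - 0.005 b^2$,
  age-free and positive for $b \le 60$;
* $\partial \%BF/\partial a = 0.503 - 0.02 b + 0.00021 b^2 > 0$ for all
  $b \le 60$, so %BF always rises with age;
* $\partial \%BF/\partial b = 3.172 + 0.181 s - b(0.052 + 0.01 s
  - 0.00042 a) - 0.02 a$. For men this is positive everywhere on the
  validation grid (age 18–100, BMI 18.5–60). **For women it changes sign**
  near BMI 55 at age 18 (boundary $b^* = (3.353 - 0.02a)/(0.062 -
  0.00042a)$): the published equation is not monotone in BMI in that
  extreme corner. We treat this as a property of the equation, verify the
  boundary in the test suite, and do not "correct" it.

### Categories and cut-offs

Both schemes use five ordered categories with C1 the reference. BMI:
18.5–24.9, 25–29.9, 30–34.9, 35–39.9, ≥ 40 kg/m²; obesity is BMI ≥ 30 for
both sexes. CUN-BAE: 5 %BF increments ending at ≥ 35 % for men
(≤ 19.9 / 20–24.9 / 25–29.9 / 30–34.9 / ≥ 35) and ≥ 45 % for women
(≤ 29.9 … ≥ 45); obesity is C3 or above, i.e. ≥ 25 %BF in men and
≥ 35 %BF in women.

Design choices here:

* **Half-open bounds** `[lower, upper)`. Published band labels like
  "25–29.9" leave values such as 29.95 unclassifiable; reading them as
  [25, 30) makes classification total and exclusive, and places the
  boundary value 30.0 in the obese band, consistent with "30 kg/m² or
  more".
* **Women's obesity threshold is 35 %BF.** A table footnote in the source
  material says 25 % for women, contradicting its own methods text; 35 %
  is the standard female cut-off and is what reproduces the published
  category structure, so the footnote is treated as a typo.
* There is no lower bound on %BF: implausibly low scores simply land
  in C1.

## Cohort handling

`load_cohort()` reads comma-separated, UTF-8, header-row, decimal-point
files (column names remappable through a JSON schema file or list — JSON
rather than YAML because no R YAML parser is available in the supported
environment). Inclusion rules: age ≥ 18 (the source criterion "over
eighteen" is ambiguous; we take it inclusive since the cohort it describes
has mean age ~50, and expose `age_inclusive = FALSE` for the strict
reading) and BMI ≥ 18.5 kg/m². BMI is derived from weight/height when not
given; when both are present they must agree within 0.1 kg/m². A pregnancy
column is filtered only if mapped. Every dropped record lands once in the
exclusion log with a machine-readable reason; missing covariates are kept
at load time and handled by complete-case deletion in the regression step,
mirroring standard practice.

## Agreement statistics

`agreement_table()` reports, per stratum (overall, each sex, each sex ×
age band with the band edge at 50 years, configurable): n, Pearson R²
between BMI and %BF, obesity prevalence under both schemes, percent
agreement, and Cohen's κ on the **binary** obese/not-obese flags (the
published comparison is about obesity diagnosis, not the five levels).
The κ confidence interval is $\hat\kappa \pm 1.96\,SE$ with the
Fleiss–Cohen–Everitt asymptotic standard error; the source material asks
only for an "index of coincidence at 95 %", which we interpret as a 95 %
CI — the estimator is frozen in a test against an independent
implementation (statsmodels) to machine precision.

## Risk models

`crude_odds_ratio()` is the closed-form 2×2 odds ratio with the Woolf
(log-odds) interval $\exp(\log OR \pm 1.96\sqrt{\sum 1/\text{cell}})$; a
zero cell yields `NA` unless the 0.5 continuity correction is explicitly
switched on. `fit_adjusted_or()` fits a binomial GLM (IRLS, relative
deviance tolerance $10^{-8}$, max 100 iterations, non-convergence is an
error) of the outcome on category indicators against C1 plus covariates:
education, marital status, tobacco, alcohol as unordered factors with the
most frequent level as reference — the source never enumerates the levels,
so the synthetic generator defines them (3/4/3/3 levels) — and age as a
continuous linear term for BMI models only, because CUN-BAE already
incorporates age. Wald 95 % intervals on the coefficients give the aOR
CIs.

Sparse categories: a category with fewer than 5 cases or 5 non-cases is
flagged non-estimable (reported, `estimable = FALSE`); a category with
zero cases or non-cases is separated and reported `NA`. For attributable
fractions, `collapse_sparse_categories()` merges any non-reference
category with fewer than `min_cases = 6` cases into its lower neighbour
(N and n summed, merges recorded); `afp_from_summary()` additionally
merges rows whose published OR is simply absent. This is one defensible
treatment of the published men/DM/BMI top category (5 cases, no OR); the
original analysis does not say what it did, and our collapse reproduces
its AFp to 0.1 points.

## Attributable fraction

`afp_miettinen()` implements the case-load formulation
$AF_p = (1 - \sum_l pd_l/OR_l) \times 100$ where $pd_l$ is the fraction
of *cases* at exposure level $l$, including the reference level with
OR ≡ 1. This interpretation of $pd$ — rather than population shares —
exactly reproduces all four published %BF-based fractions (74.03, 89.14,
71.54, 65.19) from the published case counts and adjusted ORs, which we
take as confirmation. With rounded published aORs the BMI-based AHT
fractions reproduce to ±0.1 points (36.93 vs 37.00; 45.37 vs 45.32). Two
published values are *not* recoverable from their own printed inputs and
are documented rather than matched: the women/DM/BMI fraction (prints
40.38, recomputes to 41.86 from the rounded aORs) and one crude OR cell
(men/DM/BMI 35–39.9 prints 2.97, consistent with its own CI but not with
its printed counts, which give 3.67). Negative fractions (protective
exposure) are returned with a warning, never clamped; no CI for AFp is
offered because none is published and a bootstrap is deliberately out of
scope.

## The synthetic cohort

`generate_cohort()` emulates the study population: 3888 subjects,
2033/3888 male; age truncated-normal on [18, 95] with means 50.7 (men) /
49.6 (women); BMI truncated-normal on [18.5, ∞) with means 26.9 / 26.3.
Published material gives no spreads, so the defaults (SD 15 y and
4.5 kg/m²) are fixed once as a realistic adult-cohort dispersion. Because
the stated means are *observed* means, the generator moment-matches the
truncated-normal location parameter (truncation at 18.5 would otherwise
inflate mean BMI by ~0.3 kg/m²). Age and BMI are drawn independently by
default (no joint distribution is published); a Gaussian-copula
`age_bmi_correlation` knob exists. Drawing order is fixed and part of the
determinism contract: sex, age, BMI, height, covariates (education,
marital, tobacco, alcohol), outcomes (AHT, DM), all from one seeded
generator.

Outcomes are Bernoulli draws from
$\text{logit}(p) = \beta_0 + \beta_1 \cdot \%BF$ with defaults
$\beta_1 = 0.13$ (AHT) and $0.12$ (DM) — the log-odds gradient implied by
the published prevalence span across %BF categories — and intercepts
−5.41 / −6.17 calibrated once so that overall prevalence is ≈ 29 % and
≈ 13 % (the published case loads). Generating disease from %BF rather
than BMI makes the %BF scheme the "true" exposure **by construction**:
the package's directional findings on synthetic data (stronger gradients
and higher AFp under CUN-BAE, stratified R² ≫ overall R²) are a modelling
choice that mirrors the study's direction, not evidence for it. Covariate
effects default to zero so that parameter-recovery tests are clean; an
alternative outcome mode injects known log-ORs on the category indicators
(`category_log_or`) for coverage checks against ground truth.

### What a green test does and does not establish

The generator reproduces the study's *structure* (demography, prevalence,
sex/age-driven divergence of the two scales), not its data. Exact
published statistics that depend on the unavailable individual records —
R² = 0.48 overall, κ = 28.7 %, the per-stratum R² — are explicitly
non-targets; the suite checks their directional signatures instead
(overall R² below every stratified R², %BF prevalence ≈ 3× BMI
prevalence, %BF AFp above BMI AFp). Two further statistical readings are
deliberate: interval-coverage of injected ORs is assessed per category
across 100 replicates (each interval is nominally 95 %, so ≥ 90 % per
category; joint coverage of four correlated intervals at once would be a
different, stricter statistic), and the null-effect AFp check is on the
mean across replicates, because a single fitted AFp at n = 20 000 carries
a sampling SD of several points — the reference-category OR noise enters
every $pd_l/OR_l$ term coherently.

## Numerical and degenerate-input policy

* No rounding inside any scoring or estimation path; 2-decimal rounding
  only at report time.
* Pearson R² requires ≥ 3 complete pairs and non-constant series; κ is an
  error when expected agreement is 1; the crude OR is `NA` on zero cells
  (correction opt-in); a constant outcome or non-convergent IRLS is an
  error, not a silent result.
* Category classification is total on each scheme's domain; BMI < 18.5 is
  a domain error by design (the loader guarantees it upstream).
* All randomness flows from the single config seed; identical seeds give
  byte-identical cohorts.

## Known limitations

* The CUN-BAE equation is calibrated for white adults; no recalibration
  for other populations is attempted, and inputs outside age 18–100 or
  BMI < 18.5 only warn.
* The women's-BMI non-monotonicity corner (BMI ≳ 55 at young ages) is
  inherited from the published equation.
* Adjusted-OR reproduction of the published tables is impossible without
  the individual data; only the summary-level AFp pathway is exactly
  reproducible, and two published cells are internally inconsistent as
  described above.
* κ is computed on binary obesity flags; a weighted κ on the five-level
  categories would need a weighting convention that the comparison never
  defines.
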