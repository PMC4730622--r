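# adipofrac

Tools for asking how much of the burden of hypertension and type 2 diabetes
is attributable to excess body fat — and how much the answer changes with the
yardstick used to measure "excess".

The body mass index (BMI = kg/m²) ignores the strong dependence of adiposity
on sex and age. The CUN-BAE estimator (Clínica Universidad de Navarra – Body
Adiposity Estimator) predicts percent body fat (%BF) in white adults from
BMI, sex (0 = male, 1 = female) and age:

```
%BF = −44.988 + 0.503·age + 10.689·sex + 3.172·BMI − 0.026·BMI²
      + 0.181·BMI·sex − 0.02·BMI·age − 0.005·BMI²·sex + 0.00021·BMI²·age
```

With obesity defined as BMI ≥ 30 kg/m² versus %BF ≥ 25 % (men) / ≥ 35 %
(women), the two scales disagree badly: a given cohort can be ~20 % obese by
BMI and ~60–70 % obese by %BF. `adipofrac` quantifies the consequences along
the whole chain:

* **Scoring and classification** — `cun_bae()`, `classify_bmi()`,
  `classify_cunbae()`, `score_cohort()`; five half-open categories per
  scheme, C1 the normal-weight reference.
* **Agreement** — `agreement_table()`: Pearson R² between BMI and %BF,
  obesity prevalence under each scheme, percent agreement, and Cohen's κ
  with its asymptotic (Fleiss–Cohen–Everitt) 95 % CI, stratified by sex and
  age band (< 50 / ≥ 50).
* **Risk** — `risk_table()` / `crude_odds_ratio()` / `fit_adjusted_or()`:
  per-category crude ORs with Woolf CIs, and covariate-adjusted ORs from a
  logistic regression (education, marital status, tobacco, alcohol; plus
  age for BMI models only, since CUN-BAE already encodes it).
* **Attributable fraction** — `afp_miettinen()`: Miettinen's case-load
  formula, AFp = (1 − Σₗ pdₗ/ORₗ) × 100, where pdₗ is the share of all
  cases at exposure level *l*. `afp_from_summary()` runs it from
  summary-level tables (category, cases, aOR); eight such tables from a
  cross-sectional study of 3888 Spanish adults are bundled under
  `inst/extdata/` (`summary_tables()`, `summary_fixture_path()`).
* **Simulation** — `generate_cohort()` / `cohort_config()`: a seeded,
  fully deterministic generator of two-sex adult cohorts (truncated-normal
  age and BMI, moment-matched to target means; logistic outcome models on
  %BF or on known category effects) so every stage is testable without
  restricted data.

A thin command-line wrapper over these functions is at
`inst/cli/adipofrac.R` (`simulate`, `score`, `agree`, `risk`, `afp`).

## Worked example

```r
library(adipofrac)

cun_bae(40, "male", 25)
#> [1] 23.432        # a 40-year-old man at BMI 25 carries ~23.4% body fat

scored <- score_cohort(generate_cohort(cohort_config(seed = 1)))
agreement_table(scored)[1:3, c("sex", "age_band", "n", "r_squared",
                               "pct_obese_bmi", "pct_obese_cunbae", "kappa")]
#>    sex age_band    n r_squared pct_obese_bmi pct_obese_cunbae     kappa
#> 1  all      all 3888 0.3761350      20.52469         68.67284 0.2107864
#> 2 male      all 2074 0.9000496      22.46866         65.52555 0.2645980
#> 3 male      <50 1010 0.9670377      22.27723         55.44554 0.3744106
```

Pooling sexes, BMI explains only ~38 % of the %BF variance and κ ≈ 0.21:
the two schemes barely agree on who is obese, and %BF-based obesity is
three times more prevalent. Within a sex (and age band) the correlation is
excellent — the disagreement *is* the sex/age dependence.

```r
rt <- risk_table(scored, "hypertension", "male", "cunbae")
as.data.frame(rt)[, c("label", "N", "n", "prevalence", "cOR", "aOR")]
#>     label   N   n prevalence   cOR   aOR
#> 1  <=19.9 251   7       2.79  1.00  1.00
#> 2 20-24.9 464  40       8.62  3.29  3.27
#> 3 25-29.9 700 122      17.43  7.36  7.42
#> 4 30-34.9 470 116      24.68 11.42 11.56
#> 5    >=35 189  66      34.92 18.70 18.68

afp_from_risk_table(rt)
#> Population attributable fraction: 85.97% (fitted, 5 categories)
```

Hypertension risk rises steeply across the %BF categories (this synthetic
cohort generates disease from %BF, so the gradient is built in), and most
of the male case load sits in high-%BF categories: ~86 % of cases are
attributable to above-reference adiposity on this scale.

Summary-level mode reproduces published fractions directly from a
category/cases/aOR table:

```r
afp_from_summary(summary_fixture_path("men_aht_cunbae"))
#> Population attributable fraction: 74.03% (summary-table, 5 categories)
```

## Acceptance script

`scripts/acceptance.R` exercises the full pipeline against the installed
package: it generates the default synthetic cohort from `--seed`, prints
the stratified agreement table, the obesity prevalence ratio, and fitted
attributable fractions for every outcome × sex × scheme, then recomputes
the AFp of each bundled summary table, and writes the JSON results object
to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
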