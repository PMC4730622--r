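test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(n_total = 500, seed = 42)
  a <- generate_cohort(cfg); b <- generate_cohort(cfg)
  expect_identical(subjects(a), subjects(b))
  c2 <- generate_cohort(cohort_config(n_total = 500, seed = 43))
  expect_false(identical(subjects(a), subjects(c2)))
})

test_that("defaults hit the target demography within sampling error", {
  d <- subjects(default_cohort_seed1())
  men <- d[d$sex == "male", ]; women <- d[d$sex == "female", ]
  # ~2 standard errors of a mean of ~2000 draws
  expect_equal(mean(men$bmi), 26.9, tolerance = 0.3 / 26.9)
  expect_equal(mean(women$bmi), 26.3, tolerance = 0.3 / 26.3)
  expect_equal(mean(men$age), 50.7, tolerance = 1 / 50.7)
  expect_equal(mean(women$age), 49.6, tolerance = 1 / 49.6)
  expect_equal(nrow(d), 3888)
  expect_equal(nrow(men) / nrow(d), 2033 / 3888, tolerance = 0.05)
  # calibrated outcome models: ~29% hypertension, ~13% diabetes
  expect_equal(mean(d$hypertension), 0.29, tolerance = 0.10)
  expect_equal(mean(d$diabetes), 0.13, tolerance = 0.15)
  expect_true(all(d$age >= 18 & d$age <= 95))
  expect_true(all(d$bmi >= 18.5))
})

test_that("generated cohorts pass loading validation with zero exclusions", {
  co <- generate_cohort(cohort_config(n_total = 400, seed = 9))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  reloaded <- load_cohort(path)
  expect_equal(nrow(exclusions(reloaded)), 0)
  expect_equal(nrow(subjects(reloaded)), 400)
  expect_equal(subjects(reloaded)$bmi, subjects(co)$bmi, tolerance = 1e-6)
})

test_that("invalid configurations are rejected with named offences", {
  expect_error(cohort_config(n_total = -1), "n_total")
  expect_error(cohort_config(male_fraction = 1.2), "male_fraction")
  expect_error(cohort_config(age_sd = 0), "age_sd")
  expect_error(cohort_config(bmi_range = c(17, 60)), "18.5")
  expect_error(cohort_config(covariate_spec = list(
    education = c(a = 0.5, b = 0.4))), "summing to 1")
  err <- tryCatch(cohort_config(n_total = 0, bmi_sd = -1),
                  error = conditionMessage)
  expect_match(err, "n_total"); expect_match(err, "bmi_sd")
})

test_that("a null adiposity effect yields flat odds ratios and near-zero AFp", {
  cfg <- cohort_config(
    n_total = 6000, seed = 4,
    outcome_models = list(
      hypertension = list(intercept = qlogis(0.29), slope_bf = 0),
      diabetes = list(intercept = qlogis(0.13), slope_bf = 0)))
  sc <- score_cohort(generate_cohort(cfg))
  fit <- fit_adjusted_or(sc, "hypertension", "male", "cunbae",
                         covariates = character(0))
  est <- fit[fit$estimable & fit$category != "C1", ]
  # nominal 95% intervals: allow at most one chance exclusion of the null
  expect_gte(sum(est$aOR_lo < 1 & 1 < est$aOR_hi), nrow(est) - 1)
  afp <- afp_from_risk_table(fit, min_cases = 6)
  expect_lt(abs(afp$afp), 10)
})

test_that("an injected monotone %BF effect produces a monotone prevalence gradient", {
  # majority vote over 20 seeds: observed hypertension prevalence should be
  # nondecreasing across the %BF categories present in bulk (C1..C5 pooled sexes)
  votes <- 0
  for (s in 1:20) {
    sc <- score_cohort(generate_cohort(cohort_config(n_total = 2000, seed = s)))
    d <- subjects(sc)
    prev <- tapply(d$hypertension, d$cunbae_category, mean)
    prev <- prev[!is.na(prev)]
    votes <- votes + all(diff(prev) >= 0)
  }
  expect_gte(votes, 11)
})

test_that("age-BMI correlation knob induces the requested dependence", {
  d0 <- subjects(generate_cohort(cohort_config(n_total = 4000, seed = 2)))
  d5 <- subjects(generate_cohort(cohort_config(n_total = 4000, seed = 2,
                                               age_bmi_correlation = 0.5)))
  expect_lt(abs(cor(d0$age, d0$bmi)), 0.08)
  expect_gt(cor(d5$age, d5$bmi), 0.35)
})

test_that("fixture writer reproduces the bundled CSVs and conservation holds", {
  dir <- tempfile(); paths <- generate_summary_fixtures(dir)
  expect_length(paths, 8)
  for (p in paths) {
    bundled <- summary_fixture_path(sub("\\.csv$", "", basename(p)))
    expect_identical(readLines(p), readLines(bundled))
  }
  tabs <- summary_tables()
  expect_equal(sum(tabs$men_aht_bmi$n), sum(tabs$men_aht_cunbae$n))
  expect_equal(sum(tabs$women_dm_bmi$n), sum(tabs$women_dm_cunbae$n))
})

test_that("category-effect outcome mode encodes the requested true ORs", {
  true_lor <- log(c(2, 4, 8, 16))
  cfg <- cohort_config(
    n_total = 20000, seed = 77,
    outcome_models = list(
      hypertension = list(intercept = qlogis(0.08),
                          category_log_or = true_lor,
                          category_scheme = "cunbae"),
      diabetes = list(intercept = qlogis(0.05), slope_bf = 0)))
  sc <- score_cohort(generate_cohort(cfg))
  fit <- fit_adjusted_or(sc, "hypertension", "male", "cunbae",
                         covariates = character(0))
  est <- fit[-1, ]
  expect_true(all(est$estimable))
  # fitted ORs within ~3 standard errors of the injected ones (log scale)
  expect_lt(max(abs(log(est$aOR) - true_lor)), 0.45)
})
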