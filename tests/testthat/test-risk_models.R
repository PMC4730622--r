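test_that("category tables keep all five rows, reference first", {
  d <- make_scored_df(sex = "male", age = 40, bmi = rep(22, 10),
                      hypertension = rep(c(TRUE, FALSE), c(2, 8)))
  tab <- build_category_table(d, "hypertension", "male", "bmi")
  expect_equal(tab$category, paste0("C", 1:5))
  expect_equal(tab$N, c(10, 0, 0, 0, 0))
  expect_equal(tab$n, c(2, 0, 0, 0, 0))
  expect_equal(tab$prevalence[1], 20)
  expect_true(all(is.na(tab$prevalence[-1])))  # empty rows flagged as NA
})

test_that("case totals are conserved across schemes (same people, two partitions)", {
  sc <- default_cohort_seed1()
  for (sx in c("male", "female")) {
    for (oc in c("hypertension", "diabetes")) {
      t_bmi <- build_category_table(sc, oc, sx, "bmi")
      t_cun <- build_category_table(sc, oc, sx, "cunbae")
      expect_equal(sum(t_bmi$n), sum(t_cun$n))
      expect_equal(sum(t_bmi$N), sum(t_cun$N))
    }
  }
})

test_that("crude odds ratio and Woolf CI match the closed forms", {
  est <- crude_odds_ratio(c(849, 254), c(749, 152))
  expect_equal(est$or, (254 / 595) / (152 / 597), tolerance = 1e-12)
  expect_equal(round(est$or, 2), 1.68)
  lse <- sqrt(1 / 254 + 1 / 595 + 1 / 152 + 1 / 597)
  expect_equal(est$ci, exp(log(est$or) + c(-1, 1) * qnorm(0.975) * lse),
               tolerance = 1e-12)
  expect_equal(round(crude_odds_ratio(c(297, 162), c(303, 9))$or, 2), 39.20)
  expect_equal(crude_odds_ratio(c(100, 30), c(100, 30))$or, 1.0)
})

test_that("zero cells yield NA unless the continuity correction is on", {
  plain <- crude_odds_ratio(c(50, 0), c(50, 10))
  expect_true(is.na(plain$or))
  corr <- crude_odds_ratio(c(50, 0), c(50, 10), correction = TRUE)
  expect_equal(corr$or, (0.5 / 50.5) / (10.5 / 40.5), tolerance = 1e-12)
  expect_error(crude_odds_ratio(c(10, 12), c(10, 2)), "exceed")
})

test_that("logistic regression on a bare binary exposure equals the crude OR", {
  set.seed(5)
  for (i in 1:10) {
    n <- 400
    d <- make_scored_df(
      sex = "male", age = 40,
      bmi = sample(c(22, 32), n, TRUE),  # C1 vs C3
      hypertension = FALSE)
    p <- ifelse(d$bmi > 30, 0.4, 0.15)
    d$hypertension <- runif(n) < p
    tab <- build_category_table(d, "hypertension", "male", "bmi")
    tab <- tab[tab$N > 0, ]
    closed <- crude_odds_ratio(c(tab$N[2], tab$n[2]), c(tab$N[1], tab$n[1]))
    fit <- fit_adjusted_or(d, "hypertension", "male", "bmi",
                           covariates = character(0))
    expect_equal(fit$aOR[fit$category == "C3"], closed$or, tolerance = 1e-6)
  }
})

test_that("adjusted fit applies the scheme-dependent covariate rule", {
  sc <- default_cohort_seed1()
  fit_bmi <- fit_adjusted_or(sc, "hypertension", "male", "bmi")
  fit_cun <- fit_adjusted_or(sc, "hypertension", "male", "cunbae")
  expect_true("age" %in% attr(fit_bmi, "covariates"))
  expect_false("age" %in% attr(fit_cun, "covariates"))  # %BF already has age
  expect_setequal(setdiff(attr(fit_bmi, "covariates"), "age"),
                  c("education", "marital", "tobacco", "alcohol"))
  expect_equal(fit_cun$aOR[1], 1)
  expect_true(all(fit_cun$aOR_lo <= fit_cun$aOR & fit_cun$aOR <= fit_cun$aOR_hi,
                  na.rm = TRUE))
})

test_that("degenerate and sparse situations are reported, not silently fit", {
  d <- make_scored_df(sex = "male", age = 40, bmi = runif(50, 20, 34),
                      hypertension = FALSE)
  expect_error(fit_adjusted_or(d, "hypertension", "male", "bmi",
                               covariates = character(0)), "constant")
  # a category with zero cases is non-estimable (separated indicator)
  d2 <- make_scored_df(sex = "male", age = 40,
                       bmi = c(rep(22, 100), rep(32, 50), rep(41, 8)),
                       hypertension = c(rep(c(TRUE, FALSE), 50),
                                        rep(c(TRUE, FALSE), 25),
                                        rep(FALSE, 8)))
  fit <- suppressWarnings(
    fit_adjusted_or(d2, "hypertension", "male", "bmi",
                    covariates = character(0)))
  expect_true(is.na(fit$aOR[fit$category == "C5"]))
  expect_false(fit$estimable[fit$category == "C5"])
})

test_that("Woolf intervals attain nominal coverage in simulation", {
  # 2x2 tables with known OR = 2 (p_ref = 0.2, p_exp = 1/3), N = 500+500
  set.seed(31)
  true_or <- 2
  hits <- 0; reps <- 1000
  for (i in seq_len(reps)) {
    n_r <- rbinom(1, 500, 0.2); n_e <- rbinom(1, 500, 1 / 3)
    if (n_r %in% c(0, 500) || n_e %in% c(0, 500)) next
    ci <- crude_odds_ratio(c(500, n_e), c(500, n_r))$ci
    hits <- hits + (ci[1] <= true_or && true_or <= ci[2])
  }
  expect_gte(hits / reps, 0.92)
  expect_lte(hits / reps, 0.98)
})
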