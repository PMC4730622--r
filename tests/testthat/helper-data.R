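# shared fixture builders (in-memory; no files shipped)

# minimal valid cohort CSV rows; `...` overrides columns, n rows recycled
make_cohort_rows <- function(n = 10, ...) {
  base <- data.frame(
    id = sprintf("P%02d", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    age = seq(30, 70, length.out = n),
    height = 1.70, weight = 75,
    bmi = round(75 / 1.70^2, 2),
    hypertension = rep(c(0, 1), length.out = n),
    diabetes = 0,
    education = "primary", marital = "married",
    tobacco = "never", alcohol = "none",
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- rep(over[[nm]], length.out = n)
  base
}

write_cohort_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

# a pre-scored subject table, bypassing load/score (for table-level tests)
make_scored_df <- function(sex, age, bmi, hypertension = FALSE,
                           diabetes = FALSE) {
  n <- max(length(sex), length(age), length(bmi))
  d <- data.frame(sex = rep_len(sex, n), age = rep_len(age, n),
                  bmi = rep_len(bmi, n),
                  hypertension = rep_len(hypertension, n),
                  diabetes = rep_len(diabetes, n),
                  stringsAsFactors = FALSE)
  subjects(score_cohort(d))
}

default_cohort_seed1 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- score_cohort(generate_cohort(cohort_config(seed = 1)))
    cache
  }
})
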