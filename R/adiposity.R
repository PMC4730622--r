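#' CUN-BAE percent body fat
#'
#' Evaluates the CUN-BAE (Clinica Universidad de Navarra - Body Adiposity
#' Estimator) equation, a nine-term polynomial in age, sex and BMI that
#' estimates percent body fat in white adults:
#'
#' \deqn{\%BF = -44.988 + 0.503\,age + 10.689\,sex + 3.172\,BMI
#'   - 0.026\,BMI^2 + 0.181\,BMI \cdot sex - 0.02\,BMI \cdot age
#'   - 0.005\,BMI^2 \cdot sex + 0.00021\,BMI^2 \cdot age}
#'
#' with sex coded 0 for men and 1 for women. No rounding is applied; round
#' only at report time.
#'
#' @param age Age in years. Values outside \[18, 100\] trigger a warning
#'   (the equation was calibrated on adults).
#' @param sex `"male"`/`"female"` (or a 0/1 numeric code, 1 = female).
#' @param bmi Body mass index in kg/m^2. Values below 18.5 trigger a warning.
#' @return Numeric vector of percent body fat.
#' @examples
#' cun_bae(40, "male", 25)    # 23.43
#' cun_bae(40, "female", 25)  # 35.52
#' @export
cun_bae <- function(age, sex, bmi) {
  s <- sex_code(sex)
  if (!is.numeric(age) || !is.numeric(bmi)) {
    stop("`age` and `bmi` must be numeric", call. = FALSE)
  }
  n <- max(length(age), length(s), length(bmi))
  age <- rep_len(age, n); s <- rep_len(s, n); bmi <- rep_len(bmi, n)
  if (any(!is.finite(age)) || any(!is.finite(bmi)) || any(!is.finite(s))) {
    stop("non-finite age, sex or bmi", call. = FALSE)
  }
  if (any(age < 18 | age > 100)) {
    warning("age outside [18, 100]: CUN-BAE was calibrated on adults",
            call. = FALSE)
  }
  if (any(bmi < 18.5)) {
    warning("bmi below 18.5 kg/m^2 is outside the intended range",
            call. = FALSE)
  }
  -44.988 + 0.503 * age + 10.689 * s + 3.172 * bmi - 0.026 * bmi^2 +
    0.181 * bmi * s - 0.02 * bmi * age - 0.005 * bmi^2 * s +
    0.00021 * bmi^2 * age
}

# 0 = male, 1 = female; accepts character, factor, logical or 0/1 numeric
sex_code <- function(sex) {
  if (is.factor(sex)) sex <- as.character(sex)
  if (is.character(sex)) {
    code <- c(male = 0, m = 0, female = 1, f = 1, woman = 1, man = 0,
              `0` = 0, `1` = 1)[tolower(trimws(sex))]
    if (any(is.na(code) & !is.na(sex))) {
      stop("unrecognised sex value(s): ",
           paste(unique(sex[is.na(code)]), collapse = ", "), call. = FALSE)
    }
    unname(code)
  } else if (is.numeric(sex) || is.logical(sex)) {
    sex <- as.numeric(sex)
    if (any(!sex %in% c(0, 1) & !is.na(sex))) {
      stop("numeric sex must be coded 0 (male) / 1 (female)", call. = FALSE)
    }
    sex
  } else {
    stop("cannot interpret `sex`", call. = FALSE)
  }
}

.category_labels <- c("C1", "C2", "C3", "C4", "C5")

#' Adiposity category definitions
#'
#' The five ordered adiposity bands used throughout: BMI bands shared by both
#' sexes (18.5-24.9, 25-29.9, 30-34.9, 35-39.9, >= 40 kg/m^2) and
#' sex-specific percent-body-fat bands in 5% increments (men: <= 19.9 up to
#' >= 35; women: <= 29.9 up to >= 45). All bands are half-open
#' `[lower, upper)`, so e.g. a BMI of exactly 30 is obese. C1 is always the
#' reference category.
#'
#' @param scheme `"bmi"` or `"cunbae"`.
#' @param sex Required for `"cunbae"` (cut-offs differ by sex); ignored for
#'   `"bmi"`.
#' @return A data.frame with columns `category`, `label` (display label),
#'   `lower`, `upper`, and `obese`.
#' @export
adiposity_categories <- function(scheme = c("bmi", "cunbae"), sex = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "bmi") {
    lower <- c(18.5, 25, 30, 35, 40)
    label <- c("18.5-24.9", "25-29.9", "30-34.9", "35-39.9", ">=40")
    obese <- lower >= 30
  } else {
    if (is.null(sex)) stop("`sex` is required for the cunbae scheme",
                           call. = FALSE)
    s <- sex_code(sex)[1]
    lower <- if (s == 0) c(-Inf, 20, 25, 30, 35) else c(-Inf, 30, 35, 40, 45)
    label <- if (s == 0) {
      c("<=19.9", "20-24.9", "25-29.9", "30-34.9", ">=35")
    } else {
      c("<=29.9", "30-34.9", "35-39.9", "40-44.9", ">=45")
    }
    obese <- seq_along(lower) >= 3  # >=25% men, >=35% women
  }
  data.frame(category = .category_labels, label = label,
             lower = lower, upper = c(lower[-1], Inf), obese = obese,
             stringsAsFactors = FALSE)
}

#' Classify BMI into WHO bands
#'
#' Bands `[18.5,25) [25,30) [30,35) [35,40) [40,Inf)`, labelled C1..C5;
#' obesity is BMI >= 30 kg/m^2 for both sexes.
#'
#' @param bmi BMI in kg/m^2; values below 18.5 are a domain error (filter
#'   upstream).
#' @return Ordered factor with levels C1..C5.
#' @export
classify_bmi <- function(bmi) {
  if (any(!is.finite(bmi))) stop("non-finite bmi", call. = FALSE)
  if (any(bmi < 18.5)) {
    stop("bmi below 18.5 kg/m^2: underweight subjects must be filtered out",
         call. = FALSE)
  }
  cut(bmi, breaks = c(18.5, 25, 30, 35, 40, Inf), labels = .category_labels,
      right = FALSE, ordered_result = TRUE)
}

#' Classify percent body fat into sex-specific bands
#'
#' Men: `(-Inf,20) [20,25) [25,30) [30,35) [35,Inf)`; women the same grid
#' shifted up 10 points. Labelled C1..C5; categories C3 and above are obese
#' (>= 25% body fat in men, >= 35% in women).
#'
#' @param percent_bf Percent body fat.
#' @param sex `"male"`/`"female"` (vectorised, recycled against
#'   `percent_bf`).
#' @return Ordered factor with levels C1..C5.
#' @export
classify_cunbae <- function(percent_bf, sex) {
  if (any(!is.finite(percent_bf))) stop("non-finite percent_bf", call. = FALSE)
  s <- sex_code(sex)
  n <- max(length(percent_bf), length(s))
  percent_bf <- rep_len(percent_bf, n); s <- rep_len(s, n)
  out <- rep(NA_character_, n)
  men <- s == 0
  out[men] <- as.character(cut(percent_bf[men],
    breaks = c(-Inf, 20, 25, 30, 35, Inf), labels = .category_labels,
    right = FALSE))
  out[!men] <- as.character(cut(percent_bf[!men],
    breaks = c(-Inf, 30, 35, 40, 45, Inf), labels = .category_labels,
    right = FALSE))
  factor(out, levels = .category_labels, ordered = TRUE)
}

#' Score a cohort under both adiposity schemes
#'
#' Adds `percent_bf` (CUN-BAE), `bmi_category`, `cunbae_category`,
#' `obese_bmi` and `obese_cunbae` columns.
#'
#' @param x A `cohort` (from [load_cohort()] or [generate_cohort()]) or a
#'   data.frame with `sex`, `age`, `bmi` columns.
#' @return Object of the same kind with the five added columns.
#' @export
score_cohort <- function(x) {
  d <- cohort_data(x)
  d$percent_bf <- cun_bae(d$age, d$sex, d$bmi)
  d$bmi_category <- classify_bmi(d$bmi)
  d$cunbae_category <- classify_cunbae(d$percent_bf, d$sex)
  d$obese_bmi <- d$bmi >= 30
  d$obese_cunbae <- as.integer(d$cunbae_category) >= 3
  replace_cohort_data(x, d)
}
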