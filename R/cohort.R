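#' @title Cohort container
#' @description A `cohort` is a list with `subjects` (one row per retained
#'   subject), `exclusions` (id, reason; one row per excluded input record)
#'   and `provenance` (free-text source descriptor). Constructed by
#'   [load_cohort()] or [generate_cohort()].
#' @name cohort
NULL

new_cohort <- function(subjects, exclusions = NULL, provenance = "in-memory") {
  if (is.null(exclusions)) {
    exclusions <- data.frame(id = character(), reason = character(),
                             stringsAsFactors = FALSE)
  }
  structure(list(subjects = subjects, exclusions = exclusions,
                 provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$subjects), " subjects (",
      sum(x$subjects$sex == "male"), " men, ",
      sum(x$subjects$sex == "female"), " women), ",
      nrow(x$exclusions), " excluded\n", sep = "")
  cat("source: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Subjects of a cohort
#' @param x A `cohort`.
#' @return The subject-level data.frame.
#' @export
subjects <- function(x) cohort_data(x)

#' Exclusion log of a cohort
#' @param x A `cohort`.
#' @return data.frame with columns `id`, `reason`.
#' @export
exclusions <- function(x) {
  if (inherits(x, "cohort")) x$exclusions
  else data.frame(id = character(), reason = character())
}

# accept either a cohort object or a bare subject data.frame
cohort_data <- function(x) {
  if (inherits(x, "cohort")) x$subjects
  else if (is.data.frame(x)) x
  else stop("expected a cohort or a data.frame", call. = FALSE)
}

replace_cohort_data <- function(x, d) {
  if (inherits(x, "cohort")) { x$subjects <- d; x } else d
}

#' BMI from weight and height
#'
#' @param weight Weight in kg (> 0).
#' @param height Height in metres (> 0).
#' @return BMI in kg/m^2 (weight / height^2).
#' @examples bmi_from_weight_height(80, 1.78)  # 25.25
#' @export
bmi_from_weight_height <- function(weight, height) {
  if (any(!is.finite(weight)) || any(!is.finite(height)) ||
      any(weight <= 0) || any(height <= 0)) {
    stop("weight and height must be finite and positive", call. = FALSE)
  }
  weight / height^2
}

.cohort_columns <- c("sex", "age", "height", "weight", "bmi",
                     "hypertension", "diabetes", "education", "marital",
                     "tobacco", "alcohol")

#' Load and filter an individual-level cohort
#'
#' Reads a comma-separated file (UTF-8, header row, decimal point), maps
#' columns, derives BMI from height/weight where absent, and applies the
#' adult-cohort inclusion rules: age at least `age_min` years and BMI >=
#' 18.5 kg/m^2. Records failing a rule -- or with unparseable sex, age or
#' BMI, inconsistent given vs derived BMI (> 0.1 kg/m^2 apart), duplicate
#' ids, or a TRUE `pregnant` flag when that column is mapped -- are dropped
#' and logged, never a crash. Row order of retained subjects is preserved.
#'
#' @param path CSV file path.
#' @param schema Optional column mapping: a named list/vector
#'   (`list(sex = "SEXO", ...)`) or path to a JSON file of the same shape.
#'   Recognised keys: id, sex, age, height, weight, bmi, hypertension,
#'   diabetes, education, marital, tobacco, alcohol, pregnant. Unmapped
#'   names default to themselves.
#' @param age_min Minimum age retained; default 18.
#' @param age_inclusive If `TRUE` (default) the rule is `age >= age_min`,
#'   else strict `>`. The source criterion "over eighteen" is ambiguous;
#'   inclusive matches an adult cohort whose mean ages are ~50.
#' @return A [cohort].
#' @export
load_cohort <- function(path, schema = NULL, age_min = 18,
                        age_inclusive = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  map <- resolve_schema(schema)
  required <- c("sex", "age")
  missing_cols <- required[!map[required] %in% names(raw)]
  if (length(missing_cols)) {
    stop("required column(s) not found in ", path, ": ",
         paste(map[missing_cols], collapse = ", "), call. = FALSE)
  }
  has <- function(key) map[[key]] %in% names(raw)
  col <- function(key) if (has(key)) raw[[map[[key]]]] else NULL
  if (!has("bmi") && !(has("height") && has("weight"))) {
    stop("need either a bmi column or both height and weight", call. = FALSE)
  }

  n <- nrow(raw)
  id <- if (has("id")) as.character(col("id")) else sprintf("row%d", seq_len(n))
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why

  flag(duplicated(id), "duplicate_id")

  sex <- suppressWarnings(tryCatch(sex_code(col("sex")),
                                   error = function(e) rep(NA_real_, n)))
  if (length(sex) != n) sex <- rep(NA_real_, n)
  # fall back to per-row parsing so one bad token doesn't void the column
  if (all(is.na(sex))) {
    sex <- vapply(as.character(col("sex")), function(v) {
      tryCatch(sex_code(v), error = function(e) NA_real_)
    }, numeric(1), USE.NAMES = FALSE)
  }
  flag(is.na(sex), "unparseable_sex")

  age <- suppressWarnings(as.numeric(col("age")))
  flag(is.na(age), "unparseable_age")
  flag(if (age_inclusive) age < age_min else age <= age_min,
       sprintf("under_%s", age_min))

  height <- if (has("height")) suppressWarnings(as.numeric(col("height"))) else rep(NA_real_, n)
  weight <- if (has("weight")) suppressWarnings(as.numeric(col("weight"))) else rep(NA_real_, n)
  bmi_given <- if (has("bmi")) suppressWarnings(as.numeric(col("bmi"))) else rep(NA_real_, n)
  ok_hw <- !is.na(height) & !is.na(weight) & height > 0 & weight > 0
  bmi_derived <- rep(NA_real_, n)
  bmi_derived[ok_hw] <- weight[ok_hw] / height[ok_hw]^2
  bmi <- ifelse(is.na(bmi_given), bmi_derived, bmi_given)
  flag(is.na(bmi), "unparseable_bmi")
  flag(!is.na(bmi_given) & !is.na(bmi_derived) &
         abs(bmi_given - bmi_derived) > 0.1, "bmi_inconsistent")
  flag(bmi < 18.5, "bmi_below_18.5")

  if (has("pregnant")) {
    preg <- parse_flag(col("pregnant"))
    flag(!is.na(preg) & preg, "pregnant")
  }

  to_flag <- function(key) {
    if (has(key)) parse_flag(col(key)) else rep(NA, n)
  }
  subjects <- data.frame(
    id = id,
    sex = ifelse(sex == 1, "female", "male"),
    age = age, height = height, weight = weight, bmi = bmi,
    hypertension = to_flag("hypertension"),
    diabetes = to_flag("diabetes"),
    education = as_chr_or_na(col("education"), n),
    marital = as_chr_or_na(col("marital"), n),
    tobacco = as_chr_or_na(col("tobacco"), n),
    alcohol = as_chr_or_na(col("alcohol"), n),
    stringsAsFactors = FALSE
  )
  keep <- is.na(reason)
  excl <- data.frame(id = id[!keep], reason = reason[!keep],
                     stringsAsFactors = FALSE)
  out <- subjects[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_cohort(out, excl, provenance = normalizePath(path))
}

as_chr_or_na <- function(x, n) {
  if (is.null(x)) rep(NA_character_, n) else as.character(x)
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[v %in% c("0", "false", "f", "no", "n")] <- FALSE
  out
}

resolve_schema <- function(schema) {
  keys <- c("id", .cohort_columns, "pregnant")
  map <- stats::setNames(as.list(keys), keys)
  if (is.null(schema)) return(map)
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    schema <- jsonlite::read_json(schema, simplifyVector = TRUE)
  }
  schema <- as.list(schema)
  bad <- setdiff(names(schema), keys)
  if (length(bad)) {
    stop("unknown schema key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  map[names(schema)] <- schema
  map
}

#' Write a cohort (and optionally its exclusion log) to CSV
#'
#' @param cohort A [cohort].
#' @param path Output CSV for the subjects table.
#' @param exclusions_path Optional CSV path for the `(id, reason)` log.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, exclusions_path = NULL) {
  utils::write.csv(cohort_data(cohort), path, row.names = FALSE, na = "")
  if (!is.null(exclusions_path)) {
    utils::write.csv(exclusions(cohort), exclusions_path, row.names = FALSE)
  }
  invisible(path)
}
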