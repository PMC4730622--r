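#' Per-category contingency table for one outcome/sex/scheme stratum
#'
#' One row per adiposity category in scheme order, reference (C1) first, with
#' the number of subjects `N` and of cases `n`. Empty categories are retained
#' with N = 0. Because the same cases are merely re-partitioned, the case
#' total for a given (outcome, sex) is identical across the two schemes.
#'
#' @param x A scored cohort.
#' @param outcome `"hypertension"` (AHT) or `"diabetes"` (DM).
#' @param sex `"male"` or `"female"`.
#' @param scheme `"bmi"` or `"cunbae"`.
#' @return data.frame of class `"category_table"` with columns `category`,
#'   `label`, `N`, `n`, `prevalence` (%), and attributes `outcome`, `sex`,
#'   `scheme`.
#' @export
build_category_table <- function(x, outcome = c("hypertension", "diabetes"),
                                 sex = c("male", "female"),
                                 scheme = c("bmi", "cunbae")) {
  outcome <- match.arg(outcome); sex <- match.arg(sex)
  scheme <- match.arg(scheme)
  d <- scored_data(x)
  d <- d[d$sex == sex & !is.na(d[[outcome]]), ]
  cat_col <- if (scheme == "bmi") d$bmi_category else d$cunbae_category
  N <- as.integer(table(cat_col))
  n <- as.integer(tapply(d[[outcome]], cat_col, sum, default = 0L))
  defs <- adiposity_categories(scheme, sex = sex)
  out <- data.frame(category = defs$category, label = defs$label,
                    N = N, n = n,
                    prevalence = ifelse(N > 0, 100 * n / N, NA_real_),
                    stringsAsFactors = FALSE)
  structure(out, outcome = outcome, sex = sex, scheme = scheme,
            class = c("category_table", "data.frame"))
}

#' Crude odds ratio for one exposure category against the reference
#'
#' \eqn{OR = \frac{n_e/(N_e-n_e)}{n_r/(N_r-n_r)}} with the Woolf (log-odds)
#' 95% confidence interval \eqn{\exp(\log OR \pm 1.96\sqrt{\sum 1/cell})}.
#'
#' @param exposed,reference Length-2 vectors `c(N, n)`: subjects and cases.
#' @param correction Add 0.5 to every cell when one is zero (off by
#'   default; with it off a zero cell yields `NA` estimates).
#' @return List with `or`, `ci` (length-2), `cells` (the 2x2 counts).
#' @examples
#' crude_odds_ratio(c(849, 254), c(749, 152))$or  # 1.68
#' @export
crude_odds_ratio <- function(exposed, reference, correction = FALSE) {
  stopifnot(length(exposed) == 2, length(reference) == 2)
  cells <- c(case_e = exposed[2], noncase_e = exposed[1] - exposed[2],
             case_r = reference[2], noncase_r = reference[1] - reference[2])
  if (any(cells < 0)) stop("cases exceed subjects", call. = FALSE)
  if (any(cells == 0)) {
    if (!correction) {
      return(list(or = NA_real_, ci = c(NA_real_, NA_real_), cells = cells))
    }
    cells <- cells + 0.5
  }
  or <- (cells["case_e"] / cells["noncase_e"]) /
        (cells["case_r"] / cells["noncase_r"])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(or = unname(or), ci = unname(ci), cells = cells)
}

#' Crude odds ratios for every category of a table
#'
#' Applies [crude_odds_ratio()] row-wise against the reference (first) row.
#' The reference row gets OR 1 with no interval.
#'
#' @param tab A `category_table` (or data.frame with `N`, `n`).
#' @param correction Passed to [crude_odds_ratio()].
#' @return The table with added columns `cOR`, `cOR_lo`, `cOR_hi`.
#' @export
crude_or_table <- function(tab, correction = FALSE) {
  ref <- c(tab$N[1], tab$n[1])
  est <- lapply(seq_len(nrow(tab)), function(i) {
    if (i == 1) return(list(or = 1, ci = c(NA_real_, NA_real_)))
    crude_odds_ratio(c(tab$N[i], tab$n[i]), ref, correction = correction)
  })
  tab$cOR <- vapply(est, `[[`, numeric(1), "or")
  tab$cOR_lo <- vapply(est, function(e) e$ci[1], numeric(1))
  tab$cOR_hi <- vapply(est, function(e) e$ci[2], numeric(1))
  tab
}

#' Adjusted odds ratios from a logistic regression
#'
#' Fits a maximum-likelihood logistic regression of the outcome on the
#' adiposity category (indicators against the C1 reference) plus the
#' covariate set, on complete cases of one sex. The default covariates are
#' education, marital status, tobacco and alcohol use -- treated as
#' unordered factors with the most frequent level as reference -- plus age
#' as a continuous term if and only if `scheme = "bmi"` (the CUN-BAE score
#' already incorporates age). Adjusted ORs are the exponentiated category
#' coefficients with Wald 95% confidence intervals.
#'
#' A category is flagged non-estimable when it has fewer than `min_cases`
#' cases or non-cases (its OR and CI are reported but `estimable` is FALSE);
#' a category with zero cases or zero non-cases is reported as `NA`
#' (complete separation on that indicator).
#'
#' @inheritParams build_category_table
#' @param covariates Character vector of adjustment columns; `NULL` for the
#'   scheme-dependent default described above. Use `character(0)` for an
#'   unadjusted (category-only) model.
#' @param min_cases Sparse-category threshold, default 5.
#' @return data.frame of class `"risk_table"`: `category`, `label`, `N`,
#'   `n`, `prevalence`, `aOR`, `aOR_lo`, `aOR_hi`, `estimable`; attributes
#'   `fit` (the glm), `n_used`, `n_dropped` (complete-case deletions),
#'   `covariates`.
#' @export
fit_adjusted_or <- function(x, outcome = c("hypertension", "diabetes"),
                            sex = c("male", "female"),
                            scheme = c("bmi", "cunbae"),
                            covariates = NULL, min_cases = 5) {
  outcome <- match.arg(outcome); sex <- match.arg(sex)
  scheme <- match.arg(scheme)
  d <- scored_data(x)
  d <- d[d$sex == sex, ]
  if (is.null(covariates)) {
    covariates <- c("education", "marital", "tobacco", "alcohol",
                    if (scheme == "bmi") "age")
    covariates <- intersect(covariates, names(d)[!vapply(d, function(cc)
      all(is.na(cc)), logical(1))])
  }
  cat_col <- if (scheme == "bmi") "bmi_category" else "cunbae_category"
  d$.category <- factor(as.character(d[[cat_col]]), levels = .category_labels)
  vars <- c(outcome, ".category", covariates)
  cc <- stats::complete.cases(d[vars])
  n_dropped <- sum(!cc)
  d <- d[cc, ]
  if (length(unique(d[[outcome]])) < 2) {
    stop("outcome is constant in this stratum: model degenerate",
         call. = FALSE)
  }
  for (v in covariates) {
    if (!is.numeric(d[[v]])) {
      tabv <- table(d[[v]])
      d[[v]] <- stats::relevel(factor(d[[v]]), ref = names(which.max(tabv)))
    }
  }
  d$.category <- droplevels(d$.category)
  n_par <- nlevels(d$.category) +
    sum(vapply(covariates, function(v)
      if (is.numeric(d[[v]])) 1L else nlevels(d[[v]]) - 1L, integer(1)))
  if (nrow(d) < 10 * n_par) {
    warning("fewer than 10 complete cases per parameter (", nrow(d), " for ",
            n_par, " parameters)", call. = FALSE)
  }
  fml <- stats::reformulate(c(".category", covariates), response = outcome)
  fit <- stats::glm(fml, family = stats::binomial(), data = d,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  if (!fit$converged) {
    stop("logistic regression did not converge after 100 IRLS iterations",
         call. = FALSE)
  }
  co <- stats::coef(summary(fit))
  tab <- build_category_table(d, outcome = outcome, sex = sex,
                              scheme = scheme)
  lev <- levels(d$.category)[-1]
  res <- data.frame(tab, aOR = NA_real_, aOR_lo = NA_real_,
                    aOR_hi = NA_real_, estimable = FALSE)
  res$aOR[1] <- 1; res$estimable[1] <- TRUE
  for (lv in lev) {
    i <- match(lv, res$category)
    term <- paste0(".category", lv)
    if (!term %in% rownames(co)) next
    cases <- res$n[i]; noncases <- res$N[i] - res$n[i]
    if (cases == 0 || noncases == 0) next  # separated indicator
    b <- co[term, "Estimate"]; se <- co[term, "Std. Error"]
    res$aOR[i] <- exp(b)
    res$aOR_lo[i] <- exp(b - stats::qnorm(0.975) * se)
    res$aOR_hi[i] <- exp(b + stats::qnorm(0.975) * se)
    res$estimable[i] <- cases >= min_cases && noncases >= min_cases
  }
  structure(res, outcome = outcome, sex = sex, scheme = scheme,
            fit = fit, n_used = nrow(d), n_dropped = n_dropped,
            covariates = covariates,
            class = c("risk_table", "category_table", "data.frame"))
}

#' Full risk table: counts, prevalence, crude and adjusted odds ratios
#'
#' Convenience wrapper combining [crude_or_table()] and [fit_adjusted_or()]
#' into one table shaped like a published risk-by-category summary.
#'
#' @inheritParams fit_adjusted_or
#' @return data.frame with category, label, N, n, prevalence, cOR and aOR
#'   columns (each with a 95% CI).
#' @export
risk_table <- function(x, outcome = c("hypertension", "diabetes"),
                       sex = c("male", "female"),
                       scheme = c("bmi", "cunbae"), covariates = NULL) {
  outcome <- match.arg(outcome); sex <- match.arg(sex)
  scheme <- match.arg(scheme)
  crude <- crude_or_table(build_category_table(x, outcome, sex, scheme))
  adj <- fit_adjusted_or(x, outcome, sex, scheme, covariates = covariates)
  cbind(crude, adj[c("aOR", "aOR_lo", "aOR_hi", "estimable")])
}
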