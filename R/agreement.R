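#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return r^2 in \[0, 1\].
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  stats::cor(x, y)^2
}

#' Cohen's kappa for two binary classifications
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} from the
#' 2x2 cross-classification, with the asymptotic standard error of Fleiss,
#' Cohen and Everitt and a normal-quantile 95% confidence interval
#' (\eqn{\kappa \pm 1.96\,SE}).
#'
#' @param a,b Logical (or 0/1) vectors of equal length, e.g. obesity flags
#'   under two schemes. Alternatively pass a 2x2 contingency `table` as `a`
#'   and omit `b`.
#' @param conf_level Confidence level, default 0.95.
#' @return List of class `"cohen_kappa"`: `kappa`, `se`, `ci` (length-2),
#'   `po` (observed agreement), `pe` (expected agreement), `n`.
#' @export
cohen_kappa <- function(a, b = NULL, conf_level = 0.95) {
  if (is.null(b)) {
    tab <- as.matrix(a)
    if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2", call. = FALSE)
  } else {
    if (length(a) != length(b)) stop("a and b must have equal length",
                                     call. = FALSE)
    a <- as.logical(a); b <- as.logical(b)
    ok <- !is.na(a) & !is.na(b)
    tab <- table(factor(a[ok], c(FALSE, TRUE)), factor(b[ok], c(FALSE, TRUE)))
  }
  n <- sum(tab)
  if (n == 0) stop("empty table", call. = FALSE)
  p <- tab / n
  prow <- rowSums(p); pcol <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(prow * pcol)
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    stop("expected agreement is 1 (both classifications constant and ",
         "identical): kappa undefined", call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt (1969) large-sample variance of kappa-hat
  i <- seq_len(nrow(p))
  term1 <- sum(diag(p) * ((1 - pe) - (prow + pcol) * (1 - po))^2)
  term2 <- 0
  for (r in i) for (cc in i) {
    if (r != cc) term2 <- term2 + p[r, cc] * (pcol[r] + prow[cc])^2
  }
  term2 <- (1 - po)^2 * term2
  term3 <- (po * pe - 2 * pe + po)^2
  var_k <- (term1 + term2 - term3) / (n * (1 - pe)^4)
  se <- sqrt(max(var_k, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kappa, se = se,
                 ci = c(kappa - z * se, kappa + z * se),
                 po = po, pe = pe, n = n),
            class = "cohen_kappa")
}

#' @export
print.cohen_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.3f (95%% CI %.3f-%.3f), n = %d\n",
              x$kappa, x$ci[1], x$ci[2], x$n))
  cat(sprintf("observed agreement %.1f%%, expected %.1f%%\n",
              100 * x$po, 100 * x$pe))
  invisible(x)
}

#' Obesity prevalence under both schemes, by stratum
#'
#' Counts and percentages of obesity as flagged by BMI (>= 30 kg/m^2) and by
#' CUN-BAE percent body fat (>= 25% men / >= 35% women), per sex-by-age-band
#' stratum, plus the CUN-BAE : BMI prevalence ratio. Empty strata are
#' omitted with a warning.
#'
#' @param x A scored cohort (see [score_cohort()]).
#' @param age_cut Age-band edge in years; bands are `< age_cut` and
#'   `>= age_cut`. Default 50.
#' @return data.frame with one row per stratum (`all/all`, each sex total,
#'   each sex x age band): n, obesity counts and percentages under each
#'   scheme, `prevalence_ratio`.
#' @export
prevalence_comparison <- function(x, age_cut = 50) {
  d <- scored_data(x)
  strata <- stratum_list(d, age_cut)
  rows <- lapply(names(strata), function(nm) {
    idx <- strata[[nm]]
    if (!any(idx)) {
      warning("empty stratum omitted: ", nm, call. = FALSE)
      return(NULL)
    }
    s <- d[idx, ]
    n_bmi <- sum(s$obese_bmi); n_cun <- sum(s$obese_cunbae)
    data.frame(sex = sub("\\..*", "", nm), age_band = sub(".*\\.", "", nm),
               n = nrow(s),
               n_obese_bmi = n_bmi, pct_obese_bmi = 100 * n_bmi / nrow(s),
               n_obese_cunbae = n_cun,
               pct_obese_cunbae = 100 * n_cun / nrow(s),
               prevalence_ratio = if (n_bmi > 0) n_cun / n_bmi else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Agreement between the BMI and CUN-BAE schemes, stratified
#'
#' One row per stratum (overall; each sex; each sex by age band) with the
#' number of subjects, the BMI-vs-%BF Pearson R^2, obesity prevalence under
#' each scheme, percent agreement of the binary obesity flags, and Cohen's
#' kappa with its 95% CI. Kappa is computed on the binary obese/not-obese
#' flags, not the five-level categories.
#'
#' @inheritParams prevalence_comparison
#' @return data.frame, one row per non-empty stratum.
#' @export
agreement_table <- function(x, age_cut = 50) {
  d <- scored_data(x)
  strata <- stratum_list(d, age_cut)
  rows <- lapply(names(strata), function(nm) {
    idx <- strata[[nm]]
    if (!any(idx)) return(NULL)
    s <- d[idx, ]
    k <- cohen_kappa(s$obese_bmi, s$obese_cunbae)
    data.frame(sex = sub("\\..*", "", nm), age_band = sub(".*\\.", "", nm),
               n = nrow(s),
               r_squared = pearson_r2(s$bmi, s$percent_bf),
               n_obese_bmi = sum(s$obese_bmi),
               pct_obese_bmi = 100 * mean(s$obese_bmi),
               n_obese_cunbae = sum(s$obese_cunbae),
               pct_obese_cunbae = 100 * mean(s$obese_cunbae),
               percent_agreement = 100 * k$po,
               kappa = k$kappa, kappa_lo = k$ci[1], kappa_hi = k$ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

scored_data <- function(x) {
  d <- cohort_data(x)
  if (!all(c("percent_bf", "obese_bmi", "obese_cunbae") %in% names(d))) {
    d <- cohort_data(score_cohort(d))
  }
  d
}

stratum_list <- function(d, age_cut) {
  young <- d$age < age_cut
  lab_y <- sprintf("<%s", age_cut); lab_o <- sprintf(">=%s", age_cut)
  out <- list(rep(TRUE, nrow(d)))
  names(out) <- "all.all"
  for (sx in c("male", "female")) {
    sel <- d$sex == sx
    out[[paste(sx, "all", sep = ".")]] <- sel
    out[[paste(sx, lab_y, sep = ".")]] <- sel & young
    out[[paste(sx, lab_o, sep = ".")]] <- sel & !young
  }
  out
}
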