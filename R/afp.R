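#' Population attributable fraction (Miettinen's case-load formula)
#'
#' \deqn{AF_p = \left(1 - \sum_{l=1}^{k} \frac{pd_l}{OR_l}\right) \times 100}
#'
#' where \eqn{pd_l} is the share of all cases found at exposure level
#' \eqn{l} (including the reference level, whose OR is 1) and \eqn{OR_l}
#' the (typically adjusted) odds ratio of level \eqn{l} against the
#' reference. A negative value (net-protective exposure) is returned with a
#' warning, never clamped.
#'
#' @param case_counts Non-negative cases per category, positive total.
#' @param or_vector Odds ratios per category, same length; the reference
#'   entry must equal 1 and all entries must be positive.
#' @param source Provenance tag stored in the result (`"fitted"` or
#'   `"summary-table"`).
#' @return Object of class `"afp_result"`: `afp` (percent), `pd`,
#'   `or_vector`, `source`.
#' @examples
#' afp_miettinen(c(21, 79, 208, 199, 121),
#'               c(1, 1.67, 3.80, 6.80, 11.24))$afp  # 74.03
#' @export
afp_miettinen <- function(case_counts, or_vector, source = "fitted") {
  if (length(case_counts) != length(or_vector)) {
    stop("case_counts and or_vector must have equal length", call. = FALSE)
  }
  if (any(!is.finite(case_counts)) || any(case_counts < 0)) {
    stop("case counts must be finite and non-negative", call. = FALSE)
  }
  total <- sum(case_counts)
  if (total <= 0) stop("total case count must be positive", call. = FALSE)
  if (any(!is.finite(or_vector)) || any(or_vector <= 0)) {
    stop("all odds ratios must be finite and positive", call. = FALSE)
  }
  if (abs(or_vector[1] - 1) > 1e-9) {
    stop("the first (reference) odds ratio must equal 1", call. = FALSE)
  }
  pd <- case_counts / total
  afp <- (1 - sum(pd / or_vector)) * 100
  if (afp < 0) {
    warning("negative attributable fraction (net-protective exposure)",
            call. = FALSE)
  }
  structure(list(afp = afp, pd = pd, or_vector = or_vector, source = source),
            class = "afp_result")
}

#' @export
print.afp_result <- function(x, ...) {
  cat(sprintf("Population attributable fraction: %.2f%% (%s, %d categories)\n",
              x$afp, x$source, length(x$pd)))
  invisible(x)
}

#' Attributable fraction from a summary-level CSV or table
#'
#' Re-analysis mode over a per-category summary with columns `category`,
#' `n` (cases) and `aOR` (or `or`). Exactly one row -- the first -- must be
#' the reference with odds ratio 1. Rows with a missing odds ratio (sparse
#' categories published without an estimate) have their cases merged into
#' the adjacent lower category before the computation, with a message.
#'
#' @param x Path to a CSV file, or an equivalent data.frame.
#' @return An [afp_miettinen()] result with `source = "summary-table"`.
#' @export
afp_from_summary <- function(x) {
  d <- if (is.character(x)) {
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else as.data.frame(x)
  or_col <- intersect(c("aOR", "or", "OR", "cOR"), names(d))[1]
  if (!all(c("category", "n") %in% names(d)) || is.na(or_col)) {
    stop("summary table needs columns category, n and aOR (or or/cOR)",
         call. = FALSE)
  }
  if (anyDuplicated(d$category)) {
    stop("duplicate categories in summary table", call. = FALSE)
  }
  ors <- as.numeric(d[[or_col]])
  if (is.na(ors[1]) || abs(ors[1] - 1) > 1e-9) {
    stop("first row must be the reference category with odds ratio 1",
         call. = FALSE)
  }
  n <- as.numeric(d$n)
  miss <- which(is.na(ors))
  if (length(miss)) {
    if (1 %in% miss) stop("reference row lacks an odds ratio", call. = FALSE)
    for (i in rev(sort(miss))) {
      message("category '", d$category[i], "' has no odds ratio; ",
              "merging its ", n[i], " case(s) into '", d$category[i - 1], "'")
      n[i - 1] <- n[i - 1] + n[i]
    }
    n <- n[-miss]; ors <- ors[-miss]
  }
  if (length(n) == 1) {
    return(structure(list(afp = 0, pd = 1, or_vector = 1,
                          source = "summary-table"), class = "afp_result"))
  }
  afp_miettinen(n, ors, source = "summary-table")
}

#' Merge sparse categories into their lower neighbour
#'
#' Walks a category table from the top down and merges any non-reference
#' category with fewer than `min_cases` cases into the category below it
#' (N and n summed). The reference (first) category is never merged. Used
#' before attributable-fraction computation so that every retained category
#' carries an estimable odds ratio.
#'
#' @param tab A `category_table` (or data.frame with `category`, `N`, `n`).
#' @param min_cases Minimum case count a category must keep, default 6.
#' @return The collapsed table; merges are recorded in the `"merged"`
#'   attribute as `(from, into)` pairs.
#' @export
collapse_sparse_categories <- function(tab, min_cases = 6) {
  stopifnot(all(c("category", "N", "n") %in% names(tab)))
  merged <- data.frame(from = character(), into = character(),
                       stringsAsFactors = FALSE)
  i <- nrow(tab)
  while (i >= 2) {
    if (tab$n[i] < min_cases) {
      tab$N[i - 1] <- tab$N[i - 1] + tab$N[i]
      tab$n[i - 1] <- tab$n[i - 1] + tab$n[i]
      merged <- rbind(merged,
                      data.frame(from = as.character(tab$category[i]),
                                 into = as.character(tab$category[i - 1]),
                                 stringsAsFactors = FALSE))
      tab <- tab[-i, , drop = FALSE]
    }
    i <- i - 1
  }
  if ("prevalence" %in% names(tab)) {
    tab$prevalence <- ifelse(tab$N > 0, 100 * tab$n / tab$N, NA_real_)
  }
  rownames(tab) <- NULL
  attr(tab, "merged") <- merged
  tab
}

#' Attributable fraction from a fitted risk table
#'
#' Collapses sparse categories, refits nothing: takes the adjusted odds
#' ratios already present in `rt` (categories whose OR is `NA` after
#' collapsing are merged downward as in [afp_from_summary()]).
#'
#' @param rt A `risk_table` from [fit_adjusted_or()] or [risk_table()].
#' @param min_cases Sparse threshold passed to
#'   [collapse_sparse_categories()]; set 0 to disable collapsing.
#' @return An [afp_miettinen()] result with `source = "fitted"`.
#' @export
afp_from_risk_table <- function(rt, min_cases = 0) {
  d <- as.data.frame(rt)[, c("category", "N", "n", "aOR")]
  if (min_cases > 0) d <- collapse_sparse_categories(d, min_cases)
  res <- afp_from_summary(d)
  res$source <- "fitted"
  res
}
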