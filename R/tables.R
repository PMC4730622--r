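# Published per-category summaries from a cross-sectional study of 3888
# Spanish adults (2009-2011): subjects (N), cases (n), crude and adjusted
# odds ratios for hypertension (aht) and type 2 diabetes (dm), by sex and
# adiposity scheme. The men/dm/bmi >=40 row was published without an odds
# ratio (5 cases); its NA is handled by collapse_sparse_categories().
summary_table_data <- function() {
  row5 <- function(N, n, cOR, aOR) {
    data.frame(category = c("C1", "C2", "C3", "C4", "C5"),
               N = N, n = n, cOR = cOR, aOR = aOR, stringsAsFactors = FALSE)
  }
  list(
    men_aht_bmi = row5(c(749, 849, 328, 74, 33), c(152, 254, 169, 37, 16),
                       c(1, 1.68, 4.17, 3.93, 3.70),
                       c(1, 1.33, 3.93, 4.50, 8.66)),
    men_aht_cunbae = row5(c(258, 521, 631, 415, 208),
                          c(21, 79, 208, 199, 121),
                          c(1, 2.02, 5.55, 10.40, 15.70),
                          c(1, 1.67, 3.80, 6.80, 11.24)),
    women_aht_bmi = row5(c(895, 565, 259, 86, 50), c(119, 180, 110, 45, 26),
                         c(1, 3.05, 4.81, 7.15, 7.06),
                         c(1, 1.99, 2.73, 4.93, 7.71)),
    women_aht_cunbae = row5(c(303, 402, 464, 389, 297),
                            c(9, 36, 108, 165, 162),
                            c(1, 3.21, 9.91, 24.06, 39.20),
                            c(1, 2.97, 7.82, 16.10, 23.30)),
    men_dm_bmi = row5(c(749, 849, 328, 74, 33), c(73, 113, 79, 21, 5),
                      c(1, 1.42, 2.94, 2.97, NA),
                      c(1, 1.13, 2.37, 3.19, NA)),
    men_dm_cunbae = row5(c(258, 521, 631, 415, 208), c(9, 35, 95, 87, 65),
                         c(1, 1.99, 4.90, 7.34, 12.58),
                         c(1, 1.66, 3.49, 4.91, 8.34)),
    women_dm_bmi = row5(c(895, 565, 259, 86, 50), c(50, 76, 45, 21, 19),
                        c(1, 2.63, 3.55, 5.46, 10.36),
                        c(1, 1.78, 2.09, 3.44, 8.13)),
    women_dm_cunbae = row5(c(303, 402, 464, 389, 297), c(10, 23, 36, 61, 81),
                           c(1, 1.78, 2.46, 5.45, 10.99),
                           c(1, 1.64, 1.86, 3.47, 6.49))
  )
}

# published attributable fractions (percent), same keys
summary_table_afp <- function() {
  c(men_aht_bmi = 37.00, men_aht_cunbae = 74.03,
    women_aht_bmi = 45.32, women_aht_cunbae = 89.14,
    men_dm_bmi = 26.19, men_dm_cunbae = 71.54,
    women_dm_bmi = 40.38, women_dm_cunbae = 65.19)
}

#' Bundled reference summary tables
#'
#' Eight per-category summaries (sex x outcome x scheme) of hypertension
#' (aht) and type 2 diabetes (dm) risk in a cross-sectional study of 3888
#' Spanish adults: subjects `N` and cases `n` per adiposity category,
#' published crude (`cOR`) and covariate-adjusted (`aOR`) odds ratios
#' against the normal-weight reference. These drive the summary-level
#' re-analysis mode ([afp_from_summary()]) and are also shipped as CSVs
#' under `inst/extdata/` (see [generate_summary_fixtures()]).
#'
#' @param name Optional single key, e.g. `"men_aht_cunbae"`; omit for the
#'   full named list.
#' @return A data.frame, or a named list of eight data.frames.
#' @export
summary_tables <- function(name = NULL) {
  tabs <- summary_table_data()
  if (is.null(name)) return(tabs)
  if (!name %in% names(tabs)) {
    stop("unknown table '", name, "'; available: ",
         paste(names(tabs), collapse = ", "), call. = FALSE)
  }
  tabs[[name]]
}

#' Write the bundled summary tables as CSV fixtures
#'
#' Writes the eight tables of [summary_tables()] to
#' `<out_dir>/<key>.csv` (columns category, N, n, cOR, aOR). Case-count
#' conservation -- the case total of a given (sex, outcome) is identical
#' under both schemes -- is asserted before writing.
#'
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
generate_summary_fixtures <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", out_dir, call. = FALSE)
  }
  tabs <- summary_table_data()
  for (grp in c("men_aht", "women_aht", "men_dm", "women_dm")) {
    tot <- vapply(paste0(grp, c("_bmi", "_cunbae")),
                  function(k) sum(tabs[[k]]$n), numeric(1))
    stopifnot(tot[1] == tot[2])
  }
  paths <- vapply(names(tabs), function(k) {
    p <- file.path(out_dir, paste0(k, ".csv"))
    utils::write.csv(tabs[[k]], p, row.names = FALSE, na = "")
    p
  }, character(1))
  invisible(paths)
}

#' Path to a bundled summary fixture CSV
#'
#' @param name Key such as `"men_aht_cunbae"`; omit to list all bundled
#'   fixture files.
#' @return File path(s) under the installed package's `extdata/`.
#' @export
summary_fixture_path <- function(name = NULL) {
  dir <- system.file("extdata", package = "adipofrac")
  if (is.null(name)) return(list.files(dir, pattern = "\\.csv$",
                                       full.names = TRUE))
  p <- file.path(dir, paste0(name, ".csv"))
  if (!file.exists(p)) stop("no bundled fixture '", name, "'", call. = FALSE)
  p
}
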