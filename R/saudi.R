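#' Shipped Saudi reference standards
#'
#' The package ships gender-specific Saudi score-to-age prediction
#' tables (dense grids of (maturity score, predicted age) pairs covering
#' scores ~26-100 and ages ~4-13.2) and cubic models refit from those
#' tables by least squares. The published cubic coefficients are rounded
#' to few significant figures and do not reproduce the tables to their
#' printed 5-decimal precision, so the canonical shipped models are the
#' refits; the rounded published coefficients travel along in
#' `$metadata$published_coefficients` for rounding-level checks.
#'
#' @param sex `"male"` or `"female"`.
#' @param form `"table"` for the lookup-table standard, `"cubic"` for
#'   the refit cubic model.
#' @return a `"conversion_standard"`.
#' @seealso [load_standard()], [dentage_example()]
#' @export
saudi_standard <- function(sex = c("male", "female"),
                           form = c("table", "cubic")) {
  sex <- match.arg(sex)
  form <- match.arg(form)
  load_standard(dentage_example(sprintf("saudi_%s_%s.json", sex, form)))
}

#' Path to a packaged data file
#'
#' @param file file name under the package's `extdata` directory; omit
#'   to list the available files.
#' @return a file path (or a vector of file names).
#' @export
dentage_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "dentage")))
  }
  path <- system.file("extdata", file, package = "dentage")
  if (!nzchar(path)) stop("no packaged file '", file, "'")
  path
}

#' Published per-age-group bias summaries
#'
#' Returns the published dental-age minus chronological-age summary
#' rows (per sex, 1-year age group and population standard: group size
#' n, mean difference, SD) used for internal-consistency checks of the
#' reporting pipeline, e.g. that size-weighted group means reproduce the
#' published whole-sample totals.
#'
#' @return data.frame with columns `sex`, `age_group`, `n`, `standard`,
#'   `mean_diff`, `sd`.
#' @export
published_group_stats <- function() {
  read.csv(dentage_example("published_group_stats.csv"),
           stringsAsFactors = FALSE)
}
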