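#' Maturity score of a rated subject
#'
#' Sums the weight-table contribution of each tooth's attained stage:
#' the result lies on a 0-100 scale, with 100 = full maturation of the
#' seven assessed teeth. The weight table must match the subject's sex.
#'
#' @param rating a [tooth_stage_rating()].
#' @param table a [stage_weight_table()] of the same sex.
#' @return scalar maturity score in \[0, 100\].
#' @export
maturity_score <- function(rating, table) {
  stopifnot(inherits(rating, "tooth_stage_rating"),
            inherits(table, "stage_weight_table"))
  if (rating$sex != table$sex) {
    stop("subject ", rating$subject_id, " is ", rating$sex,
         " but weight table is ", table$sex)
  }
  teeth <- demirjian_teeth()
  sum(table$weights[cbind(teeth, rating$stages[teeth])])
}

#' Score a whole cohort
#'
#' @param ratings list of [tooth_stage_rating()] objects.
#' @param weight_tables named list with elements `male` and/or `female`,
#'   each a [stage_weight_table()] of the matching sex.
#' @return data.frame with columns `subject_id`, `sex`, `ca_years`,
#'   `age_group`, `maturity_score`.
#' @export
score_cohort <- function(ratings, weight_tables) {
  rows <- lapply(ratings, function(r) {
    wt <- weight_tables[[r$sex]]
    if (is.null(wt)) stop("no weight table for sex ", r$sex)
    data.frame(subject_id = r$subject_id, sex = r$sex,
               ca_years = r$ca_years,
               age_group = assign_age_group(r$ca_years, strict = FALSE),
               maturity_score = maturity_score(r, wt),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
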