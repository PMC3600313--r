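#' The seven assessed teeth and the nine developmental stage codes
#'
#' The method stages the seven left mandibular permanent teeth (FDI 31-37,
#' third molar excluded): central and lateral incisor, canine, first and
#' second premolar, first and second molar. Each tooth is rated on the
#' ordinal scale `0` (no calcification) then `A` through `H` (complete
#' root apex closure); the order `0 < A < B < ... < H` is total.
#'
#' @return Character vector of tooth codes, respectively stage codes, in
#'   canonical order.
#' @export
demirjian_teeth <- function() c("I1", "I2", "C", "PM1", "PM2", "M1", "M2")

#' @rdname demirjian_teeth
#' @export
demirjian_stages <- function() c("0", "A", "B", "C", "D", "E", "F", "G", "H")

#' Numeric coding of stage letters
#'
#' Ordinal equal-spacing code used for reliability statistics:
#' `0 -> 0, A -> 1, ..., H -> 8`.
#'
#' @param stage character vector of stage codes.
#' @return integer vector of the same length.
#' @export
stage_to_numeric <- function(stage) {
  idx <- match(as.character(stage), demirjian_stages())
  if (anyNA(idx)) {
    bad <- unique(as.character(stage)[is.na(idx)])
    stop("unknown stage code(s): ", paste(bad, collapse = ", "))
  }
  idx - 1L
}

#' Construct a single subject's tooth-stage rating
#'
#' A rating holds the stage codes of all seven assessed teeth together
#' with the subject's sex and age provenance: either a precomputed
#' decimal chronological age (`ca_years`) or a birth date and radiograph
#' (exam) date from which it is derived.
#'
#' @param subject_id opaque subject identifier.
#' @param sex `"male"` or `"female"`.
#' @param stages named character vector or list mapping each of the seven
#'   tooth codes (see [demirjian_teeth()]) to a stage code in
#'   [demirjian_stages()]. Exactly seven teeth must be present: subjects
#'   with mandibular hypodontia are outside the method's domain.
#' @param ca_years chronological age in decimal years, or `NULL` when
#'   both dates are given.
#' @param birth_date,exam_date `Date` (or ISO-8601 string) birth and
#'   radiograph dates; `exam_date` must not precede `birth_date`.
#' @param check_range reject subjects whose chronological age falls
#'   outside the validated window \[4, 14) years (default `TRUE`). Set
#'   `FALSE` to admit a subject for estimation-only use.
#' @return an object of class `"tooth_stage_rating"`.
#' @export
tooth_stage_rating <- function(subject_id, sex, stages,
                               ca_years = NULL,
                               birth_date = NULL, exam_date = NULL,
                               check_range = TRUE) {
  sex <- match.arg(sex, c("male", "female"))
  stages <- unlist(stages)
  teeth <- demirjian_teeth()
  missing <- setdiff(teeth, names(stages))
  if (length(missing) > 0L) {
    stop("subject ", subject_id, ": missing stage for tooth ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(stages), teeth)
  if (length(extra) > 0L) {
    stop("subject ", subject_id, ": unknown tooth code ",
         paste(extra, collapse = ", "))
  }
  stages <- as.character(stages[teeth])
  names(stages) <- teeth
  bad <- !stages %in% demirjian_stages()
  if (any(bad)) {
    stop("subject ", subject_id, ": unknown stage code for tooth ",
         paste(teeth[bad], collapse = ", "),
         " (got ", paste(stages[bad], collapse = ", "), ")")
  }

  if (is.null(ca_years)) {
    if (is.null(birth_date) || is.null(exam_date)) {
      stop("subject ", subject_id,
           ": need either ca_years or both birth_date and exam_date")
    }
    birth_date <- as.Date(birth_date)
    exam_date <- as.Date(exam_date)
    ca_years <- chronological_age(birth_date, exam_date)
  } else {
    ca_years <- as.numeric(ca_years)
    if (!is.finite(ca_years) || ca_years < 0) {
      stop("subject ", subject_id, ": invalid ca_years")
    }
    if (!is.null(birth_date)) birth_date <- as.Date(birth_date)
    if (!is.null(exam_date)) exam_date <- as.Date(exam_date)
  }
  if (check_range && (ca_years < 4 || ca_years >= 14)) {
    stop("subject ", subject_id, ": chronological age ",
         format(ca_years), " out of validated range [4, 14); ",
         "use check_range = FALSE to admit for estimation only")
  }

  structure(
    list(subject_id = as.character(subject_id), sex = sex,
         stages = stages, ca_years = ca_years,
         birth_date = birth_date, exam_date = exam_date),
    class = "tooth_stage_rating")
}

#' @export
print.tooth_stage_rating <- function(x, ...) {
  cat(sprintf("<tooth_stage_rating> %s (%s), CA %.4f yr\n",
              x$subject_id, x$sex, x$ca_years))
  cat(" ", paste(sprintf("%s:%s", names(x$stages), x$stages),
                 collapse = " "), "\n")
  invisible(x)
}

#' Chronological age in decimal years
#'
#' Age at the radiograph is the day count from birth to exam divided by
#' 365.25, the conventional decimal-age definition.
#'
#' @param birth_date,exam_date `Date` vectors (or ISO-8601 strings);
#'   `exam_date >= birth_date` elementwise.
#' @return numeric vector of decimal ages.
#' @examples
#' chronological_age("2000-01-01", "2008-01-01") # 8.0000
#' @export
chronological_age <- function(birth_date, exam_date) {
  birth_date <- as.Date(birth_date)
  exam_date <- as.Date(exam_date)
  days <- as.numeric(exam_date - birth_date)
  if (any(days < 0, na.rm = TRUE)) {
    stop("exam_date precedes birth_date")
  }
  days / 365.25
}

#' Assign a chronological age to its 1-year age group
#'
#' The validated cohort spans ages 4 to 14 in half-open 1-year bins
#' labelled `"4.00-4.99"` ... `"13.00-13.99"`.
#'
#' @param ca_years numeric vector of decimal ages.
#' @param strict error on ages outside \[4, 14) (default); if `FALSE`,
#'   out-of-range ages yield `NA`.
#' @return character vector of group labels.
#' @export
assign_age_group <- function(ca_years, strict = TRUE) {
  ca_years <- as.numeric(ca_years)
  out <- ca_years < 4 | ca_years >= 14
  if (strict && any(out, na.rm = TRUE)) {
    stop("age ", paste(format(ca_years[which(out)[1L]]), collapse = ""),
         " out of validated range [4, 14)")
  }
  lower <- floor(ca_years)
  lab <- sprintf("%d.00-%d.99", lower, lower)
  lab[out | is.na(ca_years)] <- NA_character_
  lab
}

#' @rdname assign_age_group
#' @export
age_group_levels <- function() sprintf("%d.00-%d.99", 4:13, 4:13)

#' Cronbach's alpha between two rating sessions
#'
#' Treats the two sessions as k = 2 items and each (radiograph, tooth)
#' rating as a case:
#' \deqn{\alpha = \frac{k}{k-1}\Bigl(1 - \frac{\sum_i s_i^2}{s_{tot}^2}\Bigr)}
#' with item variances \eqn{s_i^2} and the variance of item sums
#' \eqn{s_{tot}^2} (n-1 denominators). Stage letters should first be
#' coded numerically via [stage_to_numeric()].
#'
#' @param ratings_a,ratings_b numeric vectors of equal length (>= 2).
#' @return object of class `"reliability_result"`: list with `alpha`,
#'   `n_items` (2), `n_ratings`. `alpha` is `NA` (with a message in
#'   `note`) when the total variance is zero.
#' @export
cronbach_alpha <- function(ratings_a, ratings_b) {
  ratings_a <- as.numeric(ratings_a)
  ratings_b <- as.numeric(ratings_b)
  n <- length(ratings_a)
  if (length(ratings_b) != n) stop("rating vectors differ in length")
  if (n < 2L) stop("need at least 2 ratings")
  vtot <- var(ratings_a + ratings_b)
  res <- list(alpha = NA_real_, n_items = 2L, n_ratings = n, note = NULL)
  if (vtot <= 0) {
    res$note <- "zero total variance: alpha undefined"
  } else {
    res$alpha <- 2 * (1 - (var(ratings_a) + var(ratings_b)) / vtot)
  }
  structure(res, class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  if (is.na(x$alpha)) {
    cat("Cronbach's alpha: undefined (", x$note, ")\n", sep = "")
  } else {
    cat(sprintf("Cronbach's alpha: %.3f (%d items, %d ratings)\n",
                x$alpha, x$n_items, x$n_ratings))
  }
  invisible(x)
}

# ---- cohort CSV dialect ----------------------------------------------------

cohort_csv_header <- function() {
  c("subject_id", "sex", "birth_date", "exam_date", "ca_years",
    demirjian_teeth())
}

#' Read / write a cohort of tooth-stage ratings as CSV
#'
#' The cohort dialect has the fixed header
#' `subject_id,sex,birth_date,exam_date,ca_years,I1,I2,C,PM1,PM2,M1,M2`.
#' Dates are ISO-8601; `ca_years` may be empty when both dates are
#' present; stage codes are single characters (literal `0` allowed).
#'
#' @param path file path.
#' @param check_range,strict reject ages outside \[4, 14) (see
#'   [tooth_stage_rating()]).
#' @return `read_cohort()`: a list of [tooth_stage_rating()] objects.
#' @export
read_cohort <- function(path, check_range = TRUE) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  need <- cohort_csv_header()
  if (!all(need %in% names(df))) {
    stop("cohort CSV ", path, " missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    ca <- if (nzchar(row$ca_years)) as.numeric(row$ca_years) else NULL
    bd <- if (nzchar(row$birth_date)) row$birth_date else NULL
    ed <- if (nzchar(row$exam_date)) row$exam_date else NULL
    tryCatch(
      tooth_stage_rating(row$subject_id, row$sex,
                         stages = unlist(row[demirjian_teeth()]),
                         ca_years = ca, birth_date = bd, exam_date = ed,
                         check_range = check_range),
      error = function(e) stop("row ", i, " of ", path, ": ",
                               conditionMessage(e), call. = FALSE))
  })
}

#' @rdname read_cohort
#' @param ratings list of [tooth_stage_rating()] objects.
#' @export
write_cohort <- function(ratings, path) {
  rows <- lapply(ratings, function(r) {
    data.frame(
      subject_id = r$subject_id, sex = r$sex,
      birth_date = if (is.null(r$birth_date)) "" else format(r$birth_date),
      exam_date = if (is.null(r$exam_date)) "" else format(r$exam_date),
      ca_years = sprintf("%.5f", r$ca_years),
      as.list(r$stages),
      check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(df[, cohort_csv_header()], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
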