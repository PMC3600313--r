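#' Sex-specific stage weight table
#'
#' The scoring system assigns each (tooth, stage) pair a self-weighted
#' contribution on a 0-100 scale; a subject's maturity score is the sum
#' over the seven teeth of the weight of the attained stage. A valid
#' table satisfies, for each tooth, weight(tooth, `0`) = 0 and weights
#' non-decreasing in stage order, and the weights of stage `H` sum to
#' 100 across teeth (full maturity).
#'
#' @param sex `"male"` or `"female"`.
#' @param weights numeric matrix with rownames [demirjian_teeth()] and
#'   colnames [demirjian_stages()] (7 x 9), or a nested named list
#'   `weights[[tooth]][[stage]]`.
#' @param provenance free-text label recording where the weights come
#'   from (e.g. a literature citation, or `"synthetic demo"`).
#' @return object of class `"stage_weight_table"`.
#' @export
stage_weight_table <- function(sex, weights, provenance = "unspecified") {
  sex <- match.arg(sex, c("male", "female"))
  teeth <- demirjian_teeth()
  stg <- demirjian_stages()
  if (is.list(weights)) {
    m <- matrix(NA_real_, length(teeth), length(stg),
                dimnames = list(teeth, stg))
    for (t in names(weights)) {
      if (!t %in% teeth) stop("unknown tooth in weight table: ", t)
      w <- unlist(weights[[t]])
      m[t, names(w)] <- as.numeric(w)
    }
    weights <- m
  }
  if (!is.matrix(weights) || !all(teeth %in% rownames(weights)) ||
      !all(stg %in% colnames(weights))) {
    stop("weights must cover all 7 teeth and 9 stages")
  }
  weights <- weights[teeth, stg, drop = FALSE]
  if (anyNA(weights)) stop("weight table has missing entries")
  if (any(abs(weights[, "0"]) > 1e-12)) {
    stop("weight at stage 0 must be zero for every tooth")
  }
  if (any(apply(weights, 1L, function(w) any(diff(w) < -1e-12)))) {
    stop("weights must be non-decreasing in stage order for every tooth")
  }
  tot <- sum(weights[, "H"])
  if (abs(tot - 100) > 1e-9) {
    stop("stage-H weights must sum to 100 (got ", format(tot), ")")
  }
  structure(list(sex = sex, weights = weights, provenance = provenance),
            class = "stage_weight_table")
}

#' @export
print.stage_weight_table <- function(x, ...) {
  cat(sprintf("<stage_weight_table> %s, provenance: %s\n",
              x$sex, x$provenance))
  print(round(x$weights, 2))
  invisible(x)
}

#' Largest single-stage weight increment of a table
#'
#' The score quantisation step: greedy stage decomposition can miss a
#' target score by at most this amount.
#'
#' @param table a [stage_weight_table()].
#' @return scalar increment in score units.
#' @export
max_stage_increment <- function(table) {
  max(apply(table$weights, 1L, function(w) max(diff(w))))
}

#' Read / write a stage weight table as JSON
#'
#' Schema: `{sex, provenance, weights: {tooth: {stage: number}}}`,
#' validated against the table invariants on load.
#'
#' @param path file path.
#' @return `read_weight_table()`: a [stage_weight_table()].
#' @export
read_weight_table <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("sex", "weights")) {
    if (is.null(doc[[f]])) stop("weight table ", path, ": missing field ", f)
  }
  stage_weight_table(doc$sex, doc$weights,
                     provenance = doc$provenance %||% "unspecified")
}

#' @rdname read_weight_table
#' @param table a [stage_weight_table()].
#' @export
write_weight_table <- function(table, path) {
  w <- lapply(rownames(table$weights), function(t) {
    as.list(table$weights[t, ])
  })
  names(w) <- rownames(table$weights)
  jsonlite::write_json(
    list(sex = table$sex, provenance = table$provenance, weights = w),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Synthetic demonstration weight table
#'
#' The original sex-specific self-weighted stage scores are not shipped
#' with this package; this constructor builds a synthetic table that
#' satisfies every structural invariant (zero at stage 0, monotone in
#' stage, stage-H total of 100) with dense, moderately increasing
#' increments, so the whole pipeline can be exercised and tested without
#' the reference values. The largest single increment is 3.6 score
#' units.
#'
#' @param sex `"male"` or `"female"`.
#' @return a [stage_weight_table()] labelled `"synthetic demo"`.
#' @export
demo_weight_table <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  # per-tooth stage-H totals (sum 100) and an increment shape over the
  # 8 stage advances; shapes sum to 20 so cumsum(shape)/20 * total is exact
  if (sex == "male") {
    tot <- c(I1 = 12, I2 = 11, C = 13, PM1 = 14, PM2 = 15, M1 = 17, M2 = 18)
    shape <- c(1, 1, 2, 2, 3, 3, 4, 4)
  } else {
    tot <- c(I1 = 13, I2 = 12, C = 12, PM1 = 14, PM2 = 14, M1 = 17, M2 = 18)
    shape <- c(1, 2, 2, 2, 3, 3, 3, 4)
  }
  w <- t(vapply(tot, function(h) c(0, cumsum(shape) / 20 * h),
                numeric(9L)))
  dimnames(w) <- list(names(tot), demirjian_stages())
  stage_weight_table(sex, w, provenance = "synthetic demo")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
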