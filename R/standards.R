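#' Population standards for score-to-age conversion
#'
#' A conversion standard maps a maturity score to a dental age. Two
#' parametric variants and one tabulated variant are supported, all
#' inheriting class `"conversion_standard"`:
#'
#' * `table_standard()` — a monotone lookup table of (score, age) pairs,
#'   evaluated exactly at grid points and by linear interpolation in
#'   between;
#' * `cubic_model()` — a cubic polynomial
#'   `age(x) = b0 + b1 x + b2 x^2 + b3 x^3` strictly increasing on its
#'   validity range (checked numerically on a 0.01 grid);
#' * `linear_model()` — `age(x) = intercept + slope * x`, slope > 0.
#'
#' `coverage` optionally narrows the validity window: a list with
#' elements `score = c(lo, hi)` and/or `age = c(lo, hi)`. Age coverage
#' models standards calibrated only on part of the age span (subjects
#' outside it are excluded from that standard's column in cohort
#' comparisons).
#'
#' @param name standard name (used as a column label downstream).
#' @param sex `"male"` or `"female"`.
#' @param scores,ages equal-length numeric vectors; `scores` strictly
#'   increasing, `ages` non-decreasing.
#' @param b0,b1,b2,b3 cubic coefficients (years, years/score, ...).
#' @param slope,intercept linear coefficients.
#' @param score_range numeric `c(smin, smax)` validity window within
#'   \[0, 100\].
#' @param coverage optional coverage list (see above).
#' @param provenance free-text origin label.
#' @param metadata optional list carried along verbatim (e.g. published
#'   rounded coefficients, fit diagnostics).
#' @return a `"conversion_standard"` object of the requested variant.
#' @name conversion_standard
NULL

new_standard <- function(variant, fields) {
  structure(c(list(variant = variant), fields),
            class = c(paste0(variant, "_standard"), "conversion_standard"))
}

#' @rdname conversion_standard
#' @export
table_standard <- function(name, sex, scores, ages, coverage = NULL,
                           provenance = "unspecified", metadata = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  scores <- as.numeric(scores)
  ages <- as.numeric(ages)
  if (length(scores) != length(ages)) stop("scores and ages differ in length")
  if (length(scores) > 0L) {
    if (any(diff(scores) <= 0)) stop("table scores must be strictly increasing")
    if (any(diff(ages) < 0)) stop("table ages must be non-decreasing")
  }
  coverage <- check_coverage(
    coverage,
    score_span = if (length(scores)) range(scores) else c(0, 0),
    age_span = if (length(ages)) range(ages) else c(0, 0))
  new_standard("table", list(name = name, sex = sex,
                             scores = scores, ages = ages,
                             coverage = coverage, provenance = provenance,
                             metadata = metadata))
}

#' @rdname conversion_standard
#' @export
cubic_model <- function(b0, b1, b2, b3, sex, score_range = c(0, 100),
                        name = "cubic", coverage = NULL,
                        provenance = "unspecified", metadata = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  score_range <- as.numeric(score_range)
  if (score_range[1] < 0 || score_range[2] > 100 ||
      score_range[1] >= score_range[2]) {
    stop("score_range must be an interval within [0, 100]")
  }
  coef <- as.numeric(c(b0, b1, b2, b3))
  if (anyNA(coef) || length(coef) != 4L) stop("need four finite coefficients")
  grid <- seq(score_range[1], score_range[2], by = 0.01)
  a <- eval_poly(coef, grid)
  if (any(diff(a) <= 0)) {
    stop("cubic model is not strictly increasing on [",
         score_range[1], ", ", score_range[2], "]")
  }
  coverage <- check_coverage(coverage, score_span = score_range,
                             age_span = range(a))
  new_standard("cubic", list(name = name, sex = sex,
                             coefficients = setNames(coef, paste0("b", 0:3)),
                             score_range = score_range, coverage = coverage,
                             provenance = provenance, metadata = metadata))
}

#' @rdname conversion_standard
#' @export
linear_model <- function(slope, intercept, sex, score_range = c(0, 100),
                         name = "linear", coverage = NULL,
                         provenance = "unspecified", metadata = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  if (slope <= 0) stop("linear model slope must be positive")
  score_range <- as.numeric(score_range)
  coverage <- check_coverage(
    coverage, score_span = score_range,
    age_span = intercept + slope * score_range)
  new_standard("linear", list(name = name, sex = sex,
                              slope = slope, intercept = intercept,
                              score_range = score_range, coverage = coverage,
                              provenance = provenance, metadata = metadata))
}

check_coverage <- function(coverage, score_span, age_span) {
  if (is.null(coverage)) coverage <- list()
  for (f in names(coverage)) {
    if (!f %in% c("score", "age")) stop("unknown coverage field: ", f)
    v <- as.numeric(coverage[[f]])
    if (length(v) != 2L || anyNA(v) || v[1] > v[2]) {
      stop("coverage$", f, " must be c(lo, hi)")
    }
    coverage[[f]] <- v
  }
  if (is.null(coverage$score)) coverage$score <- score_span
  if (is.null(coverage$age)) coverage$age <- age_span
  coverage
}

eval_poly <- function(coef, x) {
  # Horner; coef = (b0, b1, ..., bk)
  coef <- unname(coef)
  out <- rep(coef[length(coef)], length(x))
  for (k in rev(seq_len(length(coef) - 1L))) out <- out * x + coef[k]
  out
}

#' @export
print.conversion_standard <- function(x, ...) {
  cat(sprintf("<%s standard> %s (%s)\n", x$variant, x$name, x$sex))
  if (x$variant == "table") {
    cat(sprintf("  %d (score, age) pairs, scores %.1f-%.1f, ages %.3f-%.3f\n",
                length(x$scores), min(x$scores), max(x$scores),
                min(x$ages), max(x$ages)))
  } else if (x$variant == "cubic") {
    co <- x$coefficients
    cat(sprintf("  age(x) = %.4g + %.4g x + %.4g x^2 + %.4g x^3 on [%g, %g]\n",
                co[1], co[2], co[3], co[4],
                x$score_range[1], x$score_range[2]))
  } else {
    cat(sprintf("  age(x) = %.4g + %.4g x on [%g, %g]\n",
                x$intercept, x$slope, x$score_range[1], x$score_range[2]))
  }
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Convert maturity scores to dental age under a standard
#'
#' Table standards return the tabulated age exactly at grid scores and
#' linearly interpolate between adjacent pairs; polynomial standards are
#' evaluated directly. Scores outside the standard's score coverage are
#' rejected unless `extrapolate = TRUE`, in which case table standards
#' extend their end segments linearly, polynomials are evaluated as-is,
#' and the returned vector carries a logical `"extrapolated"` attribute
#' flagging the affected elements.
#'
#' @param score numeric vector of maturity scores.
#' @param standard a `"conversion_standard"`.
#' @param extrapolate allow evaluation outside the coverage window.
#' @return numeric vector of dental ages (years).
#' @export
score_to_age <- function(score, standard, extrapolate = FALSE) {
  UseMethod("score_to_age", standard)
}

#' @export
score_to_age.default <- function(score, standard, extrapolate = FALSE) {
  stop("not a conversion standard")
}

check_score_coverage <- function(score, standard, extrapolate) {
  cov <- standard$coverage$score
  outside <- score < cov[1] | score > cov[2]
  if (any(outside) && !extrapolate) {
    stop(sprintf(
      "score %s outside coverage [%g, %g] of standard '%s' (set extrapolate = TRUE to override)",
      format(score[which(outside)[1L]]), cov[1], cov[2], standard$name))
  }
  outside
}

#' @export
score_to_age.table_standard <- function(score, standard, extrapolate = FALSE) {
  outside <- check_score_coverage(score, standard, extrapolate)
  s <- standard$scores
  a <- standard$ages
  if (length(s) < 2L) {
    out <- rep(if (length(s)) a else NA_real_, length(score))
  } else {
    out <- approx(s, a, xout = pmin(pmax(score, s[1]), s[length(s)]),
                  method = "linear", ties = "ordered")$y
    # linear extension of the end segments when extrapolating
    lo <- score < s[1]
    hi <- score > s[length(s)]
    if (any(lo)) {
      sl <- (a[2] - a[1]) / (s[2] - s[1])
      out[lo] <- a[1] + sl * (score[lo] - s[1])
    }
    if (any(hi)) {
      k <- length(s)
      sl <- (a[k] - a[k - 1]) / (s[k] - s[k - 1])
      out[hi] <- a[k] + sl * (score[hi] - s[k])
    }
  }
  if (any(outside)) attr(out, "extrapolated") <- outside
  out
}

#' @export
score_to_age.cubic_standard <- function(score, standard, extrapolate = FALSE) {
  outside <- check_score_coverage(score, standard, extrapolate)
  out <- eval_poly(standard$coefficients, score)
  if (any(outside)) attr(out, "extrapolated") <- outside
  out
}

#' @export
score_to_age.linear_standard <- function(score, standard, extrapolate = FALSE) {
  outside <- check_score_coverage(score, standard, extrapolate)
  out <- standard$intercept + standard$slope * score
  if (any(outside)) attr(out, "extrapolated") <- outside
  out
}

#' Age span attainable under a standard
#'
#' @param standard a `"conversion_standard"`.
#' @return numeric `c(lo, hi)` in years (the coverage age window).
#' @export
age_range <- function(standard) standard$coverage$age

#' Does a standard cover a subject?
#'
#' @param standard a `"conversion_standard"`.
#' @param score maturity score(s).
#' @param ca_years chronological age(s); `NULL` skips the age check.
#' @return logical vector.
#' @export
covers <- function(standard, score, ca_years = NULL) {
  cs <- standard$coverage$score
  ok <- score >= cs[1] & score <= cs[2]
  if (!is.null(ca_years)) {
    cage <- standard$coverage$age
    ok <- ok & ca_years >= cage[1] & ca_years <= cage[2]
  }
  ok
}

#' Shift a standard's predicted ages by a constant offset
#'
#' Utility for building deliberately biased standards (e.g. to emulate a
#' systematic overestimation of known size in simulations).
#'
#' @param standard a `"conversion_standard"`.
#' @param offset years to add to every predicted age.
#' @param name name for the shifted standard.
#' @return a standard of the same variant.
#' @export
shift_standard <- function(standard, offset,
                           name = paste0(standard$name, "+", offset)) {
  prov <- paste0(standard$provenance, " (shifted ", offset, " yr)")
  cov <- standard$coverage
  cov$age <- cov$age + offset
  if (standard$variant == "table") {
    table_standard(name, standard$sex, standard$scores,
                   standard$ages + offset, coverage = cov,
                   provenance = prov)
  } else if (standard$variant == "cubic") {
    co <- standard$coefficients
    cubic_model(co[1] + offset, co[2], co[3], co[4], standard$sex,
                score_range = standard$score_range, name = name,
                coverage = cov, provenance = prov)
  } else {
    linear_model(standard$slope, standard$intercept + offset,
                 standard$sex, score_range = standard$score_range,
                 name = name, coverage = cov, provenance = prov)
  }
}

# ---- JSON (de)serialisation ------------------------------------------------

#' Load / save a conversion standard as JSON
#'
#' Schema:
#' `{name, sex, variant: "table"|"cubic"|"linear", pairs: [[score, age], ...]`
#' `| coefficients: {b0, b1, b2, b3} | {slope, intercept},`
#' `score_range, coverage: {score: [lo, hi], age: [lo, hi]}, provenance,`
#' `metadata}`. All structural invariants are re-validated on load;
#' `load_standard(save_standard(x))` is the identity on every field.
#'
#' @param path file path.
#' @return `load_standard()`: a `"conversion_standard"`.
#' @export
load_standard <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("name", "sex", "variant")) {
    if (is.null(doc[[f]])) stop("standard ", path, ": missing field $", f)
  }
  cov <- doc$coverage
  if (!is.null(cov)) cov <- lapply(cov, as.numeric)
  meta <- doc$metadata
  if (doc$variant == "table") {
    p <- doc$pairs
    if (is.null(p)) stop("standard ", path, ": missing field $pairs")
    if (!is.matrix(p)) {
      p <- matrix(as.numeric(unlist(p)), ncol = 2L, byrow = TRUE)
    }
    table_standard(doc$name, doc$sex, p[, 1], p[, 2], coverage = cov,
                   provenance = doc$provenance %||% "unspecified",
                   metadata = meta)
  } else if (doc$variant == "cubic") {
    co <- doc$coefficients
    for (b in paste0("b", 0:3)) {
      if (is.null(co[[b]])) stop("standard ", path,
                                 ": missing field $coefficients$", b)
    }
    cubic_model(co$b0, co$b1, co$b2, co$b3, doc$sex,
                score_range = as.numeric(doc$score_range %||% c(0, 100)),
                name = doc$name, coverage = cov,
                provenance = doc$provenance %||% "unspecified",
                metadata = meta)
  } else if (doc$variant == "linear") {
    co <- doc$coefficients
    if (is.null(co$slope) || is.null(co$intercept)) {
      stop("standard ", path, ": missing field $coefficients$slope/intercept")
    }
    linear_model(co$slope, co$intercept, doc$sex,
                 score_range = as.numeric(doc$score_range %||% c(0, 100)),
                 name = doc$name, coverage = cov,
                 provenance = doc$provenance %||% "unspecified",
                 metadata = meta)
  } else {
    stop("standard ", path, ": unknown variant tag '", doc$variant, "'")
  }
}

#' @rdname load_standard
#' @param standard a `"conversion_standard"`.
#' @export
save_standard <- function(standard, path) {
  doc <- list(name = standard$name, sex = standard$sex,
              variant = standard$variant)
  if (standard$variant == "table") {
    doc$pairs <- unname(Map(c, standard$scores, standard$ages))
  } else if (standard$variant == "cubic") {
    doc$coefficients <- as.list(standard$coefficients)
    doc$score_range <- standard$score_range
  } else {
    doc$coefficients <- list(slope = standard$slope,
                             intercept = standard$intercept)
    doc$score_range <- standard$score_range
  }
  doc$coverage <- standard$coverage
  doc$provenance <- standard$provenance
  if (!is.null(standard$metadata)) doc$metadata <- standard$metadata
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
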