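#' Fit a linear or cubic age-prediction model by least squares
#'
#' Fits chronological age as a polynomial function of maturity score —
#' age is the response because it is the unknown in a forensic case,
#' the score the observable. The design is centred and scaled
#' internally (fit in z = (x - mean)/sd) to keep the raw cubic basis
#' well conditioned at scores near 100, then mapped back to raw
#' coefficients.
#'
#' @param scores,ages equal-length numeric vectors of observations.
#' @param degree 1 (linear) or 3 (cubic).
#' @param sex `"male"` or `"female"`.
#' @param name name for the fitted standard.
#' @param provenance free-text origin label.
#' @return a [linear_model()] or [cubic_model()] whose validity range is
#'   the observed score span, with fit diagnostics (`rmse`, `r_squared`,
#'   `n`) in `$metadata$fit`.
#' @export
fit_polynomial <- function(scores, ages, degree = 3, sex,
                           name = sprintf("fitted degree-%d", degree),
                           provenance = "least-squares fit") {
  scores <- as.numeric(scores)
  ages <- as.numeric(ages)
  n <- length(scores)
  if (length(ages) != n) stop("scores and ages differ in length")
  if (!degree %in% c(1, 3)) stop("degree must be 1 or 3")
  if (n < degree + 1) stop("need at least degree + 1 observations")
  mu <- mean(scores)
  sdev <- sd(scores)
  if (!is.finite(sdev) || sdev == 0) stop("scores are all equal: rank-deficient design")
  z <- (scores - mu) / sdev
  X <- outer(z, 0:degree, `^`)
  fit <- tryCatch(stats::lm.fit(X, ages), error = function(e) {
    stop("least-squares fit failed: ", conditionMessage(e))
  })
  if (fit$rank < degree + 1) stop("rank-deficient design")
  coef_raw <- uncenter_poly(fit$coefficients, mu, sdev)
  res <- fit$residuals
  rmse <- sqrt(mean(res^2))
  sst <- sum((ages - mean(ages))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  meta <- list(fit = list(rmse = rmse, r_squared = r2, n = n))
  rng <- range(scores)
  if (degree == 1) {
    linear_model(coef_raw[2], coef_raw[1], sex, score_range = rng,
                 name = name, provenance = provenance, metadata = meta)
  } else {
    cubic_model(coef_raw[1], coef_raw[2], coef_raw[3], coef_raw[4], sex,
                score_range = rng, name = name, provenance = provenance,
                metadata = meta)
  }
}

# expand sum_k c_k ((x - mu)/s)^k into raw coefficients of x
uncenter_poly <- function(coef_z, mu, s) {
  d <- length(coef_z) - 1L
  out <- numeric(d + 1L)
  base <- 1  # coefficients of ((x - mu)/s)^k, built iteratively
  for (k in 0:d) {
    out[seq_along(base)] <- out[seq_along(base)] + coef_z[k + 1L] * base
    # multiply base polynomial by (x - mu)/s
    base <- c(-mu * base, 0) + c(0, base)
    base <- base / s
  }
  out
}

#' Tabulate a fitted model into a prediction table
#'
#' Evaluates a cubic (or linear) model on a grid of maturity scores and
#' returns a [table_standard()] with ages reported to 5 decimals —
#' the format of published score-to-age prediction tables.
#'
#' @param model a polynomial `"conversion_standard"`.
#' @param scores score grid (must lie within the model's validity range).
#' @param name name for the resulting table standard.
#' @return a [table_standard()]; empty `scores` give an empty table.
#' @export
generate_prediction_table <- function(model, scores,
                                      name = paste0(model$name, " table")) {
  if (!model$variant %in% c("cubic", "linear")) {
    stop("model must be a polynomial standard")
  }
  scores <- as.numeric(scores)
  if (length(scores) == 0L) {
    return(table_standard(name, model$sex, numeric(0), numeric(0),
                          provenance = model$provenance))
  }
  scores <- sort(unique(scores))
  ages <- round(score_to_age(scores, model), 5L)
  if (any(diff(ages) < 0)) {
    stop("model is not monotone over the requested scores")
  }
  table_standard(name, model$sex, scores, ages,
                 provenance = paste0("tabulated from: ", model$provenance))
}

#' Invert a monotone model: maturity score attaining a given age
#'
#' Solves `age(x) = age` by bisection on the model's validity range
#' (the model is strictly increasing there, so the root is unique).
#'
#' @param age target age(s) in years; must lie within
#'   `[age(smin), age(smax)]`.
#' @param model a polynomial `"conversion_standard"`.
#' @param tol absolute tolerance on the age scale (default 1e-10; the
#'   returned score satisfies `|age(score) - age| < tol`).
#' @param slack ages within `slack` years beyond the attainable range
#'   are clamped to the nearest endpoint rather than rejected (default
#'   1e-4, absorbing the 5-decimal rounding of published tables).
#' @return numeric vector of maturity scores.
#' @export
age_to_score <- function(age, model, tol = 1e-10, slack = 1e-4) {
  if (!model$variant %in% c("cubic", "linear")) {
    stop("model must be a polynomial standard")
  }
  rng <- model$score_range
  a_lo <- score_to_age(rng[1], model)
  a_hi <- score_to_age(rng[2], model)
  age <- as.numeric(age)
  eps <- slack
  if (any(age < a_lo - eps | age > a_hi + eps)) {
    bad <- age[which(age < a_lo - eps | age > a_hi + eps)[1L]]
    stop(sprintf("age %s outside attainable range [%.5f, %.5f]",
                 format(bad), a_lo, a_hi))
  }
  age <- pmin(pmax(age, a_lo), a_hi)
  vapply(age, function(a) {
    lo <- rng[1]; hi <- rng[2]
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      fm <- score_to_age(mid, model) - a
      if (abs(fm) < tol || (hi - lo) < 1e-13) return(mid)
      if (fm > 0) hi <- mid else lo <- mid
    }
    mid
  }, numeric(1L))
}
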