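#' Default cohort composition
#'
#' The per-(sex, 1-year age group) subject counts of the reference
#' cohort design: 217 boys and 205 girls aged 4-14 spread over the ten
#' groups.
#'
#' @return data.frame with columns `sex`, `age_group`, `lower`, `n`.
#' @export
default_cohort_counts <- function() {
  lower <- rep(4:13, times = 2L)
  data.frame(
    sex = rep(c("male", "female"), each = 10L),
    age_group = sprintf("%d.00-%d.99", lower, lower),
    lower = lower,
    n = c(7L, 12L, 26L, 28L, 26L, 30L, 30L, 16L, 30L, 12L,   # boys
          9L, 20L, 22L, 40L, 38L, 24L, 24L, 6L, 12L, 10L),   # girls
    stringsAsFactors = FALSE)
}

#' Configuration of a synthetic cohort
#'
#' The generator draws chronological ages uniformly within each
#' configured 1-year bin, inverts the generating model to a latent
#' maturity score, perturbs it with Gaussian rating noise of SD
#' `score_sd` (score units), clamps to the model's score range, and
#' quantises the noisy score into the seven tooth stages.
#'
#' @param counts data.frame as [default_cohort_counts()] (columns `sex`,
#'   `age_group`, `lower`, `n`).
#' @param models named list (`male`, `female`) of generating polynomial
#'   standards; defaults to the refit Saudi cubic models.
#' @param score_sd rating-noise SD on the maturity-score scale
#'   (default 2 score units — roughly one stage step of a dense table).
#' @param on_uncovered what to do with age bins outside a generating
#'   model's attainable age span: `"clamp"` (default) clamps the drawn
#'   age into the span before score inversion, so children older than
#'   the age at score 100 saturate at full maturity — the realistic
#'   behaviour for a method that tops out near age 13; `"error"`
#'   rejects any configured bin that lies entirely outside the span,
#'   naming the bin.
#' @param seed optional integer seed for reproducibility.
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(counts = default_cohort_counts(),
                          models = NULL, score_sd = 2,
                          on_uncovered = c("clamp", "error"),
                          seed = NULL) {
  on_uncovered <- match.arg(on_uncovered)
  if (is.null(models)) {
    models <- list(male = saudi_standard("male", "cubic"),
                   female = saudi_standard("female", "cubic"))
  }
  stopifnot(all(c("sex", "lower", "n") %in% names(counts)),
            all(counts$n >= 0), score_sd >= 0)
  for (sx in unique(counts$sex)) {
    if (is.null(models[[sx]])) stop("no generating model for sex ", sx)
  }
  structure(list(counts = counts, models = models,
                 score_sd = score_sd, on_uncovered = on_uncovered,
                 seed = seed),
            class = "cohort_config")
}

#' Quantise a target maturity score into tooth stages
#'
#' Greedy round-robin stage advancement: repeatedly sweeps the seven
#' teeth in canonical order, advancing each tooth one stage whenever
#' the cumulative weight stays at or below the target. The resulting
#' stage map scores at most `target` and within one maximal
#' single-stage weight increment of it (teeth in a child advance
#' roughly in parallel, which this emulates; exact subset-sum matching
#' is unnecessary given the quantisation bound).
#'
#' @param target_score number in \[0, 100\].
#' @param table a [stage_weight_table()].
#' @return named character vector of stages (a valid `stages` argument
#'   for [tooth_stage_rating()]), with the achieved score in attribute
#'   `"score"`.
#' @export
decompose_score_to_stages <- function(target_score, table) {
  stopifnot(inherits(table, "stage_weight_table"))
  if (target_score < 0 || target_score > 100) {
    stop("target_score must be in [0, 100]")
  }
  w <- table$weights
  teeth <- demirjian_teeth()
  idx <- setNames(rep(1L, length(teeth)), teeth)  # column index: 1 = stage 0
  total <- 0
  repeat {
    advanced <- FALSE
    for (t in teeth) {
      if (idx[[t]] < ncol(w)) {
        inc <- w[t, idx[[t]] + 1L] - w[t, idx[[t]]]
        if (total + inc <= target_score + 1e-9) {
          idx[[t]] <- idx[[t]] + 1L
          total <- total + inc
          advanced <- TRUE
        }
      }
    }
    if (!advanced) break
  }
  stages <- setNames(demirjian_stages()[idx], teeth)
  attr(stages, "score") <- total
  stages
}

#' Simulate a cohort of tooth-stage ratings with known ground truth
#'
#' @param config a [cohort_config()].
#' @param weight_tables named list (`male`, `female`) of
#'   [stage_weight_table()]s used to quantise scores into stages.
#' @return list of class `"dentage_cohort"`: `ratings` (list of
#'   [tooth_stage_rating()]), `truth` (data.frame with `subject_id`,
#'   `sex`, `age_group`, `ca_years`, `latent_score`, `stage_score`),
#'   and `config`.
#' @details Drawn ages outside a generating model's attainable age
#'   range are clamped into it before score inversion (the drawn
#'   chronological age is kept as truth), so subjects past the age of
#'   full maturity saturate at the top score; with
#'   `on_uncovered = "error"` in the config, bins lying entirely
#'   outside the range are instead rejected by name.
#' @export
simulate_cohort <- function(config, weight_tables) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  counts <- config$counts
  rows <- list()
  ratings <- list()
  serial <- c(male = 0L, female = 0L)
  for (r in seq_len(nrow(counts))) {
    sx <- counts$sex[r]
    lo <- counts$lower[r]
    n <- counts$n[r]
    if (n == 0L) next
    model <- config$models[[sx]]
    wt <- weight_tables[[sx]]
    if (is.null(wt)) stop("no weight table for sex ", sx)
    ar <- c(score_to_age(model$score_range[1], model),
            score_to_age(model$score_range[2], model))
    if ((lo + 1 <= ar[1] || lo >= ar[2]) &&
        identical(config$on_uncovered, "error")) {
      stop("generating model for ", sx, " cannot cover age group ",
           counts$age_group[r])
    }
    ca <- runif(n, lo, lo + 1)
    latent <- age_to_score(pmin(pmax(ca, ar[1]), ar[2]), model) +
      rnorm(n, 0, config$score_sd)
    latent <- pmin(pmax(latent, model$score_range[1]),
                   model$score_range[2])
    for (i in seq_len(n)) {
      serial[sx] <- serial[sx] + 1L
      id <- sprintf("%s%03d", toupper(substr(sx, 1L, 1L)), serial[sx])
      stages <- decompose_score_to_stages(latent[i], wt)
      ratings[[length(ratings) + 1L]] <-
        tooth_stage_rating(id, sx, stages, ca_years = ca[i])
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, sex = sx, age_group = counts$age_group[r],
        ca_years = ca[i], latent_score = latent[i],
        stage_score = attr(stages, "score"),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(ratings = ratings, truth = do.call(rbind, rows),
                 config = config),
            class = "dentage_cohort")
}

#' @export
print.dentage_cohort <- function(x, ...) {
  tb <- table(x$truth$sex)
  cat(sprintf("<dentage_cohort> %d subjects (%s)\n", nrow(x$truth),
              paste(sprintf("%s: %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Refit the generating model from a simulated cohort
#'
#' Closes the loop of the simulation study: recomputes each subject's
#' maturity score from the quantised stages, refits a cubic of
#' chronological age on score per sex, and reports the coefficient
#' error against the generating model — the parameter-recovery check
#' for the calibration procedure.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param weight_tables named list of [stage_weight_table()]s.
#' @param degree polynomial degree of the refit (default 3).
#' @return named list per sex: `model` (the refit standard),
#'   `coef_error` (refit minus generating coefficients, polynomial
#'   variants only), `n`.
#' @export
recover_model <- function(cohort, weight_tables, degree = 3) {
  stopifnot(inherits(cohort, "dentage_cohort"))
  if (length(cohort$ratings) == 0L) stop("empty cohort")
  scored <- score_cohort(cohort$ratings, weight_tables)
  out <- list()
  for (sx in unique(scored$sex)) {
    s <- scored[scored$sex == sx, ]
    fitted <- fit_polynomial(s$maturity_score, s$ca_years, degree = degree,
                             sex = sx, name = paste("recovered", sx),
                             provenance = "refit from simulated cohort")
    gen <- cohort$config$models[[sx]]
    err <- NULL
    if (degree == 3 && gen$variant == "cubic") {
      err <- fitted$coefficients - gen$coefficients
    }
    out[[sx]] <- list(model = fitted, coef_error = err, n = nrow(s))
  }
  out
}
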