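#' Estimate dental ages for a cohort under several standards
#'
#' Runs the full per-subject pipeline: maturity score from the sex's
#' weight table, then one dental-age estimate and one DA - CA
#' difference per standard. Standards whose coverage (score and/or age
#' window) excludes a subject contribute `NA` for that subject —
#' mirroring how partially calibrated standards leave younger age
#' groups blank.
#'
#' @param ratings list of [tooth_stage_rating()] objects.
#' @param weight_tables named list (`male`, `female`) of
#'   [stage_weight_table()]s.
#' @param standards list of `"conversion_standard"`s; each is applied
#'   only to subjects of its own sex. Two standards may share one name
#'   (the male and female variant of a population standard); they then
#'   fill the same output column.
#' @param extrapolate evaluate standards outside their score coverage
#'   instead of returning `NA`.
#' @return data.frame with one row per subject: `subject_id`, `sex`,
#'   `ca_years`, `age_group`, `maturity_score`, then `da_<name>` and
#'   `diff_<name>` per standard (`diff = da - ca`).
#' @export
estimate_cohort <- function(ratings, weight_tables, standards,
                            extrapolate = FALSE) {
  if (length(standards) == 0L) stop("need at least one standard")
  nms <- names(standards)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- vapply(standards, `[[`, "", "name")
  }
  df <- score_cohort(ratings, weight_tables)
  for (nm in unique(nms)) {
    da <- rep(NA_real_, nrow(df))
    for (std in standards[nms == nm]) {
      sel <- df$sex == std$sex
      if (!any(sel)) next
      if (extrapolate) {
        da[sel] <- as.numeric(score_to_age(df$maturity_score[sel], std,
                                           extrapolate = TRUE))
      } else {
        ok <- sel & covers(std, df$maturity_score, df$ca_years)
        if (any(ok)) {
          da[ok] <- as.numeric(score_to_age(df$maturity_score[ok], std))
        }
      }
    }
    df[[paste0("da_", nm)]] <- da
    df[[paste0("diff_", nm)]] <- da - df$ca_years
  }
  df
}

#' Paired t-test of mean difference against zero
#'
#' @param differences numeric vector of per-subject differences
#'   (e.g. DA - CA), length >= 2.
#' @param conf confidence level for the interval (default 0.95).
#' @return list with `t`, `df`, `p` (two-sided), `ci` (`c(lo, hi)`),
#'   `mean`, `sd`, `n`, and `degenerate = TRUE` when sd = 0.
#' @export
paired_t <- function(differences, conf = 0.95) {
  x <- as.numeric(differences)
  n <- length(x)
  if (n < 2L) stop("need at least 2 differences")
  m <- mean(x)
  s <- sd(x)
  if (s == 0) {
    # all differences identical: t degenerates
    p <- if (m == 0) 1 else 0
    return(list(t = if (m == 0) 0 else sign(m) * Inf, df = n - 1L, p = p,
                ci = c(m, m), mean = m, sd = s, n = n, degenerate = TRUE))
  }
  se <- s / sqrt(n)
  tstat <- m / se
  half <- qt(1 - (1 - conf) / 2, n - 1L) * se
  list(t = tstat, df = n - 1L, p = 2 * pt(-abs(tstat), n - 1L),
       ci = c(m - half, m + half), mean = m, sd = s, n = n,
       degenerate = FALSE)
}

#' Per-age-group summary of DA - CA for one standard
#'
#' For each 1-year age group (and a pooled `Total` row): group size,
#' mean and SD of the differences, the 95% confidence interval
#' `mean +/- t(0.975, n-1) sd/sqrt(n)`, and the paired-t p-value against
#' zero. Groups with a single subject report the mean only.
#'
#' @param results data.frame from [estimate_cohort()].
#' @param standard standard name (the `<name>` of a `diff_<name>`
#'   column) or a `"conversion_standard"`.
#' @param sex optional `"male"`/`"female"` filter.
#' @param conf confidence level.
#' @return data.frame with columns `age_group`, `n`, `mean`, `sd`,
#'   `ci_lo`, `ci_hi`, `p`; the last row is the pooled total.
#' @export
group_summary <- function(results, standard, sex = NULL, conf = 0.95) {
  nm <- if (inherits(standard, "conversion_standard")) standard$name
        else standard
  col <- paste0("diff_", nm)
  if (!col %in% names(results)) {
    stop("no column '", col, "' in results; available standards: ",
         paste(sub("^diff_", "", grep("^diff_", names(results), value = TRUE)),
               collapse = ", "))
  }
  if (!is.null(sex)) results <- results[results$sex == sex, , drop = FALSE]
  results <- results[!is.na(results[[col]]), , drop = FALSE]
  if (nrow(results) == 0L) stop("no subjects with a value for ", nm)
  one <- function(label, d) {
    n <- length(d)
    if (n == 1L) {
      return(data.frame(age_group = label, n = 1L, mean = d,
                        sd = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    tt <- paired_t(d, conf)
    data.frame(age_group = label, n = n, mean = tt$mean, sd = tt$sd,
               ci_lo = tt$ci[1], ci_hi = tt$ci[2], p = tt$p,
               stringsAsFactors = FALSE)
  }
  grp <- factor(results$age_group,
                levels = intersect(age_group_levels(),
                                   unique(results$age_group)))
  parts <- lapply(levels(grp), function(g) {
    one(g, results[[col]][!is.na(grp) & grp == g])
  })
  parts <- parts[vapply(parts, nrow, 1L) > 0]
  rbind(do.call(rbind, parts), one("Total", results[[col]]))
}

#' Sample-size-weighted mean of group means
#'
#' `sum(n * mean) / sum(n)`; equals the pooled per-subject mean exactly
#' when the group means are unrounded.
#'
#' @param n group sizes (all >= 1).
#' @param means group means.
#' @return scalar weighted mean.
#' @export
weighted_total <- function(n, means) {
  if (length(n) == 0L) stop("no groups")
  if (length(n) != length(means)) stop("n and means differ in length")
  if (any(n < 1)) stop("group sizes must be >= 1")
  sum(n * means) / sum(n)
}

#' One-way analysis of variance across standards
#'
#' Classical fixed-effects one-way ANOVA: F is the ratio of the
#' between-group to within-group mean square.
#'
#' @param samples named list of numeric vectors (>= 2 groups, each of
#'   size >= 2), e.g. the per-standard DA - CA differences.
#' @return list with `F`, `df_between`, `df_within`, `p`, `ms_within`,
#'   `means`, `n`, `grand_mean`.
#' @export
oneway_anova <- function(samples) {
  k <- length(samples)
  if (k < 2L) stop("need at least 2 groups")
  n <- vapply(samples, length, 1L)
  if (any(n < 2L)) stop("every group needs n >= 2")
  means <- vapply(samples, mean, 1)
  N <- sum(n)
  grand <- sum(unlist(samples)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(samples, function(x) sum((x - mean(x))^2), 1))
  dfb <- k - 1L
  dfw <- N - k
  if (ssw <= 0) stop("zero within-group variance everywhere")
  msw <- ssw / dfw
  Fstat <- (ssb / dfb) / msw
  list(F = Fstat, df_between = dfb, df_within = dfw,
       p = pf(Fstat, dfb, dfw, lower.tail = FALSE),
       ms_within = msw, means = means, n = n, grand_mean = grand)
}

#' Scheffe post hoc pairwise contrasts
#'
#' For every ordered pair of groups (i, j): the mean difference, its
#' standard error `sqrt(MSW (1/ni + 1/nj))`, the Scheffe-adjusted
#' p-value `P(F(k-1, N-k) >= (diff/SE)^2 / (k-1))`, and the
#' simultaneous confidence interval with half-width
#' `sqrt((k-1) F_crit) SE`. The table is exactly antisymmetric in the
#' mean difference.
#'
#' @inheritParams oneway_anova
#' @param alpha simultaneous significance level (default 0.05).
#' @return data.frame with columns `group_i`, `group_j`, `mean_diff`,
#'   `se`, `p_adj`, `ci_lo`, `ci_hi`, `significant`.
#' @export
scheffe_pairwise <- function(samples, alpha = 0.05) {
  av <- oneway_anova(samples)
  k <- length(samples)
  nms <- names(samples) %||% as.character(seq_len(k))
  fcrit <- qf(1 - alpha, av$df_between, av$df_within)
  half_mult <- sqrt(av$df_between * fcrit)
  pairs <- expand.grid(j = seq_len(k), i = seq_len(k))
  pairs <- pairs[pairs$i != pairs$j, c("i", "j")]
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$i[r]; j <- pairs$j[r]
    d <- av$means[i] - av$means[j]
    se <- sqrt(av$ms_within * (1 / av$n[i] + 1 / av$n[j]))
    stat <- (d / se)^2 / av$df_between
    data.frame(group_i = nms[i], group_j = nms[j], mean_diff = d,
               se = se,
               p_adj = pf(stat, av$df_between, av$df_within,
                          lower.tail = FALSE),
               ci_lo = d - half_mult * se, ci_hi = d + half_mult * se,
               stringsAsFactors = FALSE)
  }))
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Scheffe homogeneous subsets
#'
#' Sorts the group means ascending and reports maximal runs of
#' consecutive groups whose pairwise Scheffe comparisons are all
#' non-significant at `alpha`. Following the convention of mainstream
#' statistical software for unequal group sizes, the subset-building
#' standard error uses the harmonic mean of all group sizes, so within
#' a sorted run all pairwise tests share one SE and the run is
#' homogeneous iff its extreme pair is; each subset's reported
#' `significance` is the adjusted p of that extreme-pair comparison
#' (1 for singletons).
#'
#' @inheritParams scheffe_pairwise
#' @return list of class `"scheffe_subsets"`: `subsets` (each with
#'   `groups`, `means`, `significance`), `harmonic_n`, `alpha`,
#'   `means` (sorted), plus the underlying `anova`.
#' @export
scheffe_subsets <- function(samples, alpha = 0.05) {
  av <- oneway_anova(samples)
  k <- length(samples)
  nms <- names(samples) %||% as.character(seq_len(k))
  ord <- order(av$means)
  means <- av$means[ord]
  nms <- nms[ord]
  nh <- k / sum(1 / av$n)
  se <- sqrt(av$ms_within * 2 / nh)
  pair_p <- function(i, j) {
    stat <- ((means[j] - means[i]) / se)^2 / av$df_between
    pf(stat, av$df_between, av$df_within, lower.tail = FALSE)
  }
  # maximal end of a homogeneous run starting at i
  ends <- vapply(seq_len(k), function(i) {
    e <- i
    while (e < k && pair_p(i, e + 1L) >= alpha) e <- e + 1L
    e
  }, 1L)
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) {
    # drop runs contained in an earlier (wider) one
    if (i > 1L && any(ends[seq_len(i - 1L)] >= ends[i])) keep[i] <- FALSE
  }
  subsets <- lapply(which(keep), function(i) {
    idx <- i:ends[i]
    list(groups = nms[idx], means = unname(means[idx]),
         significance = if (length(idx) > 1L) pair_p(i, ends[i]) else 1)
  })
  structure(list(subsets = subsets, harmonic_n = nh, alpha = alpha,
                 means = setNames(unname(means), nms), anova = av),
            class = "scheffe_subsets")
}

#' @export
print.scheffe_subsets <- function(x, ...) {
  cat(sprintf("Scheffe homogeneous subsets (alpha = %g, harmonic n = %.2f)\n",
              x$alpha, x$harmonic_n))
  for (i in seq_along(x$subsets)) {
    s <- x$subsets[[i]]
    cat(sprintf("  subset %s: %s  (means %s; significance %.3f)\n",
                letters[i],
                paste(s$groups, collapse = ", "),
                paste(sprintf("%.2f", s$means), collapse = ", "),
                s$significance))
  }
  invisible(x)
}
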