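#' Full method-comparison report
#'
#' Assembles, per sex: the group-by-standard DA - CA summary table,
#' size-weighted totals per standard, the one-way ANOVA across
#' standards (on all subjects covered by each standard), the Scheffe
#' pairwise table and the homogeneous subsets.
#'
#' @param results data.frame from [estimate_cohort()].
#' @param standards character vector of standard names to compare
#'   (default: every `diff_*` column present).
#' @param alpha significance level for the post hoc procedures.
#' @return object of class `"method_comparison_report"`: a list with
#'   one element per sex, each holding `groups` (tidy data.frame),
#'   `totals`, `anova`, `scheffe_pairwise`, `scheffe_subsets`, plus
#'   `alpha`.
#' @export
comparison_report <- function(results, standards = NULL, alpha = 0.05) {
  found <- sub("^diff_", "", grep("^diff_", names(results), value = TRUE))
  if (is.null(standards)) standards <- found
  missing <- setdiff(standards, found)
  if (length(missing)) {
    stop("results carry no columns for standard(s): ",
         paste(missing, collapse = ", "))
  }
  out <- list(alpha = alpha)
  for (sx in intersect(c("male", "female"), unique(results$sex))) {
    rs <- results[results$sex == sx, , drop = FALSE]
    avail <- standards[vapply(standards, function(nm) {
      any(!is.na(rs[[paste0("diff_", nm)]]))
    }, TRUE)]
    groups <- do.call(rbind, lapply(avail, function(nm) {
      g <- group_summary(rs, nm)
      cbind(standard = nm, g, stringsAsFactors = FALSE)
    }))
    totals <- groups[groups$age_group == "Total",
                     c("standard", "n", "mean", "sd")]
    rownames(totals) <- NULL
    samples <- lapply(avail, function(nm) {
      d <- rs[[paste0("diff_", nm)]]
      d[!is.na(d)]
    })
    names(samples) <- avail
    enough <- length(samples) >= 2L &&
      all(vapply(samples, length, 1L) >= 2L)
    out[[sx]] <- list(
      groups = groups, totals = totals,
      anova = if (enough) oneway_anova(samples) else NULL,
      scheffe_pairwise = if (enough) scheffe_pairwise(samples, alpha)
                         else NULL,
      scheffe_subsets = if (enough) scheffe_subsets(samples, alpha)
                        else NULL)
    if (!enough) {
      message("sex ", sx, ": fewer than 2 usable standards, ",
              "ANOVA/post hoc skipped")
    }
  }
  structure(out, class = "method_comparison_report")
}

#' @export
print.method_comparison_report <- function(x, ...) {
  for (sx in intersect(c("male", "female"), names(x))) {
    r <- x[[sx]]
    cat("==", sx, "==\n")
    t <- r$totals
    for (i in seq_len(nrow(t))) {
      cat(sprintf("  %-16s n=%3d  DA-CA %.2f (%.2f)\n",
                  t$standard[i], t$n[i], t$mean[i], t$sd[i]))
    }
    if (!is.null(r$anova)) {
      cat(sprintf("  ANOVA F(%d, %d) = %.2f, p = %.3g\n",
                  r$anova$df_between, r$anova$df_within,
                  r$anova$F, r$anova$p))
      print(r$scheffe_subsets)
    }
  }
  invisible(x)
}

#' Write a comparison report to tidy CSV and JSON
#'
#' `write_report_csv()` writes one row per sex x standard x age group
#' with fixed columns
#' `sex,standard,age_group,n,mean,sd,ci_lo,ci_hi,p` (means/SDs at full
#' precision; round on display). `write_report_json()` mirrors the full
#' report structure.
#'
#' @param report a [comparison_report()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_report_csv <- function(report, path) {
  rows <- do.call(rbind, lapply(
    intersect(c("male", "female"), names(report)),
    function(sx) cbind(sex = sx, report[[sx]]$groups,
                       stringsAsFactors = FALSE)))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
write_report_json <- function(report, path) {
  ser <- list(alpha = report$alpha)
  for (sx in intersect(c("male", "female"), names(report))) {
    r <- report[[sx]]
    ser[[sx]] <- list(
      groups = r$groups, totals = r$totals,
      anova = if (is.null(r$anova)) NULL else
        r$anova[c("F", "df_between", "df_within", "p")],
      scheffe_pairwise = r$scheffe_pairwise,
      scheffe_subsets = if (is.null(r$scheffe_subsets)) NULL else list(
        harmonic_n = r$scheffe_subsets$harmonic_n,
        subsets = r$scheffe_subsets$subsets))
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
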