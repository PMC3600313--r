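test_that("estimate_cohort composes scoring and conversion", {
  wt <- demo_tables()
  # one subject, one table standard containing the subject's exact score
  r <- uniform_rating("D", ca = 6.5)           # demo male table: D -> 30
  sc <- maturity_score(r, wt$male)
  tab <- table_standard("t", "male", c(sc - 5, sc, sc + 5),
                        c(6.0, 7.0, 8.0), coverage = list(age = c(4, 14)))
  res <- estimate_cohort(list(r), wt, list(tab))
  expect_equal(res$da_t, 7.0)
  expect_equal(res$diff_t, 7.0 - 6.5)

  # a standard whose age coverage starts at 7.5 leaves a CA-5.2 subject NA
  r2 <- uniform_rating("D", ca = 5.2, id = "S2")
  tab2 <- table_standard("late", "male", c(0, 100), c(7.5, 14),
                         coverage = list(age = c(7.5, 14)))
  res2 <- estimate_cohort(list(r, r2), wt, list(tab2))
  expect_true(is.na(res2$da_late[res2$subject_id == "S2"]))

  # sex-paired standards fill one column
  rf <- uniform_rating("D", sex = "female", id = "S3", ca = 6.5)
  tabf <- table_standard("t", "female", c(0, 100), c(4, 13))
  res3 <- estimate_cohort(list(r, rf), wt, list(tab, tabf))
  expect_false(any(is.na(res3$da_t)))
})

test_that("zero-noise simulated cohort scores back to the latent curve", {
  wt <- demo_tables()
  # fine-grained table standard built from the generating model so the
  # subject's exact quantised score is on the grid
  gen <- demo_generating_model("male")
  counts <- data.frame(sex = "male", age_group = "8.00-8.99",
                       lower = 8, n = 20)
  cfg <- cohort_config(counts, models = list(male = gen), score_sd = 0,
                       seed = 31)
  ch <- simulate_cohort(cfg, wt)
  grid <- sort(unique(ch$truth$stage_score))
  # coverage widened past the grid: recomputed scores can sit one
  # floating-point ulp below the lowest tabulated score
  tab <- table_standard("gen", "male", grid,
                        score_to_age(grid, gen),
                        coverage = list(score = c(0, 100),
                                        age = c(0, 20)))
  res <- estimate_cohort(ch$ratings, wt, list(tab))
  # DA equals the curve at the quantised score; difference from CA is
  # bounded by the age-equivalent of the quantisation gap (tested as the
  # acceptance inverse-pair at full scale)
  expect_equal(res$da_gen, score_to_age(ch$truth$stage_score, gen),
               tolerance = 1e-9)
})

test_that("paired t and group summary reproduce the published 13-year row", {
  # reconstruct any sample with mean -0.12, sd 0.69, n 12
  x <- sample_with_moments(12, -0.12, 0.69)
  tt <- paired_t(x)
  expect_equal(round(tt$ci, 2), c(-0.56, 0.32))
  expect_equal(tt$p, 0.557, tolerance = 0.01)
  # against R's own t.test as oracle
  or <- t.test(x)
  expect_equal(tt$t, unname(or$statistic), tolerance = 1e-12)
  expect_equal(tt$p, or$p.value, tolerance = 1e-12)
  expect_equal(tt$ci, unname(or$conf.int), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("paired t degenerate cases", {
  expect_equal(paired_t(rep(0, 6))$p, 1)
  expect_equal(paired_t(rep(0, 6))$t, 0)
  d <- paired_t(rep(0.4, 5))
  expect_true(d$degenerate)
  expect_equal(d$p, 0)
  set.seed(3)
  x <- rnorm(5)
  expect_equal(paired_t(x)$t, mean(x) / (sd(x) / sqrt(5)),
               tolerance = 1e-12)
})

test_that("group summary structure: n = 1 cells and totals", {
  wt <- demo_tables()
  set.seed(17)
  ratings <- c(lapply(1:5, function(i)
    random_rating(sprintf("A%d", i), ca = runif(1, 6, 7))),
    list(random_rating("B1", ca = 9.5)))
  tab <- table_standard("t", "male", c(0, 100), c(4, 14),
                        coverage = list(age = c(4, 14)))
  res <- estimate_cohort(ratings, wt, list(tab))
  g <- group_summary(res, "t", sex = "male")
  expect_identical(g$age_group, c("6.00-6.99", "9.00-9.99", "Total"))
  one <- g[g$age_group == "9.00-9.99", ]
  expect_equal(one$n, 1L)
  expect_true(is.na(one$sd) && is.na(one$p))
  # single group equals total when there is one group
  res5 <- res[res$age_group == "6.00-6.99", ]
  g5 <- group_summary(res5, "t")
  expect_equal(g5$mean[1], g5$mean[2])
})

test_that("weighted totals reproduce the published whole-sample rows", {
  pub <- published_group_stats()
  # the comparison-table French-Canadian columns weight exactly to the
  # printed totals
  fc <- pub[pub$standard == "french_canadian", ]
  boys <- fc[fc$sex == "male", ]
  girls <- fc[fc$sex == "female", ]
  expect_equal(round(weighted_total(boys$n, boys$mean_diff), 2), 0.76)
  expect_equal(round(weighted_total(girls$n, girls$mean_diff), 2), 0.83)
  expect_equal(round(weighted_total(c(boys$n, girls$n),
                                    c(boys$mean_diff, girls$mean_diff)),
                     2), 0.80)
  # the summary-table DA-CA rows weight to the value quoted in the
  # running text (0.77 for boys; the table's own total row prints 0.76,
  # an internal rounding discrepancy of the source) and stay within one
  # display ulp of the printed total
  t1b <- pub[pub$standard == "table1_da_ca" & pub$sex == "male", ]
  wtb <- weighted_total(t1b$n, t1b$mean_diff)
  expect_equal(round(wtb, 2), 0.77)
  expect_lt(abs(wtb - 0.76), 0.01)
  # identities
  expect_equal(weighted_total(5, 1.3), 1.3)
  expect_equal(weighted_total(c(4, 4), c(1, 3)), 2)
  expect_error(weighted_total(numeric(0), numeric(0)), "no groups")
  # pooled-mean identity on per-subject data
  set.seed(8)
  d <- rnorm(60)
  grp <- sample(1:4, 60, replace = TRUE)
  expect_equal(weighted_total(tabulate(grp), tapply(d, grp, mean)),
               mean(d), tolerance = 1e-12)
})

test_that("one-way ANOVA matches oracles and its invariances", {
  set.seed(12)
  samples <- lapply(1:3, function(i) rnorm(10, i * 0.2))
  names(samples) <- paste0("g", 1:3)
  av <- oneway_anova(samples)
  # brute-force sums of squares
  all_x <- unlist(samples)
  grand <- mean(all_x)
  ssb <- sum(vapply(samples, function(x)
    length(x) * (mean(x) - grand)^2, 1))
  ssw <- sum(vapply(samples, function(x) sum((x - mean(x))^2), 1))
  Fref <- (ssb / 2) / (ssw / 27)
  expect_equal(av$F, Fref, tolerance = 1e-10)
  # R's aov as independent route
  dat <- data.frame(y = all_x,
                    g = rep(names(samples), each = 10))
  ref <- summary(aov(y ~ g, dat))[[1]]
  expect_equal(av$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(av$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)

  # identical groups -> F = 0
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(oneway_anova(same)$F, 0)
  # two groups: F equals squared pooled-t
  two <- list(a = rnorm(8), b = rnorm(12, 0.5))
  tt <- t.test(two$a, two$b, var.equal = TRUE)
  expect_equal(oneway_anova(two)$F, unname(tt$statistic)^2,
               tolerance = 1e-10)
  # invariant under relabeling and constant shifts
  expect_equal(oneway_anova(rev(samples))$F, av$F, tolerance = 1e-12)
  shifted <- lapply(samples, `+`, 100)
  expect_equal(oneway_anova(shifted)$F, av$F, tolerance = 1e-8)
  expect_error(oneway_anova(list(a = 1:3)), "2 groups")
  expect_error(oneway_anova(list(a = c(1, 1), b = c(2, 2))),
               "zero within-group")
})

test_that("Scheffe pairwise: formula oracle, antisymmetry, conservatism", {
  set.seed(14)
  k <- 4
  samples <- lapply(1:k, function(i) rnorm(5 + 2 * i, i * 0.3))
  names(samples) <- LETTERS[1:k]
  sp <- scheffe_pairwise(samples)
  av <- oneway_anova(samples)
  N <- sum(av$n)
  for (r in seq_len(nrow(sp))) {
    i <- sp$group_i[r]; j <- sp$group_j[r]
    d <- mean(samples[[i]]) - mean(samples[[j]])
    se <- sqrt(av$ms_within * (1 / length(samples[[i]]) +
                                 1 / length(samples[[j]])))
    expect_equal(sp$mean_diff[r], d, tolerance = 1e-12)
    expect_equal(sp$se[r], se, tolerance = 1e-12)
    expect_equal(sp$p_adj[r],
                 pf((d / se)^2 / (k - 1), k - 1, N - k,
                    lower.tail = FALSE), tolerance = 1e-12)
    # antisymmetry
    mirror <- sp[sp$group_i == j & sp$group_j == i, ]
    expect_equal(sp$mean_diff[r], -mirror$mean_diff)
    expect_equal(sp$p_adj[r], mirror$p_adj)
    # conservatism vs unadjusted pairwise pooled-variance t
    t_p <- 2 * pt(-abs(d / se), N - k)
    expect_gte(sp$p_adj[r] + 1e-12, t_p)
    # CI half width
    expect_equal(sp$ci_hi[r] - sp$mean_diff[r],
                 sqrt((k - 1) * qf(0.95, k - 1, N - k)) * se,
                 tolerance = 1e-12)
  }
  # identical groups -> all adjusted p near 1
  same <- lapply(1:3, function(i) c(1, 2, 3, 4))
  names(same) <- letters[1:3]
  expect_true(all(scheffe_pairwise(same)$p_adj > 0.999))
})

test_that("Scheffe homogeneous subsets: degenerate and separated cases", {
  set.seed(15)
  # all groups drawn identically -> one subset with every standard
  same <- lapply(1:4, function(i) rnorm(12))
  names(same) <- paste0("s", 1:4)
  ss <- scheffe_subsets(same)
  expect_length(ss$subsets, 1)
  expect_setequal(ss$subsets[[1]]$groups, names(same))

  # widely separated means -> all singletons, ordered ascending
  far <- list(a = rnorm(10, 0, 0.1), b = rnorm(10, 5, 0.1),
              c = rnorm(10, 10, 0.1), d = rnorm(10, 15, 0.1))
  ss2 <- scheffe_subsets(far)
  expect_length(ss2$subsets, 4)
  expect_identical(vapply(ss2$subsets, function(s) s$groups, ""),
                   c("a", "b", "c", "d"))
  expect_true(all(diff(ss2$means) > 0))
  # every group appears in at least one subset
  expect_setequal(unlist(lapply(ss2$subsets, `[[`, "groups")),
                  names(far))
  # harmonic mean n under unequal sizes
  uneq <- list(a = rnorm(10), b = rnorm(40))
  expect_equal(scheffe_subsets(uneq)$harmonic_n, 2 / (1 / 10 + 1 / 40))
})

test_that("subset pattern on samples moment-matched to the published totals", {
  # whole-sample DA-CA moments per standard (boys): Kuwaiti 0.30 (0.96)
  # n 217, Saudi 0.40 (1.00) n 138, French-Canadian 0.76 (0.85) n 217,
  # Belgian 2.12 (1.36) n 217 -> subsets {Kuwaiti, Saudi} < {FC} < {Belgian}
  samples <- list(
    kuwaiti = sample_with_moments(217, 0.30, 0.96),
    saudi = sample_with_moments(138, 0.40, 1.00),
    french_canadian = sample_with_moments(217, 0.76, 0.85),
    belgian = sample_with_moments(217, 2.12, 1.36))
  ss <- scheffe_subsets(samples)
  got <- lapply(ss$subsets, function(s) sort(s$groups))
  expect_identical(got, list(c("kuwaiti", "saudi"), "french_canadian",
                             "belgian"))
})

test_that("comparison report assembles totals and writers emit files", {
  wt <- demo_tables()
  set.seed(23)
  counts <- default_cohort_counts()
  counts$n <- pmax(4L, counts$n %/% 3L)
  ch <- simulate_cohort(cohort_config(counts, score_sd = 2, seed = 23), wt)
  stds <- list()
  for (sx in c("male", "female")) {
    base <- saudi_standard(sx, "cubic")
    stds[[length(stds) + 1L]] <- shift_standard(base, 0, name = "unbiased")
    stds[[length(stds) + 1L]] <- shift_standard(base, 1.5, name = "biased")
  }
  res <- estimate_cohort(ch$ratings, wt, stds)
  rep <- comparison_report(res)
  for (sx in c("male", "female")) {
    tot <- rep[[sx]]$totals
    expect_setequal(tot$standard, c("unbiased", "biased"))
    # injected bias separates the standards decisively
    expect_gt(rep[[sx]]$anova$F, 10)
    expect_length(rep[[sx]]$scheffe_subsets$subsets, 2)
  }
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_report_csv(rep, csv)
  write_report_json(rep, json)
  back <- read.csv(csv)
  expect_true(all(c("sex", "standard", "age_group", "n", "mean", "sd",
                    "ci_lo", "ci_hi", "p") %in% names(back)))
  parsed <- jsonlite::read_json(json)
  expect_equal(parsed$alpha, 0.05)
  expect_true(!is.null(parsed$male$anova$F))
})

test_that("single-standard cohort yields no ANOVA with a message", {
  wt <- demo_tables()
  ch <- simulate_cohort(cohort_config(
    data.frame(sex = "male", age_group = "8.00-8.99", lower = 8, n = 6),
    models = list(male = demo_generating_model()), seed = 2), wt)
  res <- estimate_cohort(ch$ratings, wt,
                         list(demo_generating_model()))
  expect_message(rep <- comparison_report(res), "fewer than 2")
  expect_null(rep$male$anova)
})
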