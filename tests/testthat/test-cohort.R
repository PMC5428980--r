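make_cohort <- function(n, len = 60, labels = NULL, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    participant_record(sprintf("P%02d", i), round(runif(len, 0, 50)),
                       if (is.null(labels)) sample(c("success", "failure"), 1)
                       else labels[i]))
}

test_that("weight trajectories map to outcome labels by the program rule", {
  expect_identical(assign_outcome_label(100, 84, 88), "success")
  expect_identical(assign_outcome_label(100, 90, NA), "failure")   # <15% loss
  expect_identical(assign_outcome_label(100, 80, 92), "failure")   # regained past 90%
  expect_identical(assign_outcome_label(100, 84, NA), "indeterminate")
  # boundary cases: exactly 15% loss qualifies, exactly 90% maintains
  expect_identical(assign_outcome_label(100, 85, 90), "success")
  expect_identical(assign_outcome_label(100, 85.01, 90), "failure")
  expect_identical(assign_outcome_label(c(100, 100), c(84, 90), c(88, NA)),
                   c("success", "failure"))
  expect_error(assign_outcome_label(100, -5), class = "actiph_validation_error")
})

test_that("pair enumeration produces each unordered pair once with its stratum", {
  labels <- setNames(c(rep("failure", 79), rep("success", 21)), sprintf("p%03d", 1:100))
  pg <- pair_groups(labels)
  expect_identical(nrow(pg), 4950L)
  expect_identical(as.integer(table(pg$group)[c("FF", "FS", "SS")]),
                   c(3081L, 1659L, 210L))
  expect_false(any(pg$id_a == pg$id_b))
  expect_false(anyDuplicated(paste(pmin(pg$id_a, pg$id_b), pmax(pg$id_a, pg$id_b))) > 0)

  small <- setNames(c("failure", "failure", "success"), c("a", "b", "c"))
  tab <- table(pair_groups(small)$group)
  expect_identical(as.integer(tab[c("FF", "FS")]), c(1L, 2L))

  withi <- c(small, d = "indeterminate")
  expect_warning(pgi <- pair_groups(withi), "indeterminate")
  expect_identical(nrow(pgi), 3L)
  expect_error(suppressWarnings(pair_groups(c(a = "failure", b = "indeterminate"))),
               class = "actiph_validation_error")
})

test_that("pair counts always sum to n(n-1)/2", {
  set.seed(20)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    labels <- setNames(sample(c("success", "failure"), n, replace = TRUE),
                       paste0("x", seq_len(n)))
    expect_identical(nrow(pair_groups(labels)), as.integer(n * (n - 1) / 2))
  }
})

test_that("pairwise cohort analysis fills every pair deterministically", {
  recs <- make_cohort(5, labels = c("failure", "failure", "success", "success", "failure"))
  pc <- pairwise_cohort_analysis(recs, window_length = 20)
  expect_identical(nrow(pc), 10L)
  expect_true(all(pc$value >= 0))
  expect_identical(pc, pairwise_cohort_analysis(recs, window_length = 20))
  # identical signals are at distance zero
  same <- lapply(1:3, function(i)
    participant_record(paste0("S", i), recs[[1]]$signal, "failure"))
  pc0 <- pairwise_cohort_analysis(same, window_length = 20)
  expect_equal(pc0$value, rep(0, 3))
  # hand-check one pair against the distance-signal path
  ds <- distance_signal(windowed_diagrams(recs[[1]]$signal, 20),
                        windowed_diagrams(recs[[2]]$signal, 20))
  expect_equal(pc$value[pc$id_a == "P01" & pc$id_b == "P02"], mean_distance(ds))
  # correlation baseline
  pcc <- pairwise_cohort_analysis(recs, metric = "correlation")
  expect_true(all(abs(pcc$value) <= 1))
  expect_equal(pcc$value[1], pearson_correlation(recs[[1]]$signal, recs[[2]]$signal))
  # mixed lengths are rejected
  recs[[2]]$signal <- recs[[2]]$signal[1:40]
  expect_error(pairwise_cohort_analysis(recs), class = "actiph_validation_error")
})

test_that("group summaries use unweighted means and sample SD", {
  pairs <- data.frame(group = c("FF", "FF", "FF", "SS"), value = c(1, 2, 3, 5))
  gs <- group_summary(pairs)
  expect_identical(gs$group, c("FF", "SS"))
  expect_equal(gs$mean, c(2, 5))
  expect_equal(gs$sd, c(1, NA))
  expect_identical(gs$n, c(3L, 1L))
  # permutation invariance
  perm <- pairs[c(4, 2, 1, 3), ]
  expect_equal(group_summary(perm), gs)
})

test_that("unpaired t test matches the pooled-variance formula", {
  tt <- unpaired_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_equal(tt$p.value, 0.02131164, tolerance = 1e-6)
  # agreement with the standard implementation
  set.seed(21)
  x <- rnorm(10); y <- rnorm(12, 1)
  ref <- t.test(x, y, var.equal = TRUE)
  tt2 <- unpaired_ttest(x, y)
  expect_equal(tt2$statistic, unname(ref$statistic))
  expect_equal(tt2$p.value, ref$p.value)
  refw <- t.test(x, y)
  ttw <- unpaired_ttest(x, y, "welch")
  expect_equal(ttw$df, unname(refw$parameter))
  # symmetry and degenerate conventions
  swap <- unpaired_ttest(y, x)
  expect_equal(swap$statistic, -tt2$statistic)
  expect_equal(swap$p.value, tt2$p.value)
  same <- unpaired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0); expect_equal(same$p.value, 1)
  const <- unpaired_ttest(c(2, 2), c(2, 2))
  expect_equal(const$p.value, 1)
  expect_error(unpaired_ttest(1, c(1, 2)), class = "actiph_validation_error")
})

test_that("stratum t tests compare FF/FS/SS pair values", {
  set.seed(22)
  pairs <- data.frame(group = rep(c("FF", "FS", "SS"), times = c(20, 15, 10)),
                      value = c(rnorm(20, 5), rnorm(15, 4), rnorm(10, 3)))
  ct <- cohort_ttests(pairs)
  expect_identical(ct$comparison, c("FF_vs_SS", "FF_vs_FS", "FS_vs_SS"))
  expect_true(all(ct$p > 0 & ct$p <= 1))
  ref <- t.test(pairs$value[pairs$group == "FF"], pairs$value[pairs$group == "SS"],
                var.equal = TRUE)
  expect_equal(ct$t[1], unname(ref$statistic))
})

test_that("random-label control is reproducible and near-null on exchangeable data", {
  recs <- make_cohort(12, labels = rep(c("failure", "success"), 6), seed = 23)
  pc <- pairwise_cohort_analysis(recs, window_length = 20)
  r1 <- random_label_control(recs, n_trials = 20, seed = 99, pairs = pc)
  r2 <- random_label_control(recs, n_trials = 20, seed = 99, pairs = pc)
  expect_identical(r1, r2)
  expect_identical(r1$n_trials, rep(20L, nrow(r1)))
  expect_true(all(r1$mean_p > 0 & r1$mean_p <= 1))
  r3 <- random_label_control(recs, n_trials = 5, seed = 1, pairs = pc,
                             preserve_sizes = FALSE)
  expect_true(all(r3$mean_p > 0 & r3$mean_p <= 1))
})

test_that("cohort_analysis chains pairs, summary and tests coherently", {
  recs <- make_cohort(8, labels = rep(c("failure", "success"), each = 4), seed = 24)
  ca <- cohort_analysis(recs, window_length = 20)
  expect_identical(nrow(ca$pairs), 28L)
  expect_identical(ca$summary$n, c(6L, 16L, 6L))
  expect_equal(ca$summary$mean[ca$summary$group == "FF"],
               mean(ca$pairs$value[ca$pairs$group == "FF"]))
  expect_identical(nrow(ca$tests), 3L)
})
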