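test_that("Mann-Whitney U statistic has the right extremes and symmetry", {
  a <- c(1.2, 3.4, 5.6, 7.1)
  expect_equal(mann_whitney(a, a)$U, length(a)^2 / 2)   # identical samples
  expect_equal(mann_whitney(c(1, 2), c(3, 4, 5))$U, 0)  # fully disjoint
  expect_equal(mann_whitney(c(3, 4, 5), c(1, 2))$U, 6)  # U + U' = n1*n2
  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(7); y <- rnorm(9)
    expect_equal(mann_whitney(x, y)$U + mann_whitney(y, x)$U, 63)
  }
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("exact p matches enumeration and wilcox.test", {
  # enumeration oracle over all C(5,2) label assignments for a=[1,2], b=[3,4,5]
  pool <- c(1, 2, 3, 4, 5)
  combs <- combn(5, 2)
  u_obs <- mann_whitney(c(1, 2), c(3, 4, 5))$U
  u_all <- apply(combs, 2, function(idx)
    mann_whitney(pool[idx], pool[-idx])$U)
  p_enum <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  mw <- mann_whitney(c(1, 2), c(3, 4, 5))
  expect_identical(mw$method, "exact")
  expect_equal(mw$p, p_enum, tolerance = 1e-12)
  # wilcox.test oracle on random tie-free small samples
  set.seed(72)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    mw <- mann_whitney(x, y)
    wt <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mw$U, unname(wt$statistic))
    expect_equal(mw$p, wt$p.value, tolerance = 1e-12)
  }
})

test_that("tie-corrected approximation tracks the exact p on small samples", {
  # exhaustive over every attainable U at n = 8/8: the worst-case gap of
  # the continuity-corrected normal approximation to the exact p is 0.0109
  # (computed from the exact U distribution; a uniform 0.01 bound is not
  # attainable by any standard normal approximation at this sample size)
  gaps <- vapply(0:64, function(u) {
    p_exact <- min(1, 2 * min(pwilcox(u, 8, 8),
                              pwilcox(u - 1, 8, 8, lower.tail = FALSE)))
    sigma <- sqrt(8 * 8 * 17 / 12)
    p_approx <- min(1, 2 * pnorm(-max((abs(u - 32) - 0.5) / sigma, 0)))
    abs(p_exact - p_approx)
  }, 0)
  expect_lt(max(gaps), 0.011)
  # and the implementation reproduces that approximation on real samples
  set.seed(73)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    wt <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(mann_whitney(x, y, exact_max = 0)$p, wt$p.value,
                 tolerance = 1e-9)
  }
  # ties force the approximation and agree with wilcox.test's correction
  x <- c(1, 2, 2, 3, 5, 5, 6, 8, 9, 9)
  y <- c(2, 3, 3, 4, 5, 7, 7, 8, 10, 11)
  mw <- mann_whitney(x, y)
  expect_identical(mw$method, "normal-approx")
  wt <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mw$p, wt$p.value, tolerance = 1e-9)
})

test_that("per-site analysis flags significant features and builds ROCs", {
  # surrogate liver cohort from the published parameters: skewness should
  # separate responders from non-responders decisively at n = 108/61
  reps <- 25
  hits <- 0
  for (i in seq_len(reps)) {
    tab <- sample_feature_cohort(cohort_spec(districts = "liver",
                                             n_noise = 3, seed = 100 + i))
    ps <- per_site_analysis(tab, tab$label, "liver")
    cmp <- ps$comparisons
    if (cmp$p[cmp$feature == "HISTO_Skewness"] < 0.05) hits <- hits + 1
    if (i == 1) {
      expect_true("HISTO_Skewness" %in% names(ps$roc))
      roc <- ps$roc[["HISTO_Skewness"]]
      expect_false(roc$not_informative)
      expect_equal(roc$auc_flipped, 1 - roc$auc, tolerance = 1e-12)
    }
  }
  expect_gte(hits / reps, 0.95)
  tab <- sample_feature_cohort(cohort_spec(districts = "liver", seed = 1))
  expect_error(per_site_analysis(tab, tab$label, "bone"), "absent")
  expect_error(per_site_analysis(tab, rep(1, nrow(tab)), "liver"),
               "single response class")
})

test_that("delta summaries separate shifted groups and handle missingness", {
  set.seed(74)
  n <- 50
  labels <- data.frame(lesion_id = sprintf("L%03d", 1:(2 * n)),
                       dichotomous = rep(c(1L, 0L), each = n))
  deltas <- data.frame(lesion_id = labels$lesion_id, feature = "F",
                       delta_percent = c(rnorm(n, -20, 10), rnorm(n, 0, 10)))
  ds <- delta_group_summary(deltas, labels)
  expect_identical(sort(ds$group), c("non_responder", "responder"))
  expect_lt(ds$p[1], 0.01)
  # identical groups: p near 1, both groups summarized
  deltas$delta_percent <- rep(rnorm(n), 2)
  ds2 <- delta_group_summary(deltas, labels)
  expect_gt(ds2$p[1], 0.5)
  # missing deltas are dropped pairwise
  deltas$delta_percent[1:10] <- NA
  expect_equal(sum(delta_group_summary(deltas, labels)$n), 2 * n - 10)
})

test_that("report bundle conserves counts and is byte-identical on rerun", {
  spec <- cohort_spec(n_noise = 2, seed = 5)
  tab <- sample_feature_cohort(spec)
  labels <- data.frame(lesion_id = tab$lesion_id,
                       category = ifelse(tab$label == 0, "PD", "SD"),
                       dichotomous = tab$label)
  rep1 <- build_report(tab, labels)
  expect_identical(sum(rep1$cohort$Freq), nrow(tab))
  expect_identical(sum(rep1$district_totals$Freq), nrow(tab))
  d1 <- tempfile(); d2 <- tempfile()
  write_report(rep1, d1)
  write_report(build_report(sample_feature_cohort(spec), labels), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_error(build_report(tab[0, ], labels[0, ]), "empty cohort")
})
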