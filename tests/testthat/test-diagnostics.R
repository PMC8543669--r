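test_that("rounding half away from zero reproduces clinical reporting", {
  expect_equal(eyecode:::round_half_away(c(0.5, 2.5, -2.5, 43.49)),
               c(1, 3, -3, 43))
  expect_equal(eyecode:::round_half_away(7.447, 1), 7.4)
  expect_equal(eyecode:::round_half_away(36.891, 1), 36.9)
})

test_that("confusion indices follow their defining identities", {
  ind <- confusion_at_cutoff(c(12, 13), c(4, 5), 10)
  expect_equal(ind$sensitivity, 1)
  expect_equal(ind$specificity, 1)
  expect_true(is.na(ind$lr_pos))  # undefined, never infinity

  set.seed(11)
  for (r in 1:20) {
    cases <- sample(4:16, sample(3:40, 1), replace = TRUE)
    noncases <- sample(4:16, sample(3:40, 1), replace = TRUE)
    k <- sample(5:16, 1)
    ind <- confusion_at_cutoff(cases, noncases, k)
    expect_equal(ind$tp + ind$fn, length(cases))
    expect_equal(ind$fp + ind$tn, length(noncases))
    expect_equal(ind$sensitivity, ind$tp / length(cases))
    expect_equal(ind$specificity, ind$tn / length(noncases))
    expect_equal(ind$accuracy,
                 (ind$tp + ind$tn) / (length(cases) + length(noncases)))
    if (ind$fp > 0)
      expect_equal(ind$lr_pos, ind$sensitivity / (1 - ind$specificity))
    if (ind$tn > 0)
      expect_equal(ind$lr_neg, (1 - ind$sensitivity) / ind$specificity)
  }
  expect_error(confusion_at_cutoff(integer(0), c(4, 5), 10), "nonempty")
  expect_error(confusion_at_cutoff(c(3, 10), c(4, 5), 10), "4-16")
})

test_that("index table covers cut-offs 5..16 with monotone sens/spec", {
  tab <- indices_table(c(4, 9, 10), c(4, 5, 9))
  expect_equal(tab$cutoff, 5:16)
  row10 <- tab[tab$cutoff == 10, ]
  expect_equal(row10$tp, 1)  # only the case scoring 10
  expect_equal(row10$fp, 0)
  expect_true(all(diff(tab$sensitivity) <= 0))
  expect_true(all(diff(tab$specificity) >= 0))

  tab <- indices_table(rep(16, 5), rep(4, 7))
  expect_true(all(tab$sensitivity == 1) && all(tab$specificity == 1))

  set.seed(7)
  cases <- sample(4:16, 30, replace = TRUE)
  noncases <- sample(4:16, 45, replace = TRUE)
  tab <- indices_table(cases, noncases)
  expect_true(all(diff(tab$sensitivity) <= 0))
  expect_true(all(diff(tab$specificity) >= 0))
})

test_that("Mann-Whitney AUC equals the pairwise definition", {
  expect_equal(auc_mann_whitney(c(10, 11), c(4, 5)), 1)
  expect_equal(auc_mann_whitney(c(4, 7, 9), c(4, 7, 9)), 0.5)
  expect_equal(auc_mann_whitney(c(4, 9, 10), c(4, 5, 9)),
               auc_pairwise(c(4, 9, 10), c(4, 5, 9)))
  expect_equal(auc_pairwise(c(4, 9, 10), c(4, 5, 9)), 6 / 9)
  set.seed(31)
  for (r in 1:25) {
    cases <- sample(4:16, sample(2:15, 1), replace = TRUE)
    noncases <- sample(4:16, sample(2:15, 1), replace = TRUE)
    expect_equal(auc_mann_whitney(cases, noncases),
                 auc_pairwise(cases, noncases))
  }
})

test_that("ROC geometry: corners, monotonicity, trapezoid = Mann-Whitney", {
  set.seed(101)
  for (r in 1:60) {
    cases <- sample(4:16, sample(2:30, 1), replace = TRUE)
    noncases <- sample(4:16, sample(2:30, 1), replace = TRUE)
    roc <- roc_curve(cases, noncases)
    expect_true(any(roc$points$fpr == 0 & roc$points$tpr == 0))
    expect_true(any(roc$points$fpr == 1 & roc$points$tpr == 1))
    # tpr and fpr nonincreasing as the threshold rises
    o <- order(roc$points$threshold)
    expect_true(all(diff(roc$points$tpr[o]) <= 0))
    expect_true(all(diff(roc$points$fpr[o]) <= 0))
    expect_lte(nrow(unique(roc$points[, c("fpr", "tpr")])), 14)
    expect_equal(roc$auc, roc$auc_mw, tolerance = 1e-13)
  }
  # shift invariance for non-integer scores via the generic sweep
  set.seed(5)
  x <- rnorm(20); y <- rnorm(25, -0.5)
  r1 <- roc_curve(x, y); r2 <- roc_curve(x + 3.7, y + 3.7)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$points$tpr, r2$points$tpr)
})

test_that("AUC and DeLong interval agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(99)
  for (r in 1:5) {
    cases <- sample(4:16, 30, replace = TRUE)
    noncases <- sample(4:14, 40, replace = TRUE)
    ref <- pROC::roc(c(rep(1, 30), rep(0, 40)), c(cases, noncases),
                     quiet = TRUE, direction = "<")
    expect_equal(auc_mann_whitney(cases, noncases),
                 as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    ci_ref <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    ci <- auc_ci(cases, noncases, method = "delong")
    expect_equal(ci$lower, max(0, ci_ref[1]), tolerance = 1e-9)
    expect_equal(ci$upper, min(1, ci_ref[3]), tolerance = 1e-9)
  }
})

test_that("AUC confidence intervals contain the estimate and truncate", {
  set.seed(17)
  cases <- sample(8:16, 25, replace = TRUE)
  noncases <- sample(4:12, 30, replace = TRUE)
  for (m in c("delong", "bootstrap")) {
    ci <- auc_ci(cases, noncases, method = m, seed = 1)
    expect_lte(ci$lower, ci$auc)
    expect_gte(ci$upper, ci$auc)
    expect_gte(ci$lower, 0); expect_lte(ci$upper, 1)
  }
  # complete separation: degenerate DeLong variance falls back to bootstrap
  expect_warning(ci <- auc_ci(rep(16, 10), rep(4, 10), method = "delong"),
                 "degenerate")
  expect_equal(ci$method, "bootstrap")
  # bootstrap is reproducible for a fixed seed and leaves the RNG alone
  set.seed(123); before <- runif(1)
  ci1 <- auc_ci(cases, noncases, method = "bootstrap", seed = 42)
  ci2 <- auc_ci(cases, noncases, method = "bootstrap", seed = 42)
  expect_identical(ci1, ci2)
})

test_that("likelihood ratios come from exact fractions", {
  # published exceedance counts at the >=10 cut-off
  fasd <- counts_cohort(16, 37)
  pooled <- c(counts_cohort(0, 65), counts_cohort(6, 33), counts_cohort(3, 57))
  ind <- confusion_at_cutoff(fasd, pooled, 10)
  expect_equal(lr_positive(ind), (16 / 37) / (9 / 155), tolerance = 1e-12)
  expect_equal(ind$lr_pos_reported, 7.4)  # one decimal from exact fractions

  ind9 <- confusion_at_cutoff(counts_cohort(21, 37, pos = 9),
                              counts_cohort(1, 65, pos = 9), 9)
  expect_equal(ind9$lr_pos_reported, 36.9)

  half <- confusion_at_cutoff(counts_cohort(5, 10), counts_cohort(5, 10), 10)
  expect_equal(lr_positive(half), 1)

  sep <- confusion_at_cutoff(counts_cohort(16, 37), counts_cohort(0, 65), 10)
  expect_true(is.na(lr_positive(sep)))

  # LR+ >= 1 exactly when sensitivity exceeds 1 - specificity
  set.seed(13)
  for (r in 1:20) {
    ind <- confusion_at_cutoff(sample(4:16, 20, TRUE),
                               sample(4:16, 20, TRUE), sample(5:16, 1))
    if (!is.na(ind$lr_pos))
      expect_equal(ind$lr_pos >= 1,
                   ind$sensitivity >= 1 - ind$specificity)
  }
})
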