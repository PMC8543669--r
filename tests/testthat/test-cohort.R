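test_that("cohort specs validate their probability tables", {
  expect_error(cohort_spec("g", 10, c(0.5, 0.5, 0, 0.1),
                           rep(0.25, 4), rep(0.25, 4), rep(0.25, 4)),
               "sum to 1")
  expect_error(cohort_spec("g", 10, c(0.5, 0.5, 0, -0), rep(0.25, 4),
                           rep(0.25, 4), c(-0.25, 0.5, 0.5, 0.25)),
               "nonnegative")
  expect_error(cohort_spec("g", 10, rep(0.25, 4), rep(0.25, 4),
                           rep(0.25, 4), rep(0.25, 4), dependence = 1.2),
               "dependence")
})

test_that("degenerate tables pin the totals and seeds are reproducible", {
  one <- c(1, 0, 0, 0); four <- c(0, 0, 0, 1)
  s <- simulate_scores(cohort_spec("g", 50, one, one, one, one), seed = 1)
  expect_true(all(s$total == 4))
  s <- simulate_scores(cohort_spec("g", 50, four, four, four, four), seed = 1)
  expect_true(all(s$total == 16))

  spec <- cohort_spec("g", 200, c(0.4, 0.3, 0.2, 0.1), rep(0.25, 4),
                      c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.2, 0.3, 0.4),
                      dependence = 0.4)
  expect_identical(simulate_scores(spec, seed = 99),
                   simulate_scores(spec, seed = 99))
  # total is always the sum and in range
  s <- simulate_scores(spec, seed = 99)
  expect_true(all(s$total == s$a + s$b + s$c + s$d))
  expect_true(all(s$total >= 4 & s$total <= 16))
})

test_that("marginals converge to the tables; dependence 0 factorises cells", {
  p_a <- c(0.25, 0.25, 0.25, 0.25)
  p_b <- c(0.4, 0.3, 0.2, 0.1)
  spec <- cohort_spec("g", 1e5, p_a, p_b, p_a, p_b, dependence = 0)
  s <- simulate_scores(spec, seed = 2024)
  emp_a <- unname(prop.table(table(factor(s$a, 1:4))))
  emp_b <- unname(prop.table(table(factor(s$b, 1:4))))
  expect_lt(max(abs(emp_a - p_a)), 0.01)
  expect_lt(max(abs(emp_b - p_b)), 0.01)
  # independent categories: joint cell = product of marginals
  joint <- mean(s$a == 1 & s$b == 1)
  expect_lt(abs(joint - p_a[1] * p_b[1]), 0.01)

  # positive dependence preserves marginals but concentrates the joint
  spec_d <- cohort_spec("g", 1e5, p_a, p_b, p_a, p_b, dependence = 0.7)
  sd_ <- simulate_scores(spec_d, seed = 2024)
  emp_bd <- unname(prop.table(table(factor(sd_$b, 1:4))))
  expect_lt(max(abs(emp_bd - p_b)), 0.01)
  expect_gt(mean(sd_$a == 1 & sd_$b == 1), joint + 0.03)
})

test_that("inverse-rubric exam sampling reproduces the drawn score vectors", {
  rub <- default_rubric()
  spec <- cohort_spec("unknown", 400, rep(0.25, 4), rep(0.25, 4),
                      rep(0.25, 4), rep(0.25, 4), dependence = 0.3)
  target <- simulate_scores(spec, seed = 77)
  ex <- simulate_exams(spec, rub, seed = 77)
  got <- score_exams(ex, rub)
  expect_true(all(got$complete))
  expect_identical(got$a, target$a)
  expect_identical(got$b, target$b)
  expect_identical(got$c, target$c)
  expect_identical(got$d, target$d)
  # the adult preset rescores its own simulations identically too
  rub_a <- default_rubric("young_adult")
  ex_a <- simulate_exams(spec, rub_a, n = 100, seed = 5)
  expect_identical(score_exams(ex_a, rub_a)$total,
                   simulate_scores(spec, n = 100, seed = 5)$total)
})

test_that("calibration reproduces summary constraints or names the violator", {
  ctrl <- calibrate_to_summaries(cohort_constraints("control"), seed = 11)
  pmf <- eyecode:::total_pmf(ctrl$p, ctrl$dependence)
  expect_true(all(pmf[as.character(10:16)] == 0))  # support capped at 9
  expect_gte(unname(cumsum(pmf)["4"]), 0.75)       # both quartiles at 4

  infeasible <- list(group = "x", n = 10, total_median = 12,
                     total_range = c(4, 6))
  expect_error(calibrate_to_summaries(infeasible, seed = 1,
                                      max_iter = 200, restarts = 1),
               class = "eyecode_infeasible_error")
})

test_that("cohort specs round-trip through JSON", {
  spec <- calibrate_to_summaries(cohort_constraints("control"), seed = 3)
  path <- tempfile(fileext = ".json")
  write_cohort_spec(spec, path)
  back <- read_cohort_spec(path)
  expect_equal(back$p, spec$p, tolerance = 1e-12)
  expect_equal(back$dependence, spec$dependence)
  expect_identical(simulate_scores(spec, n = 50, seed = 4),
                   simulate_scores(back, n = 50, seed = 4))
})

test_that("shipped specs honour the published group summaries", {
  # spot-check two groups; the full set is exercised by the pipeline
  fasd <- shipped_cohort_spec("FASD")
  s <- simulate_scores(fasd, n = 2e4, seed = 8)
  expect_equal(median(s$total), 9)
  expect_equal(mean(s$total >= 10), 16 / 37, tolerance = 0.02)
  expect_true(all(s$total >= 4 & s$total <= 16))

  ctrl <- shipped_cohort_spec("control")
  s <- simulate_scores(ctrl, n = 2e4, seed = 8)
  expect_true(all(s$total <= 9))
  expect_equal(unname(fivenum(s$total)[2:4]), c(4, 4, 4))
})
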