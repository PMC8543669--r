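test_that("spherical equivalent follows the optometric formula", {
  expect_identical(spherical_equivalent(0, 0), 0)
  expect_identical(spherical_equivalent(-2, -1), -2.5)
  expect_identical(spherical_equivalent(3, -1.5), 2.25)
  expect_true(is.na(spherical_equivalent(NA_real_, -1)))
  expect_error(spherical_equivalent(Inf, 0), "finite")
  expect_error(spherical_equivalent(1, NaN), "finite")
})

test_that("plus-cylinder refractions canonicalize without changing the SE", {
  r <- canonicalize_refraction(-1, 2, 30)
  expect_equal(r$sphere, 1)
  expect_equal(r$cylinder, -2)
  expect_equal(r$axis, 120)
  expect_equal(spherical_equivalent(r$sphere, r$cylinder),
               -1 + 2 / 2)  # SE invariant under transposition
  # already minus-cylinder: untouched
  r2 <- canonicalize_refraction(1.5, -0.75, 170)
  expect_equal(unlist(r2), c(sphere = 1.5, cylinder = -0.75, axis = 170))
})

test_that("feature derivation aggregates eyes and propagates missingness", {
  rub <- default_rubric()
  ft <- derive_features(make_exam(bcva_right = 0.65, bcva_left = 1.0), rub)
  expect_equal(ft$va, 0.65)  # worse eye

  ft <- derive_features(make_exam(
    sphere_right = -1, cylinder_right = 0,
    sphere_left = 2, cylinder_left = -1), rub)
  expect_equal(ft$myopia_se, 1)         # SE right -1
  expect_equal(ft$hypermetropia_se, 1.5)  # SE left +1.5
  expect_equal(ft$anisometropia, 2.5)
  expect_equal(ft$astigmatism, 1)

  ft <- derive_features(make_exam(
    sphere_right = NA_real_, sphere_left = NA_real_,
    cylinder_right = NA_real_, cylinder_left = NA_real_), rub)
  expect_true(all(is.na(c(ft$myopia_se, ft$astigmatism, ft$anisometropia))))
})

test_that("band boundaries take the score the clinical cut-off names", {
  rub <- default_rubric()
  # VA exactly at a band floor takes the better score
  ft <- random_features(4)
  ft$va <- c(0.8, 0.79, 0.5, 0.29)
  expect_equal(score_category(ft, rub, "A"), c(1L, 2L, 2L, 4L))
  # a worsening feature exactly at its cut-off counts as abnormal
  ft <- random_features(1)
  ft$myopia_se <- 1.0; ft$hypermetropia_se <- 0
  ft$astigmatism <- 0; ft$anisometropia <- 0
  expect_equal(score_category(ft, rub, "B"), 2L)
})

test_that("category B returns the worst triggered sub-feature band", {
  rub <- default_rubric()
  ft <- random_features(1)
  ft$myopia_se <- 1.5       # band 2
  ft$astigmatism <- 2.5     # band 3
  ft$hypermetropia_se <- 0; ft$anisometropia <- 0
  expect_equal(score_category(ft, rub, "B"), 3L)
})

test_that("category C combines strabismus and stereoacuity by maximum", {
  rub <- default_rubric()
  ft <- random_features(4)
  ft$strabismus <- c("none", "heterophoria", "none", "manifest_tropia")
  ft$stereo_kind <- c("seconds", "seconds", "fail", "seconds")
  ft$stereo_seconds <- c(60, 240, NA, 60)
  expect_equal(score_category(ft, rub, "C"), c(1L, 2L, 4L, 4L))
  # missing stereo is tolerated only when strabismus already attains 4
  ft$stereo_kind <- NA_character_; ft$stereo_seconds <- NA_real_
  expect_equal(score_category(ft, rub, "C"), c(NA, NA, NA, 4L))
})

test_that("whole-exam scoring spans 1111 to 4444 and refuses incompleteness", {
  rub <- default_rubric()
  s <- score_exam(make_exam(), rub)
  expect_equal(c(s$a, s$b, s$c, s$d), c(1L, 1L, 1L, 1L))
  expect_equal(s$total, 4L)

  worst <- make_exam(
    bcva_right = 0.1, bcva_left = 0.1,
    sphere_right = -6, sphere_left = -6,
    strabismus = "manifest_tropia", stereo_result = "untestable",
    structural_flags = "ptosis;epicanthal_folds;optic_disc_abnormality")
  s <- score_exam(worst, rub)
  expect_equal(c(s$a, s$b, s$c, s$d), c(4L, 4L, 4L, 4L))
  expect_equal(s$total, 16L)

  inc <- make_exam(strabismus = NA_character_, stereo_test = "none",
                   stereo_result = NA_character_)
  s <- score_exam(inc, rub)
  expect_false(s$complete)
  expect_true(is.na(s$total))
  # drop policy removes the row at cohort level
  expect_equal(nrow(score_exams(inc, rub, incomplete = "drop")), 0L)
})

test_that("classification against the cut-off is a >= comparison", {
  expect_equal(classify_total(10, 10), "positive")
  expect_equal(classify_total(9, 10), "negative")
  expect_equal(classify_total(9, 9), "positive")
  expect_error(classify_total(3, 10), "4-16")
  expect_error(classify_total(10, 17), "5-16")
  expect_true(is.na(classify_total(NA_integer_, 10)))
})

test_that("rubric validation rejects malformed band definitions", {
  rub <- default_rubric()
  bad <- unclass(rub); bad$acuity_breaks <- c(0.3, 0.5, 0.8)  # wrong order
  expect_error(validate_rubric(bad), "decreasing")
  bad <- unclass(rub); bad$refraction$myopia_se_breaks <- c(2, 1)
  expect_error(validate_rubric(bad), "increasing")
  bad <- unclass(rub); bad$strabismus_scores[["none"]] <- 2L
  expect_error(validate_rubric(bad), "none = 1")
  bad <- unclass(rub); bad$stereo$fail_score <- 7
  expect_error(validate_rubric(bad), "score in 1-4")
})

test_that("worsening any derived feature never lowers a category score", {
  rub <- default_rubric()
  set.seed(421)
  ft <- random_features(400)
  base <- vapply(c("A", "B", "C", "D"),
                 function(k) score_category(ft, rub, k),
                 integer(nrow(ft)))
  worse <- ft
  worse$va <- ft$va * 0.7
  worse$myopia_se <- ft$myopia_se + 1.3
  worse$hypermetropia_se <- ft$hypermetropia_se + 1.3
  worse$astigmatism <- ft$astigmatism + 0.9
  worse$anisometropia <- ft$anisometropia + 0.9
  worse$stereo_seconds <- ft$stereo_seconds * 3
  worse$n_structural <- pmin(5L, ft$n_structural + 1L)
  idx <- c(none = "heterophoria", heterophoria = "intermittent_tropia",
           intermittent_tropia = "manifest_tropia",
           manifest_tropia = "manifest_tropia")
  worse$strabismus <- unname(idx[ft$strabismus])
  after <- vapply(c("A", "B", "C", "D"),
                  function(k) score_category(worse, rub, k),
                  integer(nrow(ft)))
  expect_true(all(after >= base))
})
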