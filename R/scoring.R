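#' Score one category from derived features
#'
#' Each category is ranked independently on the 1--4 scale, 1 reflecting a
#' normal finding.  Where several sub-features feed one category (category B:
#' myopia, hypermetropia, astigmatism, anisometropia; category C: strabismus
#' class and stereoacuity) the category score is the worst (maximum)
#' triggered band.  A missing required feature makes the category
#' unscorable (`NA`), except that category C is still scorable when one
#' present sub-feature already attains 4 (the maximum cannot change).
#'
#' @param features one or more rows from [derive_features()].
#' @param rubric an `eyecode_rubric`.
#' @param category `"A"`, `"B"`, `"C"` or `"D"`.
#' @return integer score(s) in 1--4, `NA` where unscorable.
#' @export
score_category <- function(features, rubric, category = c("A", "B", "C", "D")) {
  category <- match.arg(category)
  ec_assert(inherits(rubric, "eyecode_rubric"), "rubric must be validated")
  switch(category,
    A = band_score(features$va, rubric$acuity_breaks, "lower_worse"),
    B = {
      rb <- rubric$refraction
      cand <- cbind(
        band_score(features$myopia_se, rb$myopia_se_breaks),
        band_score(features$hypermetropia_se, rb$hypermetropia_se_breaks),
        band_score(features$astigmatism, rb$astigmatism_breaks),
        band_score(features$anisometropia, rb$anisometropia_breaks))
      s <- apply(cand, 1, function(z) if (anyNA(z)) NA_integer_
                                      else max(z))
      as.integer(s)
    },
    C = {
      strab <- unname(rubric$strabismus_scores[features$strabismus])
      st <- rubric$stereo
      stereo <- rep(NA_integer_, length(features$stereo_kind))
      k <- features$stereo_kind
      stereo[!is.na(k) & k == "pass"] <- 1L
      stereo[!is.na(k) & k == "fail"] <- st$fail_score
      stereo[!is.na(k) & k == "untestable"] <- st$untestable_score
      sec <- !is.na(k) & k == "seconds"
      stereo[sec] <- band_score(features$stereo_seconds[sec],
                                st$seconds_breaks)
      s <- pmax(strab, stereo)
      # one sub-feature at 4 decides the maximum even if the other is missing
      four <- (!is.na(strab) & strab == 4L) | (!is.na(stereo) & stereo == 4L)
      s[four] <- 4L
      as.integer(s)
    },
    D = band_score(features$n_structural, rubric$structural_count_breaks)
  )
}

#' Score a table of exams
#'
#' Applies the rubric to every exam: categories A (BCVA), B (refraction),
#' C (strabismus/binocular function), D (ocular structural abnormalities),
#' and the total 4--16.  An exam with any unscorable category is marked
#' incomplete; under the default `incomplete = "refuse"` policy it keeps its
#' row with `total = NA`, under `"drop"` (complete-case cohort analysis) the
#' row is removed.
#'
#' @param exams data.frame with the columns of [exam_columns()].
#' @param rubric an `eyecode_rubric`; defaults to the shipped child preset.
#' @param incomplete `"refuse"` or `"drop"`.
#' @return data.frame with participant_id, group, a, b, c, d, total, complete.
#' @examples
#' rub <- default_rubric()
#' ex <- simulate_exams(cohort_spec("unknown", 3,
#'   p_A = c(1,0,0,0), p_B = c(1,0,0,0), p_C = c(1,0,0,0), p_D = c(1,0,0,0)),
#'   rub, seed = 1)
#' score_exams(ex, rub)  # every total is 4
#' @export
score_exams <- function(exams, rubric = default_rubric(),
                        incomplete = c("refuse", "drop")) {
  incomplete <- match.arg(incomplete)
  ft <- derive_features(exams, rubric)
  a <- score_category(ft, rubric, "A")
  b <- score_category(ft, rubric, "B")
  c_ <- score_category(ft, rubric, "C")
  d <- score_category(ft, rubric, "D")
  complete <- !(is.na(a) | is.na(b) | is.na(c_) | is.na(d))
  total <- ifelse(complete, a + b + c_ + d, NA_integer_)
  out <- data.frame(
    participant_id = exams$participant_id,
    group = if ("group" %in% names(exams)) as.character(exams$group)
            else NA_character_,
    a = a, b = b, c = c_, d = d,
    total = as.integer(total), complete = complete,
    stringsAsFactors = FALSE)
  if (incomplete == "drop") out <- out[out$complete, , drop = FALSE]
  out
}

#' Score a single exam
#'
#' @param exam a one-row data.frame (see [exam_columns()]).
#' @inheritParams score_exams
#' @return a list with elements `a`, `b`, `c`, `d`, `total`, `complete`,
#'   classed `eyecode_score`.
#' @export
score_exam <- function(exam, rubric = default_rubric()) {
  ec_assert(is.data.frame(exam) && nrow(exam) == 1,
            "score_exam expects a single exam row; see score_exams")
  s <- score_exams(exam, rubric, incomplete = "refuse")
  out <- list(a = s$a, b = s$b, c = s$c, d = s$d,
              total = s$total, complete = s$complete)
  class(out) <- "eyecode_score"
  out
}

#' @export
print.eyecode_score <- function(x, ...) {
  if (x$complete)
    cat(sprintf("FASD Eye Code %d%d%d%d, total %d\n",
                x$a, x$b, x$c, x$d, x$total))
  else
    cat("FASD Eye Code: incomplete (unscorable category), no total\n")
  invisible(x)
}

#' Classify totals against a cut-off
#'
#' A total at or above the cut-off is positive.  The derivation cohort used
#' cut-offs of 10 (primary) and 9.
#'
#' @param total integer total score(s) in 4--16 (`NA` allowed, propagates).
#' @param cutoff integer in 5--16; default 10.
#' @return character vector, `"positive"` / `"negative"`.
#' @examples
#' classify_total(c(9, 10), cutoff = 10)  # negative, positive
#' @export
classify_total <- function(total, cutoff = 10L) {
  ec_assert(length(cutoff) == 1 && cutoff == round(cutoff) &&
              cutoff >= 5 && cutoff <= 16,
            "cutoff must be a single integer in 5-16")
  ok <- is.na(total) | (total == round(total) & total >= 4 & total <= 16)
  ec_assert(all(ok), "totals must be integers in 4-16")
  ifelse(is.na(total), NA_character_,
         ifelse(total >= cutoff, "positive", "negative"))
}
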