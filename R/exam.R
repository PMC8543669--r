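#' Spherical equivalent of a spherocylindrical refraction
#'
#' SE = sphere + cylinder/2, the standard single-dioptre summary of a
#' cycloplegic refraction.  Inputs must be in minus-cylinder form (see
#' [canonicalize_refraction()]); `NA` propagates, other non-finite values are
#' rejected.
#'
#' @param sphere,cylinder dioptres, vectorised.
#' @return dioptres.
#' @examples
#' spherical_equivalent(-2, -1)   # -2.5
#' spherical_equivalent(3, -1.5)  # 2.25
#' @export
spherical_equivalent <- function(sphere, cylinder) {
  ec_assert(length(sphere) == length(cylinder),
            "sphere and cylinder must have equal length")
  bad <- (!is.na(sphere) & !is.finite(sphere)) | is.nan(sphere) |
         (!is.na(cylinder) & !is.finite(cylinder)) | is.nan(cylinder)
  ec_assert(!any(bad), "sphere/cylinder must be finite or NA")
  sphere + cylinder / 2
}

#' Canonicalize a refraction to minus-cylinder form
#'
#' Autorefractors report in plus- or minus-cylinder convention; the rubric
#' works internally in minus-cylinder form.  Transposition preserves the
#' spherical equivalent: sphere' = sphere + cyl, cyl' = -cyl,
#' axis' = (axis + 90) mod 180.
#'
#' @param sphere,cylinder,axis per-eye refraction (dioptres, dioptres,
#'   degrees); vectorised.  `axis` may be `NA` (it is ignored by the rubric).
#' @return a data.frame with columns `sphere`, `cylinder`, `axis`.
#' @export
canonicalize_refraction <- function(sphere, cylinder, axis = NA_real_) {
  n <- max(length(sphere), length(cylinder), length(axis))
  sphere <- rep_len(sphere, n); cylinder <- rep_len(cylinder, n)
  axis <- rep_len(axis, n)
  flip <- !is.na(cylinder) & cylinder > 0
  sphere[flip] <- sphere[flip] + cylinder[flip]
  axis[flip] <- (axis[flip] + 90) %% 180
  cylinder[flip] <- -cylinder[flip]
  data.frame(sphere = sphere, cylinder = cylinder, axis = axis)
}

#' Column names of an exam table
#'
#' One row per participant; missing measurements are empty cells in CSV /
#' `NA` in R.  `structural_flags` is a semicolon-separated subset of
#' ptosis, epicanthal_folds, optic_disc_abnormality,
#' retinal_vessel_abnormality, other_fundus_abnormality, or the literal
#' `"none"` for an examined, structurally normal eye (an empty cell means
#' "not examined").
#'
#' @return character vector of mandatory column names.
#' @export
exam_columns <- function() {
  c("participant_id", "age", "sex", "group",
    "bcva_right", "bcva_left",
    "sphere_right", "sphere_left", "cylinder_right", "cylinder_left",
    "axis_right", "axis_left",
    "strabismus", "stereo_test", "stereo_result", "structural_flags")
}

parse_structural <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_integer_)
    if (identical(s, "none")) return(0L)
    toks <- strsplit(s, ";", fixed = TRUE)[[1]]
    toks <- trimws(toks[nzchar(trimws(toks))])
    if (!all(toks %in% STRUCTURAL_FLAGS) || anyDuplicated(toks))
      return(NA_integer_)  # callers validate separately; here: count
    length(toks)
  }, integer(1), USE.NAMES = FALSE)
}

#' Derive the per-category features the rubric bands test
#'
#' Aggregates per-eye measurements to one feature record per participant:
#' decimal VA (worse or better eye per the rubric), maximal myopic and
#' hypermetropic spherical equivalent, maximal astigmatism (|cylinder|),
#' anisometropia (|SE_right - SE_left|), the strabismus class, the stereo
#' finding, and the structural flag count.  Missing inputs yield `NA`
#' features, never a default value.
#'
#' @param exams data.frame with the columns of [exam_columns()].
#' @param rubric an `eyecode_rubric`.
#' @return data.frame, one row per exam.
#' @export
derive_features <- function(exams, rubric) {
  ec_assert(inherits(rubric, "eyecode_rubric"), "rubric must be validated")
  missing_cols <- setdiff(exam_columns(), names(exams))
  ec_assert(length(missing_cols) == 0,
            paste("exam table lacks columns:",
                  paste(missing_cols, collapse = ", ")))

  agg_a <- rubric$eye_aggregation$acuity
  agg_b <- rubric$eye_aggregation$refraction
  # worse eye for acuity = lower VA; worse eye for refraction = larger error
  va <- if (agg_a == "worse_eye") pmin(exams$bcva_right, exams$bcva_left)
        else pmax(exams$bcva_right, exams$bcva_left)

  r <- canonicalize_refraction(exams$sphere_right, exams$cylinder_right,
                               exams$axis_right)
  l <- canonicalize_refraction(exams$sphere_left, exams$cylinder_left,
                               exams$axis_left)
  se_r <- spherical_equivalent(r$sphere, r$cylinder)
  se_l <- spherical_equivalent(l$sphere, l$cylinder)
  pick <- if (agg_b == "worse_eye") pmax else pmin
  myopia <- pick(pmax(0, -se_r), pmax(0, -se_l))
  hyper  <- pick(pmax(0, se_r), pmax(0, se_l))
  astig  <- pick(abs(r$cylinder), abs(l$cylinder))
  aniso  <- abs(se_r - se_l)

  strab <- as.character(exams$strabismus)
  strab[!is.na(strab) & !(strab %in% STRABISMUS_LEVELS)] <- NA

  st_test <- as.character(exams$stereo_test)
  st_res <- as.character(exams$stereo_result)
  n <- nrow(exams)
  stereo_kind <- rep(NA_character_, n)
  stereo_seconds <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(st_test[i]) || st_test[i] == "none") next
    if (!(st_test[i] %in% STEREO_TESTS)) next
    res <- st_res[i]
    if (is.na(res) || !nzchar(res)) next
    if (res %in% c("pass", "fail", "untestable")) {
      stereo_kind[i] <- res
    } else {
      sec <- suppressWarnings(as.numeric(res))
      if (!is.na(sec) && sec > 0) {
        stereo_kind[i] <- "seconds"
        stereo_seconds[i] <- sec
      }
    }
  }

  data.frame(
    participant_id = exams$participant_id,
    va = va,
    myopia_se = myopia, hypermetropia_se = hyper,
    astigmatism = astig, anisometropia = aniso,
    strabismus = strab,
    stereo_kind = stereo_kind, stereo_seconds = stereo_seconds,
    n_structural = parse_structural(as.character(exams$structural_flags)),
    stringsAsFactors = FALSE)
}
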