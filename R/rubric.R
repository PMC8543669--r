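#' Read a rubric configuration from JSON
#'
#' A rubric maps derived ophthalmological features to the four category
#' scores 1--4.  Bands are encoded as ordered break vectors: for a
#' "higher is worse" feature (e.g. astigmatism in dioptres) a value at or
#' above the k-th break scores k+1; for a "lower is worse" feature (decimal
#' visual acuity) a value *below* the k-th break scores k+1, so a value
#' exactly on a band floor takes the better score.  Both conventions mirror
#' how clinical cut-offs are stated ("myopia >= 1 D spherical equivalent",
#' "acuity >= 0.8 is normal").
#'
#' @param path path to a rubric JSON file.
#' @return a validated object of class `eyecode_rubric`.
#' @seealso [default_rubric()], [validate_rubric()]
#' @export
read_rubric <- function(path) {
  ec_assert(file.exists(path), sprintf("rubric file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_rubric(cfg)
}

#' Shipped rubric presets
#'
#' Two presets are installed with the package.  `"child_4_15"` targets ages
#' 4--15 (myopia cut-off 1.0 D spherical equivalent); `"young_adult"` raises
#' the myopia cut-off to 2.0 D SE, reflecting the age dependence of
#' refraction.  The shipped band definitions are a synthetic reconstruction
#' from paediatric population norms (see the file names and the methods
#' vignette); every threshold can be overridden by supplying your own JSON.
#'
#' @param preset `"child_4_15"` or `"young_adult"`.
#' @return an `eyecode_rubric`.
#' @examples
#' r <- default_rubric()
#' r$refraction$myopia_se_breaks
#' @export
default_rubric <- function(preset = c("child_4_15", "young_adult")) {
  preset <- match.arg(preset)
  file <- switch(preset,
    child_4_15 = "rubric_child_4_15_synthetic.json",
    young_adult = "rubric_young_adult_synthetic.json")
  read_rubric(system.file("extdata", file, package = "eyecode",
                          mustWork = TRUE))
}

check_breaks <- function(x, name, increasing, positive = TRUE) {
  ec_assert(is.numeric(x) && length(x) >= 1 && length(x) <= 3 &&
              all(is.finite(x)),
            sprintf("rubric: %s must be 1-3 finite numbers", name))
  if (positive)
    ec_assert(all(x > 0), sprintf("rubric: %s must be positive", name))
  d <- diff(x)
  if (increasing)
    ec_assert(length(d) == 0 || all(d > 0),
              sprintf("rubric: %s must be strictly increasing", name))
  else
    ec_assert(length(d) == 0 || all(d < 0),
              sprintf("rubric: %s must be strictly decreasing", name))
  as.numeric(x)
}

#' Validate a rubric configuration
#'
#' Checks that every band list covers its feature domain with mutually
#' exclusive bands (guaranteed by the break representation), that scores stay
#' in 1--4 and that score 1 is attainable in every category.
#'
#' @param cfg a list as produced by [jsonlite::read_json()].
#' @return the configuration, classed `eyecode_rubric`.
#' @export
validate_rubric <- function(cfg) {
  ec_assert(is.list(cfg), "rubric: configuration must be a list")
  for (f in c("name", "version", "acuity_breaks", "refraction",
              "strabismus_scores", "stereo", "structural_count_breaks"))
    ec_assert(!is.null(cfg[[f]]), sprintf("rubric: missing field '%s'", f))

  agg <- cfg$eye_aggregation %||% list()
  cfg$eye_aggregation <- list(
    acuity = agg$acuity %||% "worse_eye",
    refraction = agg$refraction %||% "worse_eye")
  ec_assert(all(unlist(cfg$eye_aggregation) %in% c("worse_eye", "better_eye")),
            "rubric: eye_aggregation must be 'worse_eye' or 'better_eye'")

  cfg$acuity_breaks <- check_breaks(cfg$acuity_breaks, "acuity_breaks",
                                    increasing = FALSE)
  for (f in c("myopia_se_breaks", "hypermetropia_se_breaks",
              "astigmatism_breaks", "anisometropia_breaks")) {
    ec_assert(!is.null(cfg$refraction[[f]]),
              sprintf("rubric: missing refraction field '%s'", f))
    cfg$refraction[[f]] <- check_breaks(cfg$refraction[[f]],
                                        paste0("refraction$", f),
                                        increasing = TRUE)
  }

  ss <- unlist(cfg$strabismus_scores)
  ec_assert(all(STRABISMUS_LEVELS %in% names(ss)),
            "rubric: strabismus_scores must name all strabismus classes")
  ec_assert(all(ss %in% 1:4) && ss[["none"]] == 1,
            "rubric: strabismus scores must lie in 1-4 with none = 1")
  cfg$strabismus_scores <- stats::setNames(as.integer(ss), names(ss))

  st <- cfg$stereo
  st$seconds_breaks <- check_breaks(st$seconds_breaks, "stereo$seconds_breaks",
                                    increasing = TRUE)
  for (f in c("fail_score", "untestable_score"))
    ec_assert(!is.null(st[[f]]) && st[[f]] %in% 1:4,
              sprintf("rubric: stereo$%s must be a score in 1-4", f))
  st$fail_score <- as.integer(st$fail_score)
  st$untestable_score <- as.integer(st$untestable_score)
  st$max_seconds <- as.numeric(st$max_seconds %||% 4000)
  cfg$stereo <- st

  scb <- cfg$structural_count_breaks
  ec_assert(is.numeric(scb) && length(scb) >= 1 && length(scb) <= 3 &&
              all(scb == round(scb)) && all(diff(scb) > 0) &&
              all(scb >= 1 & scb <= length(STRUCTURAL_FLAGS)),
            "rubric: structural_count_breaks must be increasing flag counts")
  cfg$structural_count_breaks <- as.integer(scb)

  structure(cfg, class = "eyecode_rubric")
}

#' @export
print.eyecode_rubric <- function(x, ...) {
  cat(sprintf("FASD Eye Code rubric '%s' (version %s, preset %s)\n",
              x$name, x$version, x$age_preset %||% "unspecified"))
  cat(sprintf("  A acuity breaks (decimal VA): %s\n",
              paste(x$acuity_breaks, collapse = ", ")))
  cat(sprintf("  B myopia/hyperopia SE breaks (D): %s / %s\n",
              paste(x$refraction$myopia_se_breaks, collapse = ", "),
              paste(x$refraction$hypermetropia_se_breaks, collapse = ", ")))
  cat(sprintf("  B astigmatism/anisometropia breaks (D): %s / %s\n",
              paste(x$refraction$astigmatism_breaks, collapse = ", "),
              paste(x$refraction$anisometropia_breaks, collapse = ", ")))
  cat(sprintf("  C stereo breaks (arcsec): %s\n",
              paste(x$stereo$seconds_breaks, collapse = ", ")))
  cat(sprintf("  D structural flag-count breaks: %s\n",
              paste(x$structural_count_breaks, collapse = ", ")))
  invisible(x)
}

# Band score for a scalar feature.  `direction` follows the rubric encoding
# described in read_rubric(); returns NA for a missing feature.
band_score <- function(value, breaks, direction = c("higher_worse",
                                                    "lower_worse")) {
  direction <- match.arg(direction)
  s <- rep(1L, length(value))
  for (b in breaks) {
    s <- s + if (direction == "higher_worse") as.integer(value >= b)
             else as.integer(value < b)
  }
  s[is.na(value)] <- NA_integer_
  pmin(s, 4L)
}
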