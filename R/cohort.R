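#' Define a synthetic cohort specification
#'
#' A cohort spec is a generative model for FASD Eye Code score vectors:
#' one probability table over scores 1--4 per category, an optional
#' rank-dependence parameter, and a sample size.  Dependence is applied via
#' a latent-threshold (Gaussian one-factor) coupling: category k is drawn by
#' thresholding z_k = sqrt(rho) W + sqrt(1-rho) e_k at the quantiles of its
#' table, so marginal tables are preserved exactly and rho = 0 gives
#' independent categories.
#'
#' @param group group label (see the CSV schema; e.g. "FASD", "control").
#' @param n default cohort size.
#' @param p_A,p_B,p_C,p_D probability vectors of length 4 (sum 1).
#' @param dependence rho in \[0, 1).
#' @param seed optional default seed.
#' @return object of class `eyecode_cohort_spec`.
#' @export
cohort_spec <- function(group, n, p_A, p_B, p_C, p_D,
                        dependence = 0, seed = NULL) {
  p <- list(A = p_A, B = p_B, C = p_C, D = p_D)
  for (k in names(p)) {
    pk <- as.numeric(p[[k]])
    ec_assert(length(pk) == 4 && all(is.finite(pk)) && all(pk >= 0),
              sprintf("p_%s must be 4 nonnegative numbers", k))
    ec_assert(abs(sum(pk) - 1) < 1e-9,
              sprintf("p_%s must sum to 1 (within 1e-9)", k))
    p[[k]] <- pk
  }
  ec_assert(length(dependence) == 1 && is.finite(dependence) &&
              dependence >= 0 && dependence < 1,
            "dependence must lie in [0, 1)")
  ec_assert(length(n) == 1 && n == round(n) && n >= 1,
            "n must be a positive integer")
  structure(list(group = as.character(group), n = as.integer(n), p = p,
                 dependence = as.numeric(dependence), seed = seed),
            class = "eyecode_cohort_spec")
}

#' @export
print.eyecode_cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec '%s': n = %d, dependence = %.2f\n",
              x$group, x$n, x$dependence))
  for (k in names(x$p))
    cat(sprintf("  p_%s: %s\n", k,
                paste(sprintf("%.3f", x$p[[k]]), collapse = " ")))
  invisible(x)
}

#' Read / write a cohort spec as JSON
#'
#' @param path file path.
#' @return `read_cohort_spec`: an `eyecode_cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  ec_assert(file.exists(path), sprintf("cohort spec not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_spec(j$group, j$n, j$p$A, j$p$B, j$p$C, j$p$D,
              dependence = j$dependence %||% 0, seed = j$seed)
}

#' @param spec an `eyecode_cohort_spec`.
#' @rdname read_cohort_spec
#' @export
write_cohort_spec <- function(spec, path) {
  ec_assert(inherits(spec, "eyecode_cohort_spec"), "not a cohort spec")
  jsonlite::write_json(
    list(group = spec$group, n = spec$n, p = spec$p,
         dependence = spec$dependence, seed = spec$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Shipped summary-calibrated cohort specs
#'
#' One calibrated spec per study group, stored as JSON under
#' `inst/extdata/cohorts`.  Each is one documented solution to the
#' group-level summary constraints of [cohort_constraints()]; the published
#' summaries do not determine the score distributions uniquely.
#'
#' @param group one of FASD, FAS, PFAS, ARND, control, ADHD, MLP, SRS.
#' @return an `eyecode_cohort_spec`.
#' @export
shipped_cohort_spec <- function(group = c("FASD", "FAS", "PFAS", "ARND",
                                          "control", "ADHD", "MLP", "SRS")) {
  group <- match.arg(group)
  read_cohort_spec(system.file("extdata", "cohorts",
                               paste0(tolower(group), ".json"),
                               package = "eyecode", mustWork = TRUE))
}

# Draw the latent uniforms for n individuals x 4 categories.
latent_uniforms <- function(n, rho) {
  if (rho == 0) {
    matrix(runif(4L * n), nrow = n, ncol = 4L)
  } else {
    w <- rnorm(n)
    e <- matrix(rnorm(4L * n), nrow = n, ncol = 4L)
    pnorm(sqrt(rho) * w + sqrt(1 - rho) * e)
  }
}

#' Simulate score vectors from a cohort spec
#'
#' Deterministic for a fixed seed; marginal category frequencies converge to
#' the spec's tables as n grows.
#'
#' @param spec an `eyecode_cohort_spec`.
#' @param n cohort size (default `spec$n`).
#' @param seed integer seed (default `spec$seed`; `NULL` uses and advances
#'   the current RNG stream).
#' @return data.frame with columns a, b, c, d, total.
#' @export
simulate_scores <- function(spec, n = NULL, seed = NULL) {
  ec_assert(inherits(spec, "eyecode_cohort_spec"), "not a cohort spec")
  n <- as.integer(n %||% spec$n)
  seed <- seed %||% spec$seed
  u <- with_seed_if(seed, latent_uniforms(n, spec$dependence))
  draw <- function(uk, pk) {
    s <- findInterval(uk, cumsum(pk)) + 1L
    pmin(s, 4L)
  }
  a <- draw(u[, 1], spec$p$A); b <- draw(u[, 2], spec$p$B)
  c_ <- draw(u[, 3], spec$p$C); d <- draw(u[, 4], spec$p$D)
  data.frame(a = a, b = b, c = c_, d = d, total = a + b + c_ + d)
}

# Uniform draw strictly inside [lo, hi) with a small guard band so that
# floating-point noise can never push a value onto the wrong side of a band
# boundary.
runif_band <- function(n, lo, hi) {
  ec_assert(hi > lo, "empty band interval")
  pad <- (hi - lo) * 1e-3
  runif(n, lo + pad, hi - pad)
}

# Interval of a higher_worse feature giving exactly score s.
band_interval <- function(s, breaks, cap) {
  lo <- if (s == 1) 0 else breaks[s - 1]
  hi <- if (s > length(breaks)) cap else breaks[s]
  if (hi <= lo)
    ec_stop(sprintf("rubric band for score %d is empty", s))
  c(lo, hi)
}

#' Simulate raw exams that score back to drawn score vectors
#'
#' Inverse-rubric sampling: for each individual a target score vector is
#' drawn from the spec, then raw measurements are drawn uniformly inside a
#' band combination that reproduces the target exactly under the same
#' rubric.  Category A is driven by the worse-eye decimal VA; category B by
#' myopic spherical equivalent or astigmatism (chosen at random); category C
#' by the strabismus class with normal stereoacuity (stereo drives only
#' when the rubric's strabismus map cannot reach the target); category D by
#' the number of structural flags.
#'
#' @inheritParams simulate_scores
#' @param rubric an `eyecode_rubric`.
#' @return data.frame of exams (see [exam_columns()]) with `group` taken
#'   from the spec.
#' @export
simulate_exams <- function(spec, rubric = default_rubric(), n = NULL,
                           seed = NULL) {
  ec_assert(inherits(rubric, "eyecode_rubric"), "rubric must be validated")
  n <- as.integer(n %||% spec$n)
  seed <- seed %||% spec$seed
  with_seed_if(seed, {
    sc <- simulate_scores(spec, n = n, seed = NULL)
    va_breaks <- rubric$acuity_breaks
    rb <- rubric$refraction
    # per-score VA intervals: score 1 lives above the first break
    va_interval <- function(s) {
      if (s == 1) c(va_breaks[1], min(2, va_breaks[1] + 0.45))
      else if (s <= length(va_breaks))
        c(va_breaks[s], va_breaks[s - 1])
      else c(min(0.05, va_breaks[length(va_breaks)] / 2),
             va_breaks[length(va_breaks)])
    }
    strab_inverse <- vapply(1:4, function(s) {
      hit <- names(rubric$strabismus_scores)[rubric$strabismus_scores == s]
      if (length(hit)) hit[1] else NA_character_
    }, character(1))

    ex <- data.frame(
      participant_id = sprintf("sim_%s_%04d", spec$group, seq_len(n)),
      age = round(runif(n, 5, 12), 1),
      sex = sample(SEX_LEVELS, n, replace = TRUE),
      group = spec$group,
      bcva_right = NA_real_, bcva_left = NA_real_,
      sphere_right = NA_real_, sphere_left = NA_real_,
      cylinder_right = 0, cylinder_left = 0,
      axis_right = 0, axis_left = 0,
      strabismus = NA_character_, stereo_test = "TNO",
      stereo_result = NA_character_, structural_flags = NA_character_,
      stringsAsFactors = FALSE)

    for (i in seq_len(n)) {
      iv <- va_interval(sc$a[i])
      va <- runif_band(1, iv[1], iv[2])
      ex$bcva_right[i] <- va; ex$bcva_left[i] <- va

      s <- sc$b[i]
      if (s == 1) {
        sph <- -runif_band(1, 0, rb$myopia_se_breaks[1])
        ex$sphere_right[i] <- sph; ex$sphere_left[i] <- sph
      } else if (runif(1) < 0.5) {
        iv <- band_interval(s, rb$myopia_se_breaks,
                            cap = max(rb$myopia_se_breaks) + 3)
        sph <- -runif_band(1, iv[1], iv[2])
        ex$sphere_right[i] <- sph; ex$sphere_left[i] <- sph
      } else {
        iv <- band_interval(s, rb$astigmatism_breaks,
                            cap = max(rb$astigmatism_breaks) + 2)
        cyl <- runif_band(1, iv[1], iv[2])
        # sphere +cyl/2 keeps the spherical equivalent at zero
        ex$cylinder_right[i] <- -cyl; ex$cylinder_left[i] <- -cyl
        ex$sphere_right[i] <- cyl / 2; ex$sphere_left[i] <- cyl / 2
        ex$axis_right[i] <- 90; ex$axis_left[i] <- 90
      }

      s <- sc$c[i]
      if (!is.na(strab_inverse[s])) {
        ex$strabismus[i] <- strab_inverse[s]
        ex$stereo_result[i] <- as.character(
          round(runif_band(1, 15, rubric$stereo$seconds_breaks[1] - 1)))
      } else {
        ex$strabismus[i] <- "none"
        if (s > length(rubric$stereo$seconds_breaks) + 1)
          ec_stop(sprintf("no band reaches category C score %d", s))
        iv <- band_interval(s, rubric$stereo$seconds_breaks,
                            cap = rubric$stereo$max_seconds)
        ex$stereo_result[i] <- as.character(runif_band(1, iv[1], iv[2]))
      }

      s <- sc$d[i]
      counts <- 0:length(STRUCTURAL_FLAGS)
      ok <- counts[band_score(counts, rubric$structural_count_breaks) == s]
      if (!length(ok))
        ec_stop(sprintf("no flag count yields category D score %d", s))
      k <- ok[1]
      ex$structural_flags[i] <- if (k == 0) "none"
        else paste(sample(STRUCTURAL_FLAGS, k), collapse = ";")
    }
    ex
  })
}
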