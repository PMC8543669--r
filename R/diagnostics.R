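check_totals <- function(x, what) {
  ec_assert(length(x) >= 1, sprintf("%s must be nonempty", what))
  ec_assert(all(!is.na(x)) && all(x == round(x) & x >= 4 & x <= 16),
            sprintf("%s must be integer totals in 4-16", what))
  as.integer(x)
}

#' Diagnostic indices at a single cut-off
#'
#' Cross-tabulates case and non-case totals against `total >= cutoff` and
#' derives sensitivity, specificity, accuracy and both likelihood ratios
#' from the exact fractions.  Percentages are additionally reported rounded
#' half away from zero to whole percent, and likelihood ratios to one
#' decimal, matching how such indices are printed clinically.  LR+ is
#' undefined (`NA`) when specificity is 1 (fp = 0); LR- is undefined when
#' tn = 0.  Undefined ratios are never reported as infinity.
#'
#' @param case_totals,noncase_totals integer totals in 4--16.
#' @param cutoff integer cut-off in 5--16 applied as `>= cutoff`.
#' @return an object of class `eyecode_indices`.
#' @examples
#' # complete separation
#' confusion_at_cutoff(c(12, 13), c(4, 5), cutoff = 10)
#' @export
confusion_at_cutoff <- function(case_totals, noncase_totals, cutoff = 10L) {
  cases <- check_totals(case_totals, "case_totals")
  noncases <- check_totals(noncase_totals, "noncase_totals")
  ec_assert(length(cutoff) == 1 && cutoff == round(cutoff) &&
              cutoff >= 5 && cutoff <= 16,
            "cutoff must be a single integer in 5-16")
  tp <- sum(cases >= cutoff); fn <- length(cases) - tp
  fp <- sum(noncases >= cutoff); tn <- length(noncases) - fp
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  acc <- (tp + tn) / (length(cases) + length(noncases))
  lr_pos <- if (fp > 0) sens / (1 - spec) else NA_real_
  lr_neg <- if (tn > 0) (1 - sens) / spec else NA_real_
  out <- list(
    cutoff = as.integer(cutoff),
    tp = tp, fn = fn, fp = fp, tn = tn,
    n_cases = length(cases), n_noncases = length(noncases),
    sensitivity = sens, specificity = spec, accuracy = acc,
    lr_pos = lr_pos, lr_neg = lr_neg,
    sensitivity_pct = as.integer(round_half_away(100 * sens)),
    specificity_pct = as.integer(round_half_away(100 * spec)),
    accuracy_pct = as.integer(round_half_away(100 * acc)),
    lr_pos_reported = if (is.na(lr_pos)) NA_real_
                      else round_half_away(lr_pos, 1),
    lr_neg_reported = if (is.na(lr_neg)) NA_real_
                      else round_half_away(lr_neg, 1))
  class(out) <- "eyecode_indices"
  out
}

#' @export
print.eyecode_indices <- function(x, ...) {
  fmt_lr <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f", v)
  cat(sprintf("Cut-off >= %d: tp %d fn %d fp %d tn %d\n",
              x$cutoff, x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("  sensitivity %d%%  specificity %d%%  accuracy %d%%\n",
              x$sensitivity_pct, x$specificity_pct, x$accuracy_pct))
  cat(sprintf("  LR+ %s  LR- %s\n",
              fmt_lr(x$lr_pos_reported), fmt_lr(x$lr_neg_reported)))
  invisible(x)
}

#' Positive likelihood ratio from an indices object
#'
#' sensitivity / (1 - specificity), computed from the exact fractions, never
#' from rounded percentages.  `NA` when specificity is 1.
#'
#' @param indices an `eyecode_indices` object.
#' @return numeric; the exact ratio (report with one decimal).
#' @export
lr_positive <- function(indices) {
  ec_assert(inherits(indices, "eyecode_indices"),
            "indices must come from confusion_at_cutoff")
  indices$lr_pos
}

#' Diagnostic index table over all cut-offs
#'
#' One row per cut-off 5..16.  Sensitivity is nonincreasing and specificity
#' nondecreasing as the cut-off rises.
#'
#' @inheritParams confusion_at_cutoff
#' @param cutoffs integer cut-offs; default 5:16.
#' @return data.frame with counts, exact indices and reported (rounded)
#'   columns.
#' @export
indices_table <- function(case_totals, noncase_totals, cutoffs = 5:16) {
  rows <- lapply(cutoffs, function(k) {
    x <- confusion_at_cutoff(case_totals, noncase_totals, k)
    data.frame(cutoff = x$cutoff, tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn,
               sensitivity = x$sensitivity, specificity = x$specificity,
               accuracy = x$accuracy, lr_pos = x$lr_pos, lr_neg = x$lr_neg,
               sensitivity_pct = x$sensitivity_pct,
               specificity_pct = x$specificity_pct,
               accuracy_pct = x$accuracy_pct,
               lr_pos_reported = x$lr_pos_reported,
               lr_neg_reported = x$lr_neg_reported)
  })
  do.call(rbind, rows)
}

#' Mann-Whitney AUC
#'
#' The probability that a random case outscores a random non-case, with ties
#' given half credit: mean over all case x non-case pairs of
#' 1(case > noncase) + 0.5 * 1(tie).  Computed via midranks, which is
#' algebraically identical to the pairwise mean.
#'
#' @param case_values,noncase_values numeric scores (any scale).
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(case_values, noncase_values) {
  ec_assert(length(case_values) >= 1 && length(noncase_values) >= 1,
            "both groups must be nonempty")
  ec_assert(all(is.finite(case_values)) && all(is.finite(noncase_values)),
            "scores must be finite")
  m <- length(case_values); n <- length(noncase_values)
  r <- rank(c(case_values, noncase_values))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Empirical ROC curve
#'
#' Sweeps `score >= t` over thresholds.  For integer Eye Code totals the
#' sweep runs t = 4..17 (so the curve has at most 14 distinct points and
#' always contains (0,0) and (1,1)); for arbitrary scores every observed
#' value plus a sentinel above the maximum is used.  The trapezoidal area
#' under the curve equals the Mann-Whitney statistic exactly; both are
#' returned.
#'
#' @inheritParams auc_mann_whitney
#' @param thresholds optional explicit threshold grid.
#' @return object of class `eyecode_roc` with `points` (threshold, fpr, tpr,
#'   in decreasing-fpr order), `auc` (trapezoidal) and `auc_mw`.
#' @export
roc_curve <- function(case_values, noncase_values, thresholds = NULL) {
  ec_assert(length(case_values) >= 1 && length(noncase_values) >= 1,
            "both groups must be nonempty")
  all_v <- c(case_values, noncase_values)
  ec_assert(all(is.finite(all_v)), "scores must be finite")
  if (is.null(thresholds)) {
    thresholds <- if (all(all_v == round(all_v)) && all(all_v >= 4) &&
                      all(all_v <= 16)) 4:17
                  else c(sort(unique(all_v)), max(all_v) + 1)
  }
  thresholds <- sort(unique(thresholds))
  # a threshold at/below the minimum guarantees the (1,1) corner
  if (thresholds[1] > min(all_v)) thresholds <- c(min(all_v), thresholds)
  tpr <- vapply(thresholds, function(t) mean(case_values >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(noncase_values >= t), numeric(1))
  pts <- data.frame(threshold = thresholds, fpr = fpr, tpr = tpr)
  # trapezoid over points ordered from (1,1) down to (0,0)
  o <- order(pts$fpr, pts$tpr, decreasing = TRUE)
  p <- pts[o, ]
  auc <- sum((p$fpr[-nrow(p)] - p$fpr[-1]) *
             (p$tpr[-nrow(p)] + p$tpr[-1]) / 2)
  out <- list(points = p, auc = auc,
              auc_mw = auc_mann_whitney(case_values, noncase_values),
              n_cases = length(case_values),
              n_noncases = length(noncase_values))
  class(out) <- "eyecode_roc"
  out
}

#' @export
print.eyecode_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC: %d cases vs %d non-cases, AUC %.3f\n",
              x$n_cases, x$n_noncases, x$auc))
  invisible(x)
}

#' @export
plot.eyecode_roc <- function(x, ...) {
  p <- x$points
  plot(p$fpr, p$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "Sensitivity", ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

# DeLong covariance components for the empirical AUC.
delong_components <- function(cases, noncases) {
  m <- length(cases); n <- length(noncases)
  psi <- outer(cases, noncases,
               function(x, y) (x > y) + 0.5 * (x == y))
  v10 <- rowMeans(psi)  # placement of each case among non-cases
  v01 <- colMeans(psi)
  auc <- mean(v10)
  var_auc <- if (m > 1 && n > 1) var(v10) / m + var(v01) / n else NA_real_
  list(auc = auc, var = var_auc)
}

#' Confidence interval for the AUC
#'
#' DeLong's nonparametric variance estimator by default (the convention of
#' the pROC toolchain), or a stratified bootstrap (resampling cases and
#' non-cases separately, percentile interval).  With a degenerate DeLong
#' variance (complete separation, AUC exactly 0 or 1) the function falls
#' back to the bootstrap with a warning.  Intervals are truncated to
#' \[0, 1\] and always contain the point estimate.
#'
#' @inheritParams auc_mann_whitney
#' @param level confidence level, default 0.95.
#' @param method `"delong"` or `"bootstrap"`.
#' @param boot_reps bootstrap replicates (default 2000).
#' @param seed optional integer seed for the bootstrap (the caller's RNG
#'   state is left untouched).
#' @return list with `auc`, `lower`, `upper`, `level`, `method`.
#' @export
auc_ci <- function(case_values, noncase_values, level = 0.95,
                   method = c("delong", "bootstrap"),
                   boot_reps = 2000, seed = NULL) {
  method <- match.arg(method)
  ec_assert(level > 0 && level < 1, "level must be in (0,1)")
  ec_assert(length(case_values) >= 2 && length(noncase_values) >= 2,
            "need at least 2 observations per group")
  auc <- auc_mann_whitney(case_values, noncase_values)
  if (method == "delong") {
    dl <- delong_components(case_values, noncase_values)
    if (!is.na(dl$var) && dl$var > 0) {
      z <- qnorm(1 - (1 - level) / 2)
      half <- z * sqrt(dl$var)
      return(list(auc = auc, lower = max(0, auc - half),
                  upper = min(1, auc + half),
                  level = level, method = "delong"))
    }
    warning("degenerate DeLong variance; falling back to stratified bootstrap")
    method <- "bootstrap"
  }
  boot <- with_seed_if(seed, {
    vapply(seq_len(boot_reps), function(b) {
      cs <- sample(case_values, replace = TRUE)
      ns <- sample(noncase_values, replace = TRUE)
      auc_mann_whitney(cs, ns)
    }, numeric(1))
  })
  qs <- unname(quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2)))
  list(auc = auc, lower = max(0, min(qs[1], auc)),
       upper = min(1, max(qs[2], auc)),
       level = level, method = "bootstrap")
}
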