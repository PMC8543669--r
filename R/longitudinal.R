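#' Wilcoxon signed-rank test for paired Eye Code totals
#'
#' Compares paired measurements (e.g. childhood versus young-adult totals).
#' Zero differences are dropped; tied absolute differences receive average
#' ranks.  For `n_effective <= 12` the two-sided p-value is exact,
#' obtained by enumerating all sign assignments of the observed ranks
#' (a conditional permutation distribution, valid with ties); larger
#' samples use the normal approximation with tie and continuity
#' corrections.  When every difference is zero the test is vacuous and
#' p = 1.
#'
#' @param x either a numeric vector of first measurements (e.g. childhood
#'   totals) or a data.frame with columns `total_child` and `total_adult`.
#' @param y second measurements, paired with `x` (ignored when `x` is a
#'   data.frame).
#' @param method `"auto"` (exact up to n_effective 12), `"exact"`, or
#'   `"normal"`.
#' @return list with `statistic` (V, the positive-rank sum of y - x),
#'   `p_value`, `n_effective`, `method_used`, classed `eyecode_wilcoxon`.
#' @examples
#' wilcoxon_signed_rank(rep(0, 5), 1:5)  # V = 15, exact p = 0.0625
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (is.data.frame(x)) {
    ec_assert(all(c("total_child", "total_adult") %in% names(x)),
              "paired data.frame needs total_child and total_adult")
    y <- x$total_adult; x <- x$total_child
  }
  ec_assert(length(x) >= 1 && length(x) == length(y),
            "x and y must be nonempty and of equal length")
  ec_assert(all(is.finite(x)) && all(is.finite(y)),
            "paired values must be finite")
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    out <- list(statistic = 0, p_value = 1, n_effective = 0L,
                method_used = "degenerate")
    class(out) <- "eyecode_wilcoxon"
    return(out)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  use_exact <- switch(method, exact = TRUE, normal = FALSE, auto = n <= 12)
  if (use_exact) {
    # distribution of the positive-rank sum over all 2^n sign assignments;
    # doubled ranks are integers even under midranks
    r2 <- as.integer(round(2 * r))
    f <- numeric(sum(r2) + 1)
    f[1] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), f[seq_len(length(f) - rk)])
      f <- f + shifted
    }
    f <- f / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(f[seq_len(v2 + 1)])
    p_ge <- sum(f[(v2 + 1):length(f)])
    p <- min(1, 2 * min(p_le, p_ge))
    used <- "exact"
  } else {
    e_v <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- v - e_v
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    used <- "normal"
  }
  out <- list(statistic = v, p_value = p, n_effective = as.integer(n),
              method_used = used)
  class(out) <- "eyecode_wilcoxon"
  out
}

#' @export
print.eyecode_wilcoxon <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: V = %g, p = %.4g (n_effective = %d, %s)\n",
              x$statistic, x$p_value, x$n_effective, x$method_used))
  invisible(x)
}

#' Per-individual stability of paired totals
#'
#' Tabulates delta = total_adult - total_child for every participant and
#' summarises the cohort: median delta and the share of individuals whose
#' total changed by at most one point.
#'
#' @param pairs data.frame with `participant_id`, `total_child`,
#'   `total_adult` and optionally `subgroup`.
#' @return list with `deltas` (per-individual table) and `summary`.
#' @export
stability_report <- function(pairs) {
  ec_assert(is.data.frame(pairs) && nrow(pairs) >= 1,
            "pairs must be a nonempty data.frame")
  need <- c("participant_id", "total_child", "total_adult")
  miss <- setdiff(need, names(pairs))
  ec_assert(length(miss) == 0,
            paste("pairs lacks columns:", paste(miss, collapse = ", ")))
  ec_assert(!anyDuplicated(pairs$participant_id),
            "participant ids must be unique")
  for (cl in c("total_child", "total_adult"))
    check_totals(pairs[[cl]], cl)
  delta <- pairs$total_adult - pairs$total_child
  deltas <- data.frame(
    participant_id = pairs$participant_id,
    subgroup = if ("subgroup" %in% names(pairs))
                 as.character(pairs$subgroup) else NA_character_,
    total_child = pairs$total_child, total_adult = pairs$total_adult,
    delta = delta, stringsAsFactors = FALSE)
  list(deltas = deltas,
       summary = list(
         n = nrow(pairs),
         median_delta = median(delta),
         share_within_1 = mean(abs(delta) <= 1),
         share_unchanged = mean(delta == 0)))
}
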