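# Exact distribution of the total under a spec's tables.  With dependence 0
# this is the 4-fold convolution of the category tables; with a one-factor
# latent coupling the total law is obtained by integrating the conditional
# (independent-given-factor) convolution over the factor with a fixed
# Gaussian grid.  Deterministic, so it can serve as a search objective.
total_pmf <- function(p, rho = 0) {
  if (rho == 0) {
    pmf <- 1
    for (pk in p) {
      new <- numeric(length(pmf) + 3)
      for (s in 1:4)
        new[seq_along(pmf) + s - 1] <- new[seq_along(pmf) + s - 1] + pmf * pk[s]
      pmf <- new
    }
    return(stats::setNames(pmf, 4:16))
  }
  w <- seq(-7, 7, length.out = 81)
  dw <- dnorm(w); dw <- dw / sum(dw)
  sr <- sqrt(rho); sc <- sqrt(1 - rho)
  m <- matrix(1, nrow = length(w), ncol = 1)  # conditional pmf per node
  for (pk in p) {
    cum <- pmin(pmax(cumsum(pk)[1:3], 1e-12), 1 - 1e-12)
    thr <- matrix(qnorm(cum), length(w), 3, byrow = TRUE)
    cd <- cbind(0, pnorm((thr - sr * w) / sc), 1)
    cond <- cd[, 2:5] - cd[, 1:4]
    mn <- matrix(0, length(w), ncol(m) + 3)
    for (s in 1:4) {
      idx <- s:(s + ncol(m) - 1)
      mn[, idx] <- mn[, idx] + m * cond[, s]
    }
    m <- mn
  }
  stats::setNames(colSums(m * dw), 4:16)
}

#' Published group-summary constraints
#'
#' The per-group calibration targets used for the shipped cohort specs:
#' category medians, the total-score median and printed range, and the
#' exceedance counts at the >=10 cut-off (16/37 FASD, 13/21 FAS, 6/33 ADHD,
#' 3/57 MLP, 3/16 SRS, 0/65 controls).  The control group additionally pins
#' both quartiles of the total at 4 (printed IQR 0).
#'
#' @param group group label.
#' @return a constraints list accepted by [calibrate_to_summaries()].
#' @export
cohort_constraints <- function(group = c("FASD", "FAS", "PFAS", "ARND",
                                         "control", "ADHD", "MLP", "SRS")) {
  group <- match.arg(group)
  switch(group,
    FASD = list(group = "FASD", n = 37,
                category_medians = c(A = 1, B = 2, C = 3, D = 3),
                total_median = 9, total_range = c(4, 16),
                exceedance = list(list(cutoff = 10, prob = 16 / 37))),
    FAS = list(group = "FAS", n = 21,
               category_medians = c(A = 2, B = 1, C = 3, D = 3),
               total_median = 10, total_range = c(4, 16),
               exceedance = list(list(cutoff = 10, prob = 13 / 21))),
    PFAS = list(group = "PFAS", n = 10,
                category_medians = c(A = 1.5, B = 1.5, C = 1, D = 2.5),
                total_median = 7, total_range = c(4, 11)),
    ARND = list(group = "ARND", n = 6,
                category_medians = c(A = 2, B = 1, C = 2.5, D = 2),
                total_median = 7.5, total_range = c(4, 12)),
    control = list(group = "control", n = 65,
                   category_medians = c(A = 1, B = 1, C = 1, D = 1),
                   total_median = 4, total_q1 = 4, total_q3 = 4,
                   total_range = c(4, 9), dependence = 0,
                   exceedance = list(list(cutoff = 10, prob = 0))),
    ADHD = list(group = "ADHD", n = 33,
                category_medians = c(A = 1, B = 1, C = 1, D = 1),
                total_median = 7, total_range = c(4, 11),
                exceedance = list(list(cutoff = 10, prob = 6 / 33))),
    MLP = list(group = "MLP", n = 57,
               category_medians = c(A = 1, B = 1, C = 1, D = 1),
               total_median = 5, total_range = c(4, 13),
               exceedance = list(list(cutoff = 10, prob = 3 / 57))),
    SRS = list(group = "SRS", n = 16,
               category_medians = c(A = 1, B = 1.5, C = 1, D = 3),
               total_median = 7, total_range = c(4, 13),
               exceedance = list(list(cutoff = 10, prob = 3 / 16))))
}

# Support caps per category so that the maximal attainable total equals the
# printed range maximum.  Each cap starts at the score needed to honour the
# category median target and the remainder is distributed from category D
# backwards, one level per pass.
support_caps <- function(catmed, total_max) {
  base <- pmax(1L, as.integer(ceiling(catmed %||% c(A = 1, B = 1, C = 1,
                                                    D = 1))))
  names(base) <- c("A", "B", "C", "D")
  extra <- total_max - sum(base)
  ec_assert(extra >= 0,
            "total range maximum inconsistent with category medians",
            class = "eyecode_infeasible_error")
  while (extra > 0) {
    advanced <- FALSE
    for (k in c("D", "C", "B", "A")) {
      if (extra > 0 && base[k] < 4L) {
        base[k] <- base[k] + 1L
        extra <- extra - 1
        advanced <- TRUE
      }
    }
    if (!advanced)
      ec_stop("total range maximum exceeds 16",
              class = "eyecode_infeasible_error")
  }
  base
}

# Violations of one constraint set, all nonnegative, named.  Quantile
# targets are enforced with a margin delta on the population CDF so large
# simulated cohorts hit the target quantile exactly; half-integer medians
# instead pin the CDF near 0.5 at the floor value.
constraint_violations <- function(p, rho, constraints, delta = 0.03,
                                  exc_tol = 0.005) {
  v <- c()
  quant_viol <- function(cdf, values, target, q, label) {
    if (target == round(target)) {
      i <- match(target, values)
      below <- if (i > 1) cdf[i - 1] else 0
      z <- c(max(0, below - (q - delta)), max(0, (q + delta) - cdf[i]))
      stats::setNames(z, paste0(label, c("_below", "_at")))
    } else {
      i <- match(floor(target), values)
      stats::setNames(max(0, abs(cdf[i] - q) - 0.01), label)
    }
  }
  for (k in names(constraints$category_medians %||% c())) {
    m <- constraints$category_medians[[k]]
    cdf <- cumsum(p[[k]])
    v <- c(v, quant_viol(cdf, 1:4, m, 0.5, paste0("median_", k)))
  }
  pmf <- total_pmf(p, rho)
  cdf <- cumsum(pmf)
  if (!is.null(constraints$total_median))
    v <- c(v, quant_viol(cdf, 4:16, constraints$total_median, 0.5,
                         "total_median"))
  if (!is.null(constraints$total_q1))
    v <- c(v, quant_viol(cdf, 4:16, constraints$total_q1, 0.25, "total_q1"))
  if (!is.null(constraints$total_q3))
    v <- c(v, quant_viol(cdf, 4:16, constraints$total_q3, 0.75, "total_q3"))
  for (e in constraints$exceedance %||% list()) {
    pr <- sum(pmf[as.numeric(names(pmf)) >= e$cutoff])
    v <- c(v, stats::setNames(max(0, abs(pr - e$prob) - exc_tol),
                              sprintf("exceedance_ge%d", e$cutoff)))
  }
  v
}

init_tables <- function(caps, catmed) {
  p <- list()
  for (k in c("A", "B", "C", "D")) {
    L <- caps[[k]]
    w <- numeric(4)
    m <- if (!is.null(catmed) && k %in% names(catmed)) catmed[[k]] else 1
    lo <- min(max(1L, floor(m)), L)
    w[1:lo] <- 0.6 / lo
    if (L > lo) w[(lo + 1):L] <- 0.4 / (L - lo)
    p[[k]] <- w / sum(w)
  }
  p
}

#' Calibrate a cohort spec to published summary statistics
#'
#' Searches for per-category probability tables (and, unless pinned, a
#' latent dependence parameter) whose implied total-score distribution
#' satisfies the supplied constraints: category medians, total median and
#' quartiles, total range (enforced structurally: the support of implied
#' totals equals the printed range), and exceedance probabilities at
#' cut-offs.  The search is a seeded stochastic hill-climb minimising the
#' sum of constraint violations computed from the exact total distribution;
#' it stops when every violation is zero.  Many tables satisfy any given
#' summary set — the result is one documented solution, not a unique
#' reconstruction.
#'
#' @param constraints list with optional fields `group`, `n`,
#'   `category_medians` (named A--D, may be half-integers), `total_median`,
#'   `total_q1`, `total_q3`, `total_range` (c(min, max), min must be 4),
#'   `exceedance` (list of `list(cutoff =, prob =)`), `dependence` (pin the
#'   coupling instead of searching it).
#' @param seed integer seed for the search.
#' @param max_iter hill-climb iterations per restart.
#' @param restarts independent restarts; the first solution found wins.
#' @return an `eyecode_cohort_spec` whose large-n cohorts reproduce the
#'   constrained quantiles exactly and exceedance proportions within the
#'   stated tolerance.
#' @examples
#' spec <- calibrate_to_summaries(cohort_constraints("control"), seed = 1)
#' range(simulate_scores(spec, n = 1000, seed = 1)$total)  # within 4..9
#' @export
calibrate_to_summaries <- function(constraints, seed = 1,
                                   max_iter = 20000, restarts = 4) {
  rng <- constraints$total_range %||% c(4, 16)
  ec_assert(rng[1] == 4,
            "total range minimum must be 4 (all categories attain 1)",
            class = "eyecode_infeasible_error")
  caps <- support_caps(constraints$category_medians, rng[2])
  fixed_rho <- constraints$dependence
  floor_w <- 2e-3

  best <- NULL; best_obj <- Inf; best_viol <- NULL
  for (r in seq_len(restarts)) {
    res <- with_seed_if(seed + 1000L * (r - 1L), {
      p <- init_tables(caps, constraints$category_medians)
      rho <- fixed_rho %||% 0.25
      viol <- constraint_violations(p, rho, constraints)
      obj <- sum(viol)
      it <- 0L
      while (obj > 0 && it < max_iter) {
        it <- it + 1L
        p2 <- p; rho2 <- rho
        if (is.null(fixed_rho) && runif(1) < 0.15) {
          rho2 <- min(0.95, max(0, rho + rnorm(1, 0, 0.08)))
        } else {
          k <- sample(c("A", "B", "C", "D"), 1)
          L <- caps[[k]]
          if (L > 1) {
            w <- p2[[k]][1:L]
            if (runif(1) < 0.3) {
              # transfer a fraction of one cell's mass to another
              ij <- sample.int(L, 2)
              amt <- w[ij[1]] * runif(1, 0, 0.5)
              w[ij[1]] <- w[ij[1]] - amt
              w[ij[2]] <- w[ij[2]] + amt
            } else {
              j <- sample.int(L, 1)
              w[j] <- w[j] * exp(rnorm(1, 0, 0.5))
            }
            w <- pmax(w / sum(w), floor_w)
            p2[[k]][1:L] <- w / sum(w)
          }
        }
        viol2 <- constraint_violations(p2, rho2, constraints)
        obj2 <- sum(viol2)
        if (obj2 <= obj) {
          p <- p2; rho <- rho2; obj <- obj2; viol <- viol2
        }
      }
      list(p = p, rho = rho, obj = obj, viol = viol)
    })
    if (res$obj < best_obj) {
      best <- res; best_obj <- res$obj; best_viol <- res$viol
    }
    if (best_obj == 0) break
  }

  if (best_obj > 0) {
    worst <- names(best_viol)[which.max(best_viol)]
    ec_stop(sprintf(
      "calibration infeasible or search failed; worst violated constraint: %s (%.4f)",
      worst, max(best_viol)), class = "eyecode_infeasible_error")
  }
  cohort_spec(constraints$group %||% "unknown", constraints$n %||% 100L,
              best$p$A, best$p$B, best$p$C, best$p$D,
              dependence = best$rho)
}
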