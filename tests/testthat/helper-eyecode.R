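# Fixtures are built in code; no data files are stored.

# A single exam row with every finding normal; override any field.
make_exam <- function(...) {
  ex <- data.frame(
    participant_id = "p1", age = 8, sex = "female", group = "control",
    bcva_right = 1.0, bcva_left = 1.0,
    sphere_right = 0.25, sphere_left = 0.25,
    cylinder_right = 0, cylinder_left = 0,
    axis_right = 0, axis_left = 0,
    strabismus = "none", stereo_test = "TNO", stereo_result = "60",
    structural_flags = "none",
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) ex[[nm]] <- over[[nm]]
  ex
}

# Random derived-feature rows for property tests on category scoring.
random_features <- function(n) {
  data.frame(
    participant_id = sprintf("f%03d", seq_len(n)),
    va = runif(n, 0.1, 1.2),
    myopia_se = runif(n, 0, 6),
    hypermetropia_se = runif(n, 0, 7),
    astigmatism = runif(n, 0, 4),
    anisometropia = runif(n, 0, 4),
    strabismus = sample(c("none", "heterophoria", "intermittent_tropia",
                          "manifest_tropia"), n, replace = TRUE),
    stereo_kind = "seconds",
    stereo_seconds = runif(n, 15, 3000),
    n_structural = sample(0:5, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# Pairwise brute-force Mann-Whitney AUC (independent oracle).
auc_pairwise <- function(cases, noncases) {
  s <- 0
  for (x in cases) for (y in noncases)
    s <- s + (x > y) + 0.5 * (x == y)
  s / (length(cases) * length(noncases))
}

# Brute-force exact two-sided signed-rank p via full sign enumeration
# (independent of the package's convolution).
wilcoxon_bruteforce_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Independent per-step matching oracle: exhaustively evaluate every
# remaining candidate with stats::t.test (pooled variance) where group
# sizes permit, falling back to the floored formula for singleton groups.
oracle_step <- function(case_m, pool_m, selected, remaining, variables) {
  best <- Inf; best_i <- NA_integer_
  for (i in remaining) {
    tmax <- 0
    for (j in seq_along(variables)) {
      x <- case_m[, j]; y <- c(pool_m[selected, j], pool_m[i, j])
      tv <- if (length(y) >= 2 && (var(x) > 0 || var(y) > 0))
        abs(unname(stats::t.test(x, y, var.equal = TRUE)$statistic))
      else {
        vp <- ((length(x) - 1) * var(x) +
                 (length(y) - 1) * (if (length(y) > 1) var(y) else 0)) /
          (length(x) + length(y) - 2)
        abs((mean(x) - mean(y)) /
              sqrt(max(vp, 1e-12) * (1 / length(x) + 1 / length(y))))
      }
      tmax <- max(tmax, tv)
    }
    if (tmax < best) { best <- tmax; best_i <- i }
  }
  best_i
}

# Score totals reproducing the published per-group exceedance counts at the
# >=10 cut-off; the exact totals are irrelevant for confusion counts, only
# their side of the cut-off matters.
counts_cohort <- function(n_pos, n_total, pos = 10L, neg = 4L) {
  c(rep(pos, n_pos), rep(neg, n_total - n_pos))
}
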