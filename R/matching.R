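# Two-sample t statistic with a variance floor so that zero-variance
# matching variables degrade to a standardized mean difference instead of
# dividing by zero.
t_statistic <- function(x, y, method = "pooled", var_floor = 1e-12) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- if (n1 > 1) var(x) else 0
  v2 <- if (n2 > 1) var(y) else 0
  if (method == "pooled") {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / max(1, n1 + n2 - 2)
    (m1 - m2) / sqrt(max(vp, var_floor) * (1 / n1 + 1 / n2))
  } else {
    (m1 - m2) / sqrt(max(v1 / n1 + v2 / n2, var_floor))
  }
}

code_variable <- function(x, name) {
  if (is.numeric(x)) return(as.numeric(x))
  if (name == "sex") {
    ec_assert(all(x %in% SEX_LEVELS),
              "sex must be 'female'/'male' or numeric 0/1")
    return(as.numeric(x == "male"))  # female 0, male 1
  }
  ec_stop(sprintf("matching variable '%s' is not numeric", name))
}

#' Greedy control matching by minimal maximal t-statistic
#'
#' Selects `n_select` controls from a reference pool one at a time: at each
#' step, for every unselected candidate and every matching variable, the
#' two-sample t-statistic between the case group and the already-selected
#' controls plus that candidate is computed, and the candidate minimising
#' the maximum |t| over variables is added.  Ties are broken by input
#' order; selection is without replacement and fully deterministic.  Sex
#' enters as a 0/1 coding (a proportion comparison), an approximation of
#' the population-matching method this mirrors.
#'
#' @param cases,pool data.frames with `participant_id` and the matching
#'   variables; ids must be unique and the two sets disjoint.
#' @param n_select number of controls to select (at most `nrow(pool)`).
#' @param variables matching variable names, default `c("age", "sex")`.
#' @param method `"pooled"` (pooled-variance t, default) or `"welch"`.
#' @return object of class `eyecode_match`: `selected` (ids in selection
#'   order) and `trace` (per-step max |t|).
#' @examples
#' cases <- data.frame(participant_id = c("a", "b"), age = c(10, 10),
#'                     sex = c("male", "female"))
#' pool <- data.frame(participant_id = c("p1", "p2", "p3"),
#'                    age = c(9, 10, 20), sex = "male")
#' match_controls(cases, pool, 1, variables = "age")$selected  # "p2"
#' @export
match_controls <- function(cases, pool, n_select,
                           variables = c("age", "sex"),
                           method = c("pooled", "welch")) {
  method <- match.arg(method)
  ec_assert(is.data.frame(cases) && nrow(cases) >= 1, "cases must be nonempty")
  ec_assert(is.data.frame(pool) && nrow(pool) >= 1, "pool must be nonempty")
  ec_assert(n_select >= 1 && n_select <= nrow(pool),
            "n_select must be between 1 and the pool size")
  for (df_name in c("cases", "pool")) {
    df <- get(df_name)
    ec_assert("participant_id" %in% names(df),
              sprintf("%s must carry participant_id", df_name))
    miss <- setdiff(variables, names(df))
    ec_assert(length(miss) == 0,
              sprintf("%s lacks matching variables: %s", df_name,
                      paste(miss, collapse = ", ")))
    ec_assert(!anyDuplicated(df$participant_id),
              sprintf("duplicate participant_id in %s", df_name))
  }
  ec_assert(length(intersect(cases$participant_id, pool$participant_id)) == 0,
            "pool must be disjoint from cases")

  case_m <- vapply(variables, function(v) code_variable(cases[[v]], v),
                   numeric(nrow(cases)))
  case_m <- matrix(case_m, nrow = nrow(cases))
  pool_m <- vapply(variables, function(v) code_variable(pool[[v]], v),
                   numeric(nrow(pool)))
  pool_m <- matrix(pool_m, nrow = nrow(pool))
  ec_assert(all(is.finite(case_m)) && all(is.finite(pool_m)),
            "matching variables must be finite")

  selected <- integer(0)
  remaining <- seq_len(nrow(pool))
  trace <- data.frame(step = integer(0), participant_id = character(0),
                      max_abs_t = numeric(0), stringsAsFactors = FALSE)
  for (step in seq_len(n_select)) {
    best_t <- Inf; best_i <- NA_integer_
    for (i in remaining) {
      cand <- c(selected, i)
      tmax <- 0
      for (j in seq_along(variables)) {
        tv <- abs(t_statistic(case_m[, j], pool_m[cand, j], method))
        if (tv > tmax) tmax <- tv
      }
      if (tmax < best_t) { best_t <- tmax; best_i <- i }
    }
    selected <- c(selected, best_i)
    remaining <- setdiff(remaining, best_i)
    trace <- rbind(trace, data.frame(
      step = step, participant_id = pool$participant_id[best_i],
      max_abs_t = best_t, stringsAsFactors = FALSE))
  }
  structure(list(selected = pool$participant_id[selected], trace = trace,
                 variables = variables, method = method),
            class = "eyecode_match")
}

#' @export
print.eyecode_match <- function(x, ...) {
  cat(sprintf("Greedy min-max-t matching: %d controls selected on %s (%s t)\n",
              length(x$selected), paste(x$variables, collapse = ", "),
              x$method))
  cat(sprintf("  final max |t| = %.4f\n",
              x$trace$max_abs_t[nrow(x$trace)]))
  invisible(x)
}
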