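# Parse a character column to numeric, collecting row-level errors.
parse_numeric_col <- function(x, col, errors) {
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    if (is.na(s) || !nzchar(s)) next
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v))
      errors$add(sprintf("row %d, column %s: value '%s' is not numeric",
                         i, col, s))
    out[i] <- v
  }
  out
}

error_collector <- function() {
  msgs <- character(0)
  list(add = function(m) msgs <<- c(msgs, m),
       any = function() length(msgs) > 0,
       messages = function() msgs)
}

#' Read an exam table from CSV
#'
#' One row per participant, columns exactly as [exam_columns()] (unknown
#' extra columns are preserved untouched).  Missing measurements are empty
#' cells.  Malformed values are reported with their row and column; a file
#' with only a header yields an empty table, not an error.
#'
#' @param path CSV path.
#' @return validated exam data.frame.
#' @export
read_exams <- function(path) {
  ec_assert(file.exists(path), sprintf("file not found: %s", path))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(exam_columns(), names(raw))
  ec_assert(length(miss) == 0,
            paste("missing mandatory columns:", paste(miss, collapse = ", ")))
  errs <- error_collector()
  blank_na <- function(x) ifelse(is.na(x) | !nzchar(x), NA_character_, x)
  out <- raw
  num_cols <- c("age", "bcva_right", "bcva_left", "sphere_right",
                "sphere_left", "cylinder_right", "cylinder_left",
                "axis_right", "axis_left")
  for (cl in num_cols) out[[cl]] <- parse_numeric_col(raw[[cl]], cl, errs)
  for (cl in c("participant_id", "sex", "group", "strabismus", "stereo_test",
               "stereo_result", "structural_flags"))
    out[[cl]] <- blank_na(raw[[cl]])

  check_level <- function(col, levels, required = FALSE) {
    x <- out[[col]]
    for (i in seq_along(x)) {
      if (is.na(x[i])) {
        if (required)
          errs$add(sprintf("row %d, column %s: value is required", i, col))
      } else if (!(x[i] %in% levels)) {
        errs$add(sprintf("row %d, column %s: invalid value '%s'",
                         i, col, x[i]))
      }
    }
  }
  check_level("sex", SEX_LEVELS)
  check_level("group", GROUP_LEVELS)
  check_level("strabismus", STRABISMUS_LEVELS)
  check_level("stereo_test", STEREO_TESTS)

  for (i in seq_len(nrow(out))) {
    if (is.na(out$participant_id[i]))
      errs$add(sprintf("row %d, column participant_id: value is required", i))
    for (cl in c("bcva_right", "bcva_left")) {
      v <- out[[cl]][i]
      if (!is.na(v) && (v <= 0 || v > 2))
        errs$add(sprintf("row %d, column %s: decimal VA must lie in (0, 2]",
                         i, cl))
    }
    for (cl in c("axis_right", "axis_left")) {
      v <- out[[cl]][i]
      if (!is.na(v) && (v < 0 || v >= 180))
        errs$add(sprintf("row %d, column %s: axis must lie in [0, 180)",
                         i, cl))
    }
    v <- out$age[i]
    if (!is.na(v) && v < 0)
      errs$add(sprintf("row %d, column age: age must be nonnegative", i))
    sr <- out$stereo_result[i]
    if (!is.na(sr) && !(sr %in% c("pass", "fail", "untestable"))) {
      sec <- suppressWarnings(as.numeric(sr))
      if (is.na(sec) || sec <= 0)
        errs$add(sprintf(
          "row %d, column stereo_result: '%s' is neither seconds-of-arc nor pass/fail/untestable",
          i, sr))
      else if (is.na(out$stereo_test[i]) || out$stereo_test[i] == "none")
        errs$add(sprintf(
          "row %d, column stereo_result: seconds-of-arc require stereo_test TNO or LangI",
          i))
    }
    fl <- out$structural_flags[i]
    if (!is.na(fl) && fl != "none") {
      toks <- trimws(strsplit(fl, ";", fixed = TRUE)[[1]])
      toks <- toks[nzchar(toks)]
      if (!length(toks) || !all(toks %in% STRUCTURAL_FLAGS) ||
            anyDuplicated(toks))
        errs$add(sprintf(
          "row %d, column structural_flags: invalid flag list '%s'", i, fl))
    }
  }
  if (errs$any()) {
    msgs <- errs$messages()
    shown <- utils::head(msgs, 10)
    more <- if (length(msgs) > 10)
      sprintf("\n  ... and %d more", length(msgs) - 10) else ""
    ec_stop(paste0("invalid exam table:\n  ",
                   paste(shown, collapse = "\n  "), more))
  }
  out
}

#' Write an exam table to CSV
#'
#' Numeric columns are written with full (17 significant digit) precision so
#' that `read_exams(write_exams(x))` round-trips losslessly; missing values
#' become empty cells.
#'
#' @param exams exam data.frame.
#' @param path output CSV path.
#' @export
write_exams <- function(exams, path) {
  out <- exams
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]))
      out[[cl]] <- ifelse(is.na(out[[cl]]), "",
                          sprintf("%.17g", out[[cl]]))
  }
  write.csv(out, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

#' Read / write score tables
#'
#' Score CSVs carry `participant_id`, `group` and `total` (plus any extra
#' columns, preserved).  Lines starting with `#` are provenance comments
#' and are skipped on read.
#'
#' @param path CSV path.
#' @return `read_scores`: data.frame with totals validated against 4--16.
#' @export
read_scores <- function(path) {
  ec_assert(file.exists(path), sprintf("file not found: %s", path))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("participant_id", "group", "total"), names(df))
  ec_assert(length(miss) == 0,
            paste("missing mandatory columns:", paste(miss, collapse = ", ")))
  if (nrow(df)) {
    keep <- !is.na(df$total)
    ec_assert(all(df$total[keep] == round(df$total[keep]) &
                    df$total[keep] >= 4 & df$total[keep] <= 16),
              "totals must be integers in 4-16 (or empty for incomplete)")
  }
  df
}

#' @param scores data.frame to write.
#' @param provenance character vector of comment lines (written as
#'   `# ...` headers).
#' @rdname read_scores
#' @export
write_scores <- function(scores, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance))
    writeLines(paste0("# ", provenance), con)
  utils::write.table(scores, con, sep = ",", row.names = FALSE, na = "",
                     qmethod = "double")
  invisible(path)
}

totals_by_group <- function(scores) {
  keep <- !is.na(scores$total)
  split(as.integer(scores$total[keep]), scores$group[keep])
}
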