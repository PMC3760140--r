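#' Read and write trial-level and covariate CSV files
#'
#' Strict, lossless round-trip serialization of trial records and subject
#' covariates. Readers validate the schema up front and name any missing
#' column; parsing problems are reported with line numbers. Missed trials
#' are written with empty choice/transition/reward fields and survive the
#' round trip as `NA`.
#'
#' @param trials,covariates Tibbles as produced by the simulators.
#' @param path File path.
#' @return Readers return validated tibbles; writers return the input
#'   invisibly.
#' @name twostep_io
NULL

check_schema <- function(found, expected, path) {
  missing_cols <- setdiff(expected, found)
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
}

check_problems <- function(df, path) {
  pr <- readr::problems(df)
  if (nrow(pr)) {
    stop(sprintf("%s: parse error at line %d, column %d: expected %s, got %s",
                 path, pr$row[1], pr$col[1], pr$expected[1], pr$actual[1]),
         call. = FALSE)
  }
  df
}

trial_cols <- c("subject_id", "trial", "choice1", "pair", "common",
                "choice2", "reward", "missed")

#' @rdname twostep_io
#' @export
write_trials <- function(trials, path) {
  check_schema(names(trials), trial_cols, "trials")
  readr::write_csv(trials[trial_cols], path, na = "")
  invisible(trials)
}

#' @rdname twostep_io
#' @export
read_trials <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  check_schema(hdr, trial_cols, path)
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      trial = readr::col_integer(),
      choice1 = readr::col_integer(),
      pair = readr::col_integer(),
      common = readr::col_logical(),
      choice2 = readr::col_integer(),
      reward = readr::col_integer(),
      missed = readr::col_logical()
    ),
    na = ""
  )
  check_problems(out, path)
  bad <- which(out$missed &
                 (!is.na(out$choice1) | !is.na(out$choice2) | !is.na(out$reward)))
  if (length(bad)) {
    stop(sprintf("%s: line %d: missed trial has non-empty choice/reward fields",
                 path, bad[1] + 1L), call. = FALSE)
  }
  out
}

covariate_cols <- c("subject_id", "subsample", "extraversion_raw", "extra")

#' @rdname twostep_io
#' @export
write_covariates <- function(covariates, path) {
  check_schema(names(covariates), covariate_cols, "covariates")
  readr::write_csv(covariates[covariate_cols], path, na = "")
  invisible(covariates)
}

#' @rdname twostep_io
#' @export
read_covariates <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  check_schema(hdr, covariate_cols, path)
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      subsample = readr::col_integer(),
      extraversion_raw = readr::col_double(),
      extra = readr::col_double()
    ),
    na = ""
  )
  check_problems(out, path)
  out
}
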