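#' Encode raw trials into the factorial stay/switch design
#'
#' Builds one regression row per consecutive pair of completed trials
#' (n, n+1) of the same subject: the outcome `stay` is 1 when the
#' first-stage choice on trial n+1 repeats the choice on trial n, and the
#' predictors come from trial n with the factorial +/-1 coding — `rew` is
#' +1 if trial n was rewarded and -1 otherwise, `trans` is +1 after a
#' common transition and -1 after a rare one, and `rewXtrans` is their
#' product. Pairs touching a missed trial are dropped.
#'
#' @param trials A tibble of trial records as produced by
#'   [simulate_session()] or [read_trials()], sorted by subject and trial.
#'
#' @return A tibble of design rows with columns `subject_id`,
#'   `outcome_trial` (the index of trial n+1), `stay`, `rew`, `trans`,
#'   `rewXtrans`.
#' @examples
#' trials <- simulate_session(random_agent(), task_config(n_trials = 20), seed = 1)
#' encode_trials(trials)
#' @export
encode_trials <- function(trials) {
  need <- c("subject_id", "trial", "choice1", "common", "reward", "missed")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    stop("`trials` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(trials[c("subject_id", "trial")])) {
    stop("duplicate (subject_id, trial) keys in `trials`", call. = FALSE)
  }
  trials |>
    dplyr::arrange(.data$subject_id, .data$trial) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(
      next_trial = dplyr::lead(.data$trial),
      next_choice1 = dplyr::lead(.data$choice1),
      next_missed = dplyr::lead(.data$missed)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(
      !is.na(.data$next_trial),
      .data$next_trial == .data$trial + 1L,
      !.data$missed,
      !.data$next_missed
    ) |>
    dplyr::transmute(
      subject_id = .data$subject_id,
      outcome_trial = .data$next_trial,
      stay = as.integer(.data$next_choice1 == .data$choice1),
      rew = ifelse(.data$reward == 1L, 1, -1),
      trans = ifelse(.data$common, 1, -1),
      rewXtrans = .data$rew * .data$trans
    )
}

#' Split encoded rows into odd- and even-trial subsets
#'
#' Partitions design rows by the parity of a trial number, supporting the
#' cross-fitting scheme in which the engagement score is defined on
#' odd-numbered trials and its effects are tested on even-numbered trials.
#' Each row spans two trials (n, n+1); by default parity is taken on the
#' outcome trial n+1, with `on = "previous"` using trial n instead. Both
#' conventions must (and do) leave the downstream pipeline qualitatively
#' unchanged; the switch exists because the trial-pair convention is
#' ambiguous in common usage.
#'
#' @param rows Encoded design rows from [encode_trials()].
#' @param on Which trial index carries the parity: `"outcome"` (trial n+1,
#'   default) or `"previous"` (trial n).
#'
#' @return A list with tibbles `odd` and `even`; a disjoint partition of
#'   the input rows.
#' @export
split_odd_even <- function(rows, on = c("outcome", "previous")) {
  on <- match.arg(on)
  stopifnot("outcome_trial" %in% names(rows))
  idx <- if (on == "outcome") rows$outcome_trial else rows$outcome_trial - 1L
  list(odd = rows[idx %% 2L == 1L, , drop = FALSE],
       even = rows[idx %% 2L == 0L, , drop = FALSE])
}
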