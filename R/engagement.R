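#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Standardize to Z-scores
#'
#' Centers and scales to sample mean 0 and sample SD 1 (n - 1 denominator).
#'
#' @param x Numeric vector with at least 2 distinct finite values.
#' @return The standardized vector.
#' @examples
#' zscore(c(1, 2, 3))
#' @export
zscore <- function(x) {
  if (!is.numeric(x) || length(x) < 2L || any(!is.finite(x))) {
    abort_bad_arg("x", "must be a finite numeric vector of length >= 2")
  }
  s <- sd(x)
  if (s == 0) abort_bad_arg("x", "is constant; Z-scores are undefined")
  (x - mean(x)) / s
}

#' Deviance-based task-engagement score for one subject
#'
#' Measures a subject's overall responsiveness to trial events without
#' assuming a model-based or model-free form: the deviance of an
#' intercept-only stay/switch logistic regression minus the deviance of the
#' full 2 x 2 factorial model (intercept, `trans`, `rew`, `rewXtrans`), both
#' fit to the same rows. This difference is the likelihood-ratio statistic
#' comparing the two models (3 df), so unresponsive subjects score around 3
#' and strongly event-driven subjects score much higher. To keep the score a
#' likelihood-ratio statistic the full model is fit unpenalized where its
#' optimum is finite; under separation it falls back to a small ridge
#' penalty (reporting the unpenalized deviance at that optimum) and records
#' the fallback in `method`.
#'
#' @param rows Encoded design rows for one subject (at least `min_rows`).
#' @param ridge_fallback Ridge weight used only when the unpenalized fit
#'   fails to converge or diverges. Default `1e-4`.
#' @param min_rows Minimum rows required. Default 8.
#'
#' @return A one-row tibble with `score`, `method` (`"unpenalized"` or
#'   `"penalized"`) and `converged`.
#' @export
engagement_score <- function(rows, ridge_fallback = 1e-4, min_rows = 8L) {
  if (nrow(rows) < min_rows) {
    stop(sprintf("need at least %d rows to score a subject", min_rows),
         call. = FALSE)
  }
  full <- fit_subject_logistic(rows, ridge = 0)
  method <- "unpenalized"
  if (!full$converged || max(abs(full$coefs)) > 15) {
    full <- fit_subject_logistic(rows, ridge = ridge_fallback)
    method <- "penalized"
  }
  null <- fit_subject_logistic(rows, ridge = 0, terms = character(0))
  tibble::tibble(
    score = null$deviance - full$deviance,
    method = method,
    converged = full$converged && null$converged
  )
}

#' Engagement scores, ranks and subgroup membership for a cohort
#'
#' Applies [engagement_score()] to every subject's rows (intended to be the
#' odd-trial subset from [split_odd_even()]), ranks subjects by score
#' (descending; ties broken by subject-id order), flags the top fraction,
#' and standardizes the scores across the included subjects.
#'
#' @param rows Encoded design rows for the whole cohort.
#' @param fraction Top fraction to flag (0 < fraction <= 1). The subgroup
#'   size is `ceiling(fraction * N)`. Default 0.2.
#' @param min_rows Subjects with fewer rows are excluded with a warning.
#' @param ridge_fallback Passed to [engagement_score()].
#'
#' @return A tibble of class `engagement_table`: `subject_id`, `score`,
#'   `n_rows`, `method`, `rank`, `in_top_fraction`, `engagement_z`.
#' @export
engagement_table <- function(rows, fraction = 0.2, min_rows = 8L,
                             ridge_fallback = 1e-4) {
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction > 1) {
    abort_bad_arg("fraction", "must lie in (0, 1]")
  }
  if (nrow(rows) == 0L) stop("no rows to score", call. = FALSE)
  counts <- dplyr::count(rows, .data$subject_id)
  short <- counts$subject_id[counts$n < min_rows]
  if (length(short)) {
    warning(sprintf("excluding %d subject(s) with fewer than %d rows: %s",
                    length(short), min_rows,
                    paste(short, collapse = ", ")), call. = FALSE)
    rows <- rows[!rows$subject_id %in% short, , drop = FALSE]
  }
  if (nrow(rows) == 0L) stop("no subjects with enough rows", call. = FALSE)
  out <- rows |>
    dplyr::group_by(subject_id = .data$subject_id) |>
    dplyr::group_modify(function(d, key) {
      sc <- engagement_score(d, ridge_fallback = ridge_fallback,
                             min_rows = min_rows)
      sc$n_rows <- nrow(d)
      sc
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subject_id)
  ord <- order(-out$score, out$subject_id)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  k <- as.integer(ceiling(fraction * nrow(out)))
  out$in_top_fraction <- out$rank <= k
  out$engagement_z <- zscore(out$score)
  out <- out[, c("subject_id", "score", "n_rows", "method", "rank",
                 "in_top_fraction", "engagement_z")]
  class(out) <- c("engagement_table", class(out))
  attr(out, "fraction") <- fraction
  out
}

#' Select the top-scoring fraction of subjects
#'
#' @param table An [engagement_table()].
#' @param fraction Top fraction to select; defaults to the fraction the
#'   table was built with. The selection size is `ceiling(fraction * N)`;
#'   ties are broken by subject-id order.
#' @return Character vector of selected subject ids (highest score first).
#' @export
select_top_fraction <- function(table, fraction = NULL) {
  if (!nrow(table)) stop("empty engagement table", call. = FALSE)
  fraction <- fraction %||% attr(table, "fraction") %||% 0.2
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction > 1) {
    abort_bad_arg("fraction", "must lie in (0, 1]")
  }
  k <- as.integer(ceiling(fraction * nrow(table)))
  ord <- order(-table$score, table$subject_id)
  table$subject_id[ord][seq_len(k)]
}
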