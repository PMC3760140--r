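#' Stay-probability summary by previous reward and transition
#'
#' Computes the Figure-style 2 x 2 summary of stay behaviour: for each
#' subject, the frequency of repeating the previous first-stage choice in
#' each cell of (previous trial rewarded yes/no, previous transition
#' common/rare); cells are then averaged across subjects (subject means
#' first, then the grand mean). A model-free learner separates the cells by
#' reward only; a model-based learner shows the crossover in which
#' rewarded-common and unrewarded-rare trials have the highest stay rates.
#'
#' @param trials A trial-record tibble, or already-encoded design rows.
#' @return A tibble with `rewarded` (logical), `transition`
#'   (`"common"`/`"rare"`), `stay_prob` (grand mean of subject means), `se`
#'   (between-subject standard error) and `n_subjects`. Cells with no data
#'   appear with `NA` mean.
#' @export
stay_probability_summary <- function(trials) {
  rows <- if (all(c("stay", "rew", "trans") %in% names(trials))) {
    trials
  } else {
    encode_trials(trials)
  }
  if (!nrow(rows)) stop("no encoded trial pairs to summarize", call. = FALSE)
  cells <- tidyr::expand_grid(rewarded = c(TRUE, FALSE),
                              transition = c("common", "rare"))
  per_subject <- rows |>
    dplyr::group_by(.data$subject_id,
                    rewarded = .data$rew == 1,
                    transition = ifelse(.data$trans == 1, "common", "rare")) |>
    dplyr::summarise(stay_prob = mean(.data$stay), .groups = "drop")
  out <- per_subject |>
    dplyr::group_by(.data$rewarded, .data$transition) |>
    dplyr::summarise(
      se = sd(.data$stay_prob) / sqrt(dplyr::n()),
      stay_prob = mean(.data$stay_prob),
      n_subjects = dplyr::n(),
      .groups = "drop"
    )
  dplyr::left_join(cells, out, by = c("rewarded", "transition")) |>
    dplyr::select("rewarded", "transition", "stay_prob", "se", "n_subjects")
}

#' Configuration of the end-to-end synthetic-study analysis
#'
#' Bundles everything [run_analysis()] needs: the cohort generator, the task
#' configuration, the engagement subgroup fraction, the odd/even
#' cross-fitting conventions, the estimation engine and the seed. The
#' configuration enforces the cross-fitting integrity rule structurally:
#' the trial-parity subset that defines the engagement score must differ
#' from the subset on which engagement effects are tested, so a
#' configuration with `engage_parity == test_parity` is rejected outright.
#'
#' @param cohort A [population_spec()] (agents playing the task) or a
#'   [regression_gen_spec()] (direct generative model of the regression).
#' @param task A [task_config()] used when `cohort` is a population spec.
#' @param top_fraction Engagement subgroup fraction. Default 0.2.
#' @param engage_parity,test_parity `"odd"`/`"even"`: which parity subset
#'   defines engagement and which is used to test its effects. Must differ.
#' @param parity_on Passed to [split_odd_even()]: `"outcome"` or
#'   `"previous"`.
#' @param engine Estimation engine for [fit_multilevel()].
#' @param include_subsample_model Also fit the subsample-moderation variant
#'   (only meaningful for population cohorts with 2 subsamples).
#' @param seed Integer seed driving every random stage.
#'
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(cohort = population_spec(),
                            task = task_config(),
                            top_fraction = 0.2,
                            engage_parity = c("odd", "even"),
                            test_parity = c("even", "odd"),
                            parity_on = c("outcome", "previous"),
                            engine = c("glmmTMB", "lme4"),
                            include_subsample_model = FALSE,
                            seed = 1L) {
  engage_parity <- match.arg(engage_parity)
  test_parity <- match.arg(test_parity)
  parity_on <- match.arg(parity_on)
  engine <- match.arg(engine)
  if (!inherits(cohort, "population_spec") &&
      !inherits(cohort, "regression_gen_spec")) {
    abort_bad_arg("cohort", "must be a population_spec or regression_gen_spec")
  }
  if (engage_parity == test_parity) {
    stop(paste0(
      "cross-fitting violation: engagement would be defined and tested on ",
      "the same (", engage_parity, ") trials; `engage_parity` and ",
      "`test_parity` must differ"), call. = FALSE)
  }
  if (!is_scalar_number(seed)) abort_bad_arg("seed", "must be a single number")
  structure(
    list(cohort = cohort, task = task, top_fraction = top_fraction,
         engage_parity = engage_parity, test_parity = test_parity,
         parity_on = parity_on, engine = engine,
         include_subsample_model = include_subsample_model,
         seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Run the full synthetic-study analysis pipeline
#'
#' Executes the complete trial-by-trial analysis on a freshly generated
#' synthetic cohort: simulate (or generate) the data, encode stay/switch
#' design rows, split by trial parity, compute engagement scores on the
#' engagement subset, then fit the three multilevel models — (a) the
#' extraversion-moderation model on all rows, (b) the same model on the
#' test-parity rows of the top-engagement subgroup, and (c) the
#' engagement-interaction model on the test-parity rows of everyone —
#' followed by the Wald contrast comparing the engagement moderation of the
#' model-free (reward-by-extraversion) and model-based
#' (reward-by-transition-by-extraversion) effects in model (c).
#'
#' @param config An [analysis_config()].
#' @return An object of class `twostep_report`: list with `stay_table`,
#'   `engagement`, `covariates`, `fits` (named `overall`, `top`,
#'   `engagement`, optionally `subsample`), `contrast`, `top_subjects`,
#'   `rows_used` (row counts per stage), `config` and `seed`.
#' @examples
#' \donttest{
#' cfg <- analysis_config(
#'   cohort = regression_gen_spec(n_subjects = 24, n_trials = 80), seed = 2)
#' rep <- run_analysis(cfg)
#' rep$contrast
#' }
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (config$engage_parity == config$test_parity) {
    stop("cross-fitting violation: engagement-defining rows would overlap ",
         "testing rows", call. = FALSE)
  }
  set.seed(config$seed)

  if (inherits(config$cohort, "population_spec")) {
    cohort <- simulate_population(config$cohort, config$task)
    trials <- cohort$trials
    rows <- encode_trials(trials)
    covariates <- cohort$covariates
    stay_table <- stay_probability_summary(rows)
  } else {
    rows <- simulate_from_regression(config$cohort)
    trials <- NULL
    ids <- unique(rows$subject_id)
    covariates <- tibble::tibble(subject_id = ids)
    covariates$extra <- if ("extra" %in% names(rows)) {
      rows$extra[match(ids, rows$subject_id)]
    } else {
      zscore(rnorm(length(ids)))
    }
    stay_table <- stay_probability_summary(rows)
  }

  split <- split_odd_even(rows, on = config$parity_on)
  engage_rows <- split[[config$engage_parity]]
  test_rows <- split[[config$test_parity]]
  stopifnot(nrow(dplyr::inner_join(
    engage_rows[c("subject_id", "outcome_trial")],
    test_rows[c("subject_id", "outcome_trial")],
    by = c("subject_id", "outcome_trial"))) == 0L)

  engagement <- engagement_table(engage_rows, fraction = config$top_fraction)
  top_ids <- select_top_fraction(engagement)
  covariates <- dplyr::left_join(
    covariates,
    dplyr::select(tibble::as_tibble(engagement), "subject_id",
                  engage = "engagement_z"),
    by = "subject_id"
  )

  fits <- list(
    overall = fit_multilevel(rows, covariates, moderators = "extra",
                             engine = config$engine),
    top = fit_multilevel(
      dplyr::filter(test_rows, .data$subject_id %in% top_ids),
      covariates, moderators = "extra", engine = config$engine),
    engagement = fit_multilevel(test_rows, covariates,
                                moderators = c("extra", "engage"),
                                engine = config$engine)
  )
  if (isTRUE(config$include_subsample_model) &&
      "subsample" %in% names(covariates) &&
      length(unique(covariates$subsample)) > 1L) {
    covariates$subsample_dev <- ifelse(covariates$subsample == 1L, -1, 1)
    fits$subsample <- fit_multilevel(rows, covariates,
                                     moderators = "subsample_dev",
                                     engine = config$engine)
  }

  contrast <- wald_contrast(
    fits$engagement,
    c("rew:extra:engage" = 1, "trans:rew:extra:engage" = -1)
  )

  structure(
    list(
      stay_table = stay_table,
      engagement = engagement,
      covariates = covariates,
      fits = fits,
      contrast = contrast,
      top_subjects = top_ids,
      rows_used = c(all = nrow(rows), engage = nrow(engage_rows),
                    test = nrow(test_rows)),
      trials = trials,
      config = config,
      seed = config$seed
    ),
    class = "twostep_report"
  )
}

#' @export
print.twostep_report <- function(x, ...) {
  cat("<twostep_report>\n")
  cat(sprintf("  seed %d; rows: %d total, %d engagement-defining, %d testing\n",
              x$seed, x$rows_used["all"], x$rows_used["engage"],
              x$rows_used["test"]))
  cat(sprintf("  top-%d%% subgroup: %d subjects\n",
              round(100 * x$config$top_fraction), length(x$top_subjects)))
  cat("\nStay probabilities (subject means):\n")
  print(as.data.frame(x$stay_table), row.names = FALSE, digits = 3)
  key <- dplyr::filter(x$fits$overall$fixed,
                       .data$term %in% c("rew", "trans:rew"))
  cat("\nOverall model, learning effects:\n")
  print(as.data.frame(key), row.names = FALSE, digits = 3)
  cat(sprintf("\nModel-free vs model-based engagement-moderation contrast: chi^2(1) = %.2f, p = %.3g\n",
              x$contrast$chi_square, x$contrast$p))
  invisible(x)
}
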