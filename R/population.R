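#' Specification of a simulated study cohort of hybrid agents
#'
#' Describes a population of hybrid agents emulating a two-subsample study
#' cohort. Per-subject parameters are drawn from population distributions on
#' scales that respect their legal ranges: `w`, `alpha` and `lam` are
#' logit-normal (location at the logit of the stated mean, spread on the
#' logit scale), `beta1` and `beta2` are log-normal, and `persev` is normal.
#' A standardized latent trait drives both the observed questionnaire score
#' (extraversion on the EPQ-R scale: normal, truncated to `[0, trait_max]`,
#' rounded) and, through `link_w` and `link_beta1`, systematic strategy
#' differences: `link_w` shifts `logit(w)` and `link_beta1` shifts
#' `log(beta1)` by the stated amount per trait SD.
#'
#' @param subsample_sizes Integer vector of subjects per subsample.
#'   Default `c(48, 49)` (97 subjects total).
#' @param subsample_trials Trials per session for each subsample.
#'   Default `c(350, 300)`.
#' @param w_mean,w_sd Population mean of `w` (probability scale) and SD of
#'   `logit(w)`. `w_mean` 0 or 1 pins `w` (requires `w_sd = 0`, `link_w = 0`).
#' @param alpha_mean,alpha_sd Mean of `alpha` and SD of `logit(alpha)`.
#' @param lam_mean,lam_sd Mean of `lam` and SD of `logit(lam)`.
#' @param beta1_mean,beta1_sd Mean of `beta1` and SD of `log(beta1)`.
#' @param beta2_mean,beta2_sd Mean of `beta2` and SD of `log(beta2)`.
#' @param persev_mean,persev_sd Normal mean/SD of the perseveration bonus.
#' @param link_w,link_beta1 Linear effect of the standardized latent trait
#'   on `logit(w)` and `log(beta1)`.
#' @param trait_mean,trait_sd,trait_max Raw questionnaire scale of the
#'   trait; scores are truncated to `[0, trait_max]` and rounded.
#' @param miss_rate Proportion of trials masked as missed. Default 0.014.
#'
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(subsample_sizes = c(48L, 49L),
                            subsample_trials = c(350L, 300L),
                            w_mean = 0.5, w_sd = 1,
                            alpha_mean = 0.4, alpha_sd = 0.5,
                            lam_mean = 0.6, lam_sd = 0.5,
                            beta1_mean = 4, beta1_sd = 0.5,
                            beta2_mean = 4, beta2_sd = 0.5,
                            persev_mean = 0.1, persev_sd = 0.1,
                            link_w = 0, link_beta1 = -0.3,
                            trait_mean = 16, trait_sd = 5, trait_max = 23,
                            miss_rate = 0.014) {
  if (length(subsample_sizes) != length(subsample_trials) ||
      any(subsample_sizes < 1) || any(subsample_trials < 2)) {
    abort_bad_arg("subsample_sizes/subsample_trials",
                  "must be parallel vectors of positive sizes and trial counts >= 2")
  }
  if (w_mean %in% c(0, 1) && (w_sd != 0 || link_w != 0)) {
    abort_bad_arg("w_mean", "of 0 or 1 requires w_sd = 0 and link_w = 0")
  }
  for (nm in c("w_mean", "alpha_mean", "lam_mean")) {
    v <- get(nm)
    if (v < 0 || v > 1) abort_bad_arg(nm, "must lie in [0, 1]")
  }
  if (alpha_mean == 0) abort_bad_arg("alpha_mean", "must be > 0")
  if (beta1_mean <= 0 || beta2_mean <= 0) {
    abort_bad_arg("beta1_mean/beta2_mean", "must be > 0")
  }
  if (miss_rate < 0 || miss_rate >= 1) abort_bad_arg("miss_rate", "must lie in [0, 1)")
  structure(
    list(
      subsample_sizes = as.integer(subsample_sizes),
      subsample_trials = as.integer(subsample_trials),
      w_mean = w_mean, w_sd = w_sd,
      alpha_mean = alpha_mean, alpha_sd = alpha_sd,
      lam_mean = lam_mean, lam_sd = lam_sd,
      beta1_mean = beta1_mean, beta1_sd = beta1_sd,
      beta2_mean = beta2_mean, beta2_sd = beta2_sd,
      persev_mean = persev_mean, persev_sd = persev_sd,
      link_w = link_w, link_beta1 = link_beta1,
      trait_mean = trait_mean, trait_sd = trait_sd, trait_max = trait_max,
      miss_rate = miss_rate
    ),
    class = "population_spec"
  )
}

# Draw on a transformed scale; a zero SD and link pins the parameter at its mean.
draw_logit_normal <- function(n, mean, sd_logit, shift = 0) {
  if (mean %in% c(0, 1)) return(rep(mean, n))
  plogis(qlogis(mean) + shift + rnorm(n, 0, sd_logit))
}

draw_log_normal <- function(n, mean, sd_log, shift = 0) {
  exp(log(mean) + shift + rnorm(n, 0, sd_log))
}

#' Simulate a full cohort of hybrid agents playing the task
#'
#' Draws per-subject agent parameters and a linked covariate from a
#' [population_spec()], simulates one session per subject (independent
#' reward walks per subject), and returns the trial table, the subject
#' covariate table and the ground-truth generating parameters.
#'
#' @param spec A [population_spec()].
#' @param config A [task_config()]; `n_trials` is overridden per subsample.
#' @param seed Optional integer seed.
#'
#' @return A list of class `twostep_cohort` with tibbles `trials`
#'   (trial records of all subjects), `covariates` (`subject_id`,
#'   `subsample`, `extraversion_raw`, `extra` = z-scored extraversion) and
#'   `params` (per-subject generating parameters including the latent trait).
#' @examples
#' cohort <- simulate_population(
#'   population_spec(subsample_sizes = 4, subsample_trials = 60), seed = 1)
#' cohort$covariates
#' @export
simulate_population <- function(spec = population_spec(),
                                config = task_config(),
                                seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- sum(spec$subsample_sizes)
  subsample <- rep(seq_along(spec$subsample_sizes), spec$subsample_sizes)
  n_trials <- rep(spec$subsample_trials, spec$subsample_sizes)
  ids <- sprintf("s%03d", seq_len(n))

  trait_z <- rnorm(n)
  raw <- round(pmin(pmax(spec$trait_mean + spec$trait_sd * trait_z, 0),
                    spec$trait_max))
  params <- tibble::tibble(
    subject_id = ids,
    subsample = subsample,
    trait_z = trait_z,
    w = draw_logit_normal(n, spec$w_mean, spec$w_sd, spec$link_w * trait_z),
    alpha = draw_logit_normal(n, spec$alpha_mean, spec$alpha_sd),
    lam = draw_logit_normal(n, spec$lam_mean, spec$lam_sd),
    beta1 = draw_log_normal(n, spec$beta1_mean, spec$beta1_sd,
                            spec$link_beta1 * trait_z),
    beta2 = draw_log_normal(n, spec$beta2_mean, spec$beta2_sd),
    persev = rnorm(n, spec$persev_mean, spec$persev_sd)
  )
  # alpha must stay in (0, 1]: the logit-normal draw cannot reach 0 unless
  # alpha_mean is 0, which the spec constructor rejects.

  trials <- purrr::pmap(
    list(seq_len(n), ids, n_trials),
    function(i, id, nt) {
      cfg <- config
      cfg$n_trials <- nt
      pars <- agent_params(
        w = params$w[i], alpha = params$alpha[i], lam = params$lam[i],
        beta1 = params$beta1[i], beta2 = params$beta2[i],
        persev = params$persev[i]
      )
      simulate_session(hybrid_agent(pars, cfg), cfg, subject_id = id,
                       miss_rate = spec$miss_rate)
    }
  )
  trials <- dplyr::bind_rows(trials)

  covariates <- tibble::tibble(
    subject_id = ids,
    subsample = subsample,
    extraversion_raw = raw,
    extra = zscore(raw)
  )
  structure(
    list(trials = trials, covariates = covariates, params = params,
         seed = seed),
    class = "twostep_cohort"
  )
}

#' @export
print.twostep_cohort <- function(x, ...) {
  cat("<twostep_cohort>\n")
  cat(sprintf("  %d subjects, %d trial rows (%.1f%% missed)\n",
              nrow(x$covariates), nrow(x$trials), 100 * mean(x$trials$missed)))
  invisible(x)
}

#' Generative specification matching the stay/switch regression
#'
#' Describes data generated directly from the factorial multilevel logistic
#' model used for analysis: per subject a random-effect vector on
#' (intercept, trans, rew, trans:rew) is drawn from a zero-mean multivariate
#' normal; per trial the previous-trial predictors are drawn independently
#' (`rew = +1` with probability `p_reward_marginal`, `trans = +1` with
#' probability `p_common`) and the stay outcome follows a logistic model in
#' the four within-subject terms, optionally interacted with standardized
#' between-subject covariates.
#'
#' @param fixed Named numeric vector of the four within-subject fixed
#'   effects `intercept`, `trans`, `rew`, `trans_rew` (log-odds).
#' @param re_sd Random-effect SDs for the four terms. Default `rep(0.3, 4)`.
#' @param re_cor 4 x 4 random-effect correlation matrix. Default identity.
#' @param n_subjects,n_trials Cohort dimensions. Defaults 97 and 300.
#' @param p_reward_marginal Marginal probability that the previous trial is
#'   coded rewarded. Default 0.5.
#' @param p_common Marginal probability of a common transition. Default 0.7.
#' @param moderator_coefs Optional named list; each element is a length-4
#'   numeric vector giving the interaction of one standardized covariate
#'   (or product of two, named `"a:b"`) with the four within-subject terms.
#'
#' @return An object of class `regression_gen_spec`.
#' @export
regression_gen_spec <- function(fixed = c(intercept = 1.0, trans = 0,
                                          rew = 0.198, trans_rew = 0.132),
                                re_sd = rep(0.3, 4),
                                re_cor = diag(4),
                                n_subjects = 97L,
                                n_trials = 300L,
                                p_reward_marginal = 0.5,
                                p_common = 0.7,
                                moderator_coefs = NULL) {
  stopifnot(length(fixed) == 4L, length(re_sd) == 4L, all(re_sd >= 0))
  names(fixed) <- c("intercept", "trans", "rew", "trans_rew")
  re_cor <- as.matrix(re_cor)
  if (!isTRUE(all.equal(re_cor, t(re_cor))) ||
      any(eigen(re_cor, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
    abort_bad_arg("re_cor", "must be a symmetric positive semidefinite matrix")
  }
  re_cov <- diag(re_sd) %*% re_cor %*% diag(re_sd)
  if (!is.null(moderator_coefs)) {
    stopifnot(is.list(moderator_coefs), !is.null(names(moderator_coefs)),
              all(vapply(moderator_coefs, length, 1L) == 4L))
  }
  structure(
    list(fixed = fixed, re_sd = re_sd, re_cor = re_cor, re_cov = re_cov,
         n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
         p_reward_marginal = p_reward_marginal, p_common = p_common,
         moderator_coefs = moderator_coefs),
    class = "regression_gen_spec"
  )
}

#' Simulate an encoded stay/switch dataset from the regression model
#'
#' Direct generative counterpart of [fit_multilevel()]: draws per-subject
#' random effects, per-trial `rew`/`trans` codes, and Bernoulli stay
#' outcomes from the logistic model described by the spec. Useful for
#' self-consistency (parameter-recovery) studies of the inference pipeline.
#'
#' @param spec A [regression_gen_spec()].
#' @param covariates Optional tibble with `subject_id` and one standardized
#'   column per moderator named in `spec$moderator_coefs`; when `NULL` and
#'   moderators are present, standard-normal covariates are drawn.
#' @param seed Optional integer seed.
#'
#' @return A tibble of encoded rows (`subject_id`, `outcome_trial`, `stay`,
#'   `rew`, `trans`, `rewXtrans`, moderator columns) with the generating
#'   random effects in attribute `"random_effects"` and the spec in
#'   attribute `"truth"`.
#' @export
simulate_from_regression <- function(spec = regression_gen_spec(),
                                     covariates = NULL, seed = NULL) {
  stopifnot(inherits(spec, "regression_gen_spec"))
  if (!is.null(seed)) set.seed(seed)
  n_sub <- spec$n_subjects
  n_row <- spec$n_trials - 1L
  ids <- sprintf("s%03d", seq_len(n_sub))

  mod_names <- unique(unlist(strsplit(names(spec$moderator_coefs) %||% character(0), ":")))
  if (length(mod_names)) {
    if (is.null(covariates)) {
      covariates <- tibble::as_tibble(
        c(list(subject_id = ids),
          setNames(lapply(mod_names, function(.) zscore(rnorm(n_sub))), mod_names))
      )
    }
    stopifnot(all(c("subject_id", mod_names) %in% names(covariates)),
              nrow(covariates) == n_sub)
    covariates <- covariates[match(ids, covariates$subject_id), ]
  }

  # matrix square root via eigendecomposition so that singular (including
  # zero) random-effect covariances are legal generating configurations
  ev <- eigen(spec$re_cov, symmetric = TRUE)
  sqrt_cov <- diag(sqrt(pmax(ev$values, 0)), 4L) %*% t(ev$vectors)
  b <- matrix(rnorm(n_sub * 4L), n_sub, 4L) %*% sqrt_cov
  colnames(b) <- c("intercept", "trans", "rew", "trans_rew")

  sub_idx <- rep(seq_len(n_sub), each = n_row)
  rew <- ifelse(runif(n_sub * n_row) < spec$p_reward_marginal, 1, -1)
  trans <- ifelse(runif(n_sub * n_row) < spec$p_common, 1, -1)
  rxt <- rew * trans

  eta <- (spec$fixed["intercept"] + b[sub_idx, "intercept"]) +
    (spec$fixed["trans"] + b[sub_idx, "trans"]) * trans +
    (spec$fixed["rew"] + b[sub_idx, "rew"]) * rew +
    (spec$fixed["trans_rew"] + b[sub_idx, "trans_rew"]) * rxt

  if (length(spec$moderator_coefs)) {
    for (nm in names(spec$moderator_coefs)) {
      parts <- strsplit(nm, ":")[[1]]
      zval <- Reduce(`*`, lapply(parts, function(p) covariates[[p]]))[sub_idx]
      co <- spec$moderator_coefs[[nm]]
      eta <- eta + zval * (co[1] + co[2] * trans + co[3] * rew + co[4] * rxt)
    }
  }

  stay <- rbinom(length(eta), 1L, plogis(eta))
  out <- tibble::tibble(
    subject_id = ids[sub_idx],
    outcome_trial = rep(seq_len(n_row) + 1L, times = n_sub),
    stay = stay, rew = rew, trans = trans, rewXtrans = rxt
  )
  if (length(mod_names)) {
    out <- dplyr::left_join(out, covariates[, c("subject_id", mod_names)],
                            by = "subject_id")
  }
  attr(out, "random_effects") <- tibble::as_tibble(
    cbind(tibble::tibble(subject_id = ids), as.data.frame(b))
  )
  attr(out, "truth") <- spec
  out
}
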