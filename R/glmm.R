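#' Multilevel (random-slopes) logistic stay/switch regression
#'
#' Fits the factorial multilevel logistic regression of stay behaviour:
#' fixed effects for `trans`, `rew` and their interaction (optionally in a
#' full factorial with up to two standardized between-subject moderators),
#' with all four within-subject terms also instantiated as correlated
#' per-subject random effects. For a single moderator `extra` the model is
#'
#'   `stay ~ trans * rew * extra + (1 + trans * rew | subject_id)`
#'
#' estimated by maximizing the Laplace-approximated marginal likelihood.
#' Two interchangeable engines are provided: `"glmmTMB"` (default) and
#' `"lme4"` (`glmer`); both use the Laplace approximation and agree closely,
#' the former being substantially faster at cohort scale.
#'
#' @param rows Encoded design rows ([encode_trials()] or
#'   [simulate_from_regression()]) with columns `stay`, `trans`, `rew`,
#'   `subject_id`.
#' @param covariates Optional tibble keyed by `subject_id` supplying the
#'   moderator columns; not needed when the moderators are already columns
#'   of `rows`.
#' @param moderators Character vector (0-2 names) of standardized
#'   between-subject covariates to interact factorially with the
#'   within-subject terms.
#' @param engine `"glmmTMB"` or `"lme4"`.
#'
#' @return An object of class `twostep_glmm`: list with `fixed` (tibble of
#'   term, estimate, se, z, p), `vcov_fixed`, `re_cov` (estimated 4 x 4
#'   random-effect covariance), `deviance` (-2 log-likelihood of the
#'   Laplace-approximated marginal likelihood), `converged`, `engine`,
#'   `formula`, `n_obs`, `n_subjects` and the underlying `fit` object.
#' @examples
#' \donttest{
#' rows <- simulate_from_regression(
#'   regression_gen_spec(n_subjects = 20, n_trials = 80), seed = 1)
#' fit <- fit_multilevel(rows)
#' tidy(fit)
#' }
#' @export
fit_multilevel <- function(rows, covariates = NULL, moderators = character(),
                           engine = c("glmmTMB", "lme4")) {
  engine <- match.arg(engine)
  stopifnot(length(moderators) <= 2L)
  need <- c("subject_id", "stay", "trans", "rew")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols)) {
    stop("`rows` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- as.data.frame(rows)
  if (!is.null(covariates)) {
    keep <- setdiff(intersect(names(covariates), c("subject_id", moderators)),
                    names(dat))
    dat <- merge(dat, as.data.frame(covariates)[, c("subject_id", keep),
                                                drop = FALSE],
                 by = "subject_id", sort = FALSE)
  }
  for (m in moderators) {
    if (!m %in% names(dat)) {
      stop(sprintf("moderator `%s` not found in `rows` or `covariates`", m),
           call. = FALSE)
    }
    if (!is.numeric(dat[[m]]) || any(!is.finite(dat[[m]])) ||
        sd(dat[[m]]) == 0) {
      stop(sprintf("moderator `%s` must be numeric, finite and non-constant", m),
           call. = FALSE)
    }
  }
  dat$subject_id <- factor(dat$subject_id)

  fe <- paste(c("trans", "rew", moderators), collapse = " * ")
  fml <- stats::as.formula(
    paste0("stay ~ ", fe, " + (1 + trans * rew | subject_id)"))

  if (engine == "glmmTMB") {
    fit <- glmmTMB::glmmTMB(fml, data = dat, family = stats::binomial())
    beta <- glmmTMB::fixef(fit)$cond
    V <- as.matrix(stats::vcov(fit)$cond)
    vc <- glmmTMB::VarCorr(fit)$cond$subject_id
    re_cov <- matrix(as.numeric(vc), nrow(vc), ncol(vc),
                     dimnames = list(rownames(vc), colnames(vc)))
    converged <- isTRUE(fit$sdr$pdHess) &&
      isTRUE(fit$fit$convergence == 0)
  } else {
    fit <- lme4::glmer(fml, data = dat, family = stats::binomial())
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    vc <- lme4::VarCorr(fit)$subject_id
    re_cov <- matrix(as.numeric(vc), nrow(vc), ncol(vc),
                     dimnames = list(rownames(vc), colnames(vc)))
    converged <- length(fit@optinfo$conv$lme4) == 0
  }
  se <- sqrt(diag(V))
  z <- beta / se
  fixed <- tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    se = unname(se),
    z = unname(z),
    p = 2 * pnorm(-abs(unname(z)))
  )
  structure(
    list(
      fixed = fixed,
      vcov_fixed = V,
      re_cov = re_cov,
      deviance = -2 * as.numeric(stats::logLik(fit)),
      loglik = as.numeric(stats::logLik(fit)),
      converged = converged,
      engine = engine,
      formula = fml,
      n_obs = nrow(dat),
      n_subjects = nlevels(dat$subject_id),
      fit = fit
    ),
    class = "twostep_glmm"
  )
}

#' @export
print.twostep_glmm <- function(x, ...) {
  cat("<twostep_glmm> ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  engine=%s  n=%d obs, %d subjects  deviance=%.2f  converged=%s\n",
              x$engine, x$n_obs, x$n_subjects, x$deviance, x$converged))
  fx <- x$fixed
  fx$estimate <- round(fx$estimate, 4)
  fx$se <- round(fx$se, 4)
  fx$z <- round(fx$z, 2)
  fx$p <- signif(fx$p, 3)
  print(as.data.frame(fx), row.names = FALSE)
  invisible(x)
}

#' Tidy the fixed effects of a multilevel stay/switch fit
#'
#' @param x A `twostep_glmm` object.
#' @param effects `"fixed"` (default) for the coefficient table or
#'   `"ran_pars"` for the random-effect SDs and correlations.
#' @param ... Unused.
#' @return A tibble in broom convention (`term`, `estimate`, `std.error`,
#'   `statistic`, `p.value` for fixed effects).
#' @exportS3Method generics::tidy
tidy.twostep_glmm <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    return(tibble::tibble(
      term = x$fixed$term,
      estimate = x$fixed$estimate,
      std.error = x$fixed$se,
      statistic = x$fixed$z,
      p.value = x$fixed$p
    ))
  }
  sds <- sqrt(diag(x$re_cov))
  cors <- stats::cov2cor(x$re_cov)
  nm <- rownames(x$re_cov)
  out <- tibble::tibble(term = paste0("sd__", nm), estimate = sds)
  pairs <- which(upper.tri(cors), arr.ind = TRUE)
  if (nrow(pairs)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("cor__", nm[pairs[, 1]], ".", nm[pairs[, 2]]),
      estimate = cors[pairs]
    ))
  }
  out
}

#' @rdname tidy.twostep_glmm
#' @exportS3Method generics::glance
glance.twostep_glmm <- function(x, ...) {
  tibble::tibble(
    deviance = x$deviance, logLik = x$loglik, nobs = x$n_obs,
    n_subjects = x$n_subjects, converged = x$converged, engine = x$engine
  )
}

#' Wald test of a linear contrast of fixed effects
#'
#' Computes `c'beta`, its standard error from the estimated fixed-effect
#' covariance, and the 1-df chi-square statistic `(c'beta)^2 / (c'Vc)`.
#' Used, e.g., to compare the engagement moderation of the
#' extraversion-by-reward effect (model-free) against that of the
#' extraversion-by-reward-by-transition effect (model-based).
#'
#' @param fit A `twostep_glmm` object.
#' @param contrast Either a numeric vector with one weight per fixed-effect
#'   term (in `fit$fixed$term` order) or a named numeric vector of weights
#'   for a subset of terms (others implicitly zero).
#'
#' @return A one-row tibble with `estimate`, `se`, `chi_square`, `df`, `p`.
#' @export
wald_contrast <- function(fit, contrast) {
  stopifnot(inherits(fit, "twostep_glmm"))
  terms <- fit$fixed$term
  if (!is.null(names(contrast)) && any(nzchar(names(contrast)))) {
    unknown <- setdiff(names(contrast), terms)
    if (length(unknown)) {
      stop("unknown term(s) in contrast: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cv <- setNames(rep(0, length(terms)), terms)
    cv[names(contrast)] <- contrast
  } else {
    if (length(contrast) != length(terms)) {
      stop("unnamed contrast must have one weight per fixed-effect term",
           call. = FALSE)
    }
    cv <- as.numeric(contrast)
  }
  est <- sum(cv * fit$fixed$estimate)
  v <- drop(t(cv) %*% fit$vcov_fixed %*% cv)
  if (v <= 0) stop("contrast has zero variance", call. = FALSE)
  chi <- est^2 / v
  tibble::tibble(
    estimate = est, se = sqrt(v), chi_square = chi, df = 1L,
    p = pchisq(chi, df = 1, lower.tail = FALSE)
  )
}
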