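#' Per-subject factorial logistic regression
#'
#' Fits the 2 x 2 factorial stay/switch logistic regression (intercept,
#' `trans`, `rew`, `rewXtrans`) to one subject's encoded rows by Newton
#' iteration on the penalized Bernoulli log-likelihood. An optional L2
#' (ridge) penalty on the non-intercept coefficients keeps the optimum
#' finite under separation; the reported deviance is always the
#' *unpenalized* -2 log-likelihood evaluated at the optimum, so nested-fit
#' deviance differences remain likelihood-ratio statistics.
#'
#' @param rows Encoded design rows for a single subject (at least 8).
#' @param ridge Non-negative L2 penalty weight on non-intercept terms.
#'   Default `1e-4`; use 0 for an unpenalized fit.
#' @param terms Character vector of predictor columns besides the
#'   intercept; `character(0)` fits the intercept-only model.
#' @param max_iter,tol_loglik,tol_grad Convergence controls: iteration cap,
#'   relative penalized log-likelihood change, and gradient norm.
#'
#' @return An object of class `subject_logit`: list with `coefs` (named),
#'   `deviance` (unpenalized), `loglik`, `converged`, `ridge`, `n`.
#'   Non-convergence is flagged, not an error.
#' @examples
#' rows <- simulate_from_regression(
#'   regression_gen_spec(n_subjects = 1, n_trials = 200), seed = 1)
#' fit_subject_logistic(rows)
#' @export
fit_subject_logistic <- function(rows, ridge = 1e-4,
                                 terms = c("trans", "rew", "rewXtrans"),
                                 max_iter = 100L, tol_loglik = 1e-8,
                                 tol_grad = 1e-5) {
  stopifnot(is.numeric(ridge), ridge >= 0)
  if (nrow(rows) < 8L) {
    stop("need at least 8 rows for a per-subject fit", call. = FALSE)
  }
  missing_cols <- setdiff(c("stay", terms), names(rows))
  if (length(missing_cols)) {
    stop("`rows` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- rows$stay
  stopifnot(all(y %in% c(0L, 1L)))
  X <- cbind(`(Intercept)` = 1, as.matrix(rows[terms]))
  p <- ncol(X)
  pen <- c(0, rep(ridge, p - 1L))

  loglik_at <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - log1p(exp(eta)))
  }
  objective <- function(beta) -loglik_at(beta) + sum(pen * beta^2)

  beta <- rep(0, p)
  obj <- objective(beta)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    grad <- -drop(crossprod(X, y - mu)) + 2 * pen * beta
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + diag(2 * pen, p)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    # step halving on the penalized objective
    s <- 1
    repeat {
      beta_new <- beta - s * step
      obj_new <- objective(beta_new)
      if (is.finite(obj_new) && obj_new <= obj + 1e-12) break
      s <- s / 2
      if (s < 1e-10) break
    }
    rel_change <- abs(obj - obj_new) / (abs(obj) + 1e-10)
    beta <- beta_new
    obj <- obj_new
    if (rel_change < tol_loglik && sqrt(sum(grad^2)) < tol_grad) {
      converged <- TRUE
      break
    }
  }
  ll <- loglik_at(beta)
  structure(
    list(
      coefs = setNames(drop(beta), colnames(X)),
      loglik = ll,
      deviance = -2 * ll,
      converged = converged,
      ridge = ridge,
      n = nrow(rows),
      terms = terms
    ),
    class = "subject_logit"
  )
}

#' @export
print.subject_logit <- function(x, ...) {
  cat(sprintf("<subject_logit> n=%d deviance=%.3f converged=%s ridge=%g\n",
              x$n, x$deviance, x$converged, x$ridge))
  print(round(x$coefs, 4))
  invisible(x)
}

#' @rdname fit_subject_logistic
#' @param x A `subject_logit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.subject_logit <- function(x, ...) {
  tibble::tibble(term = names(x$coefs), estimate = unname(x$coefs))
}

#' @rdname fit_subject_logistic
#' @exportS3Method generics::glance
glance.subject_logit <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, logLik = x$loglik, nobs = x$n,
                 converged = x$converged, ridge = x$ridge)
}
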