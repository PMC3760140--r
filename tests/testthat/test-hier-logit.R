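test_that("per-subject logistic regression matches the glm oracle", {
  spec <- regression_gen_spec(
    fixed = c(intercept = 1.0, trans = 0, rew = 0.5, trans_rew = 0.3),
    re_sd = rep(0, 4), n_subjects = 1, n_trials = 5001)
  rows <- simulate_from_regression(spec, seed = 101)
  fit <- fit_subject_logistic(rows, ridge = 0)
  expect_true(fit$converged)
  # large-sample consistency
  expect_true(all(abs(fit$coefs - c(1.0, 0, 0.5, 0.3)) < 0.1))
  # independent general-purpose fitter agrees
  gfit <- glm(stay ~ trans + rew + rewXtrans, family = binomial(), data = rows)
  expect_equal(unname(fit$coefs), unname(coef(gfit)), tolerance = 1e-6)
  expect_equal(fit$deviance, deviance(gfit), tolerance = 1e-8)
})

test_that("null outcomes give near-zero slopes", {
  rows <- null_rows(1, 5001, seed = 102)
  fit <- fit_subject_logistic(rows, ridge = 0)
  expect_true(all(abs(fit$coefs[-1]) < 0.1))
})

test_that("ridge keeps separated fits finite", {
  rows <- null_rows(1, 101, seed = 103)
  rows$stay <- 1L  # complete separation on the intercept
  fit <- fit_subject_logistic(rows, ridge = 1e-4)
  expect_true(all(is.finite(fit$coefs)))
  expect_true(is.finite(fit$deviance))
  # too-few-rows precondition
  expect_error(fit_subject_logistic(rows[1:5, ]), "at least 8")
})

test_that("full-model deviance never exceeds the intercept-only deviance", {
  rows <- simulate_from_regression(
    regression_gen_spec(n_subjects = 20, n_trials = 61), seed = 104)
  for (id in unique(rows$subject_id)) {
    d <- rows[rows$subject_id == id, ]
    full <- fit_subject_logistic(d, ridge = 0)
    null <- fit_subject_logistic(d, ridge = 0, terms = character(0))
    expect_lte(full$deviance, null$deviance + 1e-8)
  }
})

test_that("zero random-effect variance reduces the GLMM to the pooled fit", {
  rows <- simulate_from_regression(
    regression_gen_spec(re_sd = rep(0, 4), n_subjects = 30, n_trials = 101),
    seed = 105)
  pooled <- glm(stay ~ trans * rew, family = binomial(), data = rows)
  # in the zero-variance limit the Laplace marginal likelihood collapses to
  # the pooled likelihood exactly
  expect_true(all(abs(glmmtmb_pooled_limit(rows) - unname(coef(pooled))) < 1e-3))
  # and the free fit stays close, with small estimated heterogeneity
  fit <- suppressWarnings(fit_multilevel(rows))
  expect_true(all(abs(fit$fixed$estimate - unname(coef(pooled))) < 0.05))
  expect_true(all(sqrt(diag(fit$re_cov)) < 0.25))
})

test_that("the Laplace objective matches the adaptive-quadrature oracle", {
  beta <- c(1.0, 0, 0.198, 0.132)
  sds <- rep(0.15, 4)
  rows <- simulate_from_regression(
    regression_gen_spec(n_subjects = 2, n_trials = 41, re_sd = sds),
    seed = 106)
  ll_engine <- glmmtmb_laplace_at(rows, beta, sds)
  ll_laplace <- laplace_loglik(rows, beta, diag(sds^2))
  ll_agq <- agq_loglik(rows, beta, diag(sds^2), n_nodes = 11)
  # the engine computes exactly the Laplace approximation ...
  expect_equal(ll_engine, ll_laplace, tolerance = 1e-6)
  # ... and the approximation agrees with 4-dim adaptive Gauss-Hermite
  expect_lt(abs(ll_engine - ll_agq), 1e-2)
})

test_that("the two Laplace engines agree on fixed effects", {
  rows <- simulate_from_regression(
    regression_gen_spec(n_subjects = 25, n_trials = 121), seed = 107)
  f1 <- suppressWarnings(fit_multilevel(rows, engine = "glmmTMB"))
  f2 <- suppressWarnings(suppressMessages(fit_multilevel(rows, engine = "lme4")))
  expect_equal(f1$fixed$term, f2$fixed$term)
  expect_true(all(abs(f1$fixed$estimate - f2$fixed$estimate) < 5e-3))
  expect_true(all(abs(f1$fixed$se - f2$fixed$se) < 5e-3))
})

test_that("Wald machinery is internally consistent", {
  rows <- simulate_from_regression(
    regression_gen_spec(n_subjects = 30, n_trials = 101), seed = 108)
  fit <- fit_multilevel(rows)
  # p-values follow the two-sided normal reference
  expect_equal(fit$fixed$p, 2 * pnorm(-abs(fit$fixed$z)))
  # a single-term contrast reproduces Z^2
  ct <- wald_contrast(fit, c(rew = 1))
  z_rew <- fit$fixed$z[fit$fixed$term == "rew"]
  expect_equal(ct$chi_square, z_rew^2, tolerance = 1e-10)
  expect_equal(ct$df, 1L)
  # unnamed full-length contrast
  ct2 <- wald_contrast(fit, c(0, 0, 1, 0))
  expect_equal(ct2$estimate, fit$fixed$estimate[3])
  # degenerate contrasts are rejected
  expect_error(wald_contrast(fit, c(rew = 0)), "zero variance")
  expect_error(wald_contrast(fit, c(nope = 1)), "unknown term")
  expect_error(wald_contrast(fit, c(1, 1)), "one weight per")
})

test_that("difference contrasts are calibrated under equal true effects", {
  # equal generating rew and trans:rew coefficients: the difference
  # contrast should reject at about the nominal 5% rate
  rejections <- vapply(1:60, function(s) {
    rows <- simulate_from_regression(
      regression_gen_spec(fixed = c(intercept = 0.5, trans = 0, rew = 0.15,
                                    trans_rew = 0.15),
                          re_sd = rep(0.25, 4), n_subjects = 24, n_trials = 81),
      seed = 200 + s)
    fit <- suppressWarnings(fit_multilevel(rows))
    ct <- wald_contrast(fit, c(rew = 1, `trans:rew` = -1))
    ct$p < 0.05
  }, logical(1))
  expect_lt(mean(rejections), 0.15)
})

test_that("tidy and glance follow broom conventions", {
  rows <- simulate_from_regression(
    regression_gen_spec(n_subjects = 15, n_trials = 61), seed = 109)
  fit <- suppressWarnings(fit_multilevel(rows))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  rp <- tidy(fit, effects = "ran_pars")
  expect_equal(sum(grepl("^sd__", rp$term)), 4L)
  gl <- glance(fit)
  expect_named(gl, c("deviance", "logLik", "nobs", "n_subjects", "converged",
                     "engine"))
  sfit <- fit_subject_logistic(rows[rows$subject_id == "s001", ])
  expect_named(tidy(sfit), c("term", "estimate"))
  expect_equal(glance(sfit)$nobs, 60L)
})
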