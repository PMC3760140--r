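test_that("SARSA(lambda) updates telescope as expected", {
  p_full <- agent_params(alpha = 1, lam = 1)
  fresh <- function() list(q1 = c(0, 0), q2 = matrix(0, 2, 2))
  # alpha = lambda = 1: a terminal reward propagates fully to stage 1
  s <- fresh()
  upd <- mf_update(s$q1, s$q2, choice1 = 0, pair = 0, choice2 = 1, reward = 1,
                   p_full)
  expect_equal(upd$q1[1], 1)
  expect_equal(upd$q2[1, 2], 1)
  # lambda = 0: only the stage-2 value moves on the first trial
  p0 <- agent_params(alpha = 1, lam = 0)
  upd0 <- mf_update(s$q1, s$q2, 0, 0, 1, 1, p0)
  expect_equal(upd0$q1[1], 0)
  expect_equal(upd0$q2[1, 2], 1)
})

test_that("repeated rewarded trials drive stage-1 values to the reward", {
  # fixed-point iteration oracle: the map has q1 = q2 = r as its fixed point
  p <- agent_params(alpha = 0.3, lam = 1)
  q1 <- c(0, 0); q2 <- matrix(0, 2, 2)
  for (i in 1:200) {
    upd <- mf_update(q1, q2, 0, 0, 1, 1, p)
    q1 <- upd$q1; q2 <- upd$q2
  }
  expect_equal(q1[1], 1, tolerance = 1e-6)
  expect_equal(q2[1, 2], 1, tolerance = 1e-6)
})

test_that("model-based values are the transition-weighted best outcomes", {
  cfg <- task_config(p_common = 0.7)
  q2 <- rbind(c(1, 0.2), c(0, 0))     # pair maxima (1, 0)
  expect_equal(mb_values(q2, cfg), c(0.7, 0.3))
  # equal pair maxima give equal stage-1 values
  q2eq <- rbind(c(0.6, 0.1), c(0.2, 0.6))
  expect_equal(mb_values(q2eq, cfg)[1], mb_values(q2eq, cfg)[2])
  # uninformative transitions make stage-1 values identical
  cfg5 <- cfg; cfg5$p_common <- 0.5
  v <- mb_values(rbind(c(0.9, 0.1), c(0.3, 0.2)), cfg5)
  expect_equal(v[1], v[2])
})

test_that("hybrid choice probabilities follow the softmax closed form", {
  expect_equal(
    hybrid_choice_prob(c(0.9, 0.1), c(0.2, 0.8), NA,
                       agent_params(beta1 = 0, persev = 0)),
    0.5)
  # w = 1: model-free values are irrelevant
  p1 <- agent_params(w = 1, beta1 = 3, persev = 0)
  expect_equal(hybrid_choice_prob(c(0.7, 0.3), c(0, 1), NA, p1),
               hybrid_choice_prob(c(0.7, 0.3), c(1, 0), NA, p1))
  # closed form: beta1 * (Q0 - Q1) = 0.8 -> logistic(0.8)
  expect_equal(
    hybrid_choice_prob(c(0.7, 0.3), c(0.7, 0.3), NA,
                       agent_params(w = 0.5, beta1 = 2, persev = 0)),
    1 / (1 + exp(-0.8)))
  # perseveration raises the repeat probability
  pp <- agent_params(beta1 = 2, persev = 1)
  expect_gt(hybrid_choice_prob(c(0.5, 0.5), c(0.5, 0.5), 0, pp), 0.5)
  expect_lt(hybrid_choice_prob(c(0.5, 0.5), c(0.5, 0.5), 1, pp), 0.5)
})

test_that("agent_params validates ranges", {
  expect_error(agent_params(w = 1.2), "w")
  expect_error(agent_params(alpha = 0), "alpha")
  expect_error(agent_params(lam = -0.1), "lam")
  expect_error(agent_params(beta1 = -1), "beta1")
})

test_that("population draws respect parameter ranges and covariate links", {
  spec <- population_spec(subsample_sizes = 200, subsample_trials = 2,
                          link_w = 0.8, link_beta1 = -0.3)
  cohort <- simulate_population(spec, task_config(), seed = 31)
  p <- cohort$params
  expect_true(all(p$w >= 0 & p$w <= 1))
  expect_true(all(p$alpha > 0 & p$alpha <= 1))
  expect_true(all(p$lam >= 0 & p$lam <= 1))
  expect_true(all(p$beta1 > 0 & p$beta2 > 0))
  # links act on the transformed scales
  expect_gt(cor(p$trait_z, qlogis(p$w)), 0.3)
  expect_lt(cor(p$trait_z, log(p$beta1)), -0.2)
  # covariate table matches the questionnaire emulation
  expect_true(all(cohort$covariates$extraversion_raw >= 0 &
                    cohort$covariates$extraversion_raw <= 23))
  expect_equal(mean(cohort$covariates$extra), 0, tolerance = 1e-10)
  expect_equal(sd(cohort$covariates$extra), 1, tolerance = 1e-10)
})

test_that("strategy signatures are monotone in the model-based weight", {
  # pooled logistic fits over small cohorts: the reward-by-transition
  # coefficient grows with w while the reward main effect shrinks
  fit_cohort <- function(w, seed) {
    spec <- population_spec(subsample_sizes = 40, subsample_trials = 150,
                            w_mean = w, w_sd = 0, link_w = 0, link_beta1 = 0,
                            miss_rate = 0)
    cohort <- simulate_population(spec, task_config(), seed = seed)
    rows <- encode_trials(cohort$trials)
    coef(glm(stay ~ trans * rew, family = binomial(), data = rows))
  }
  co <- vapply(c(0, 0.5, 1), fit_cohort, numeric(4), seed = 41)
  expect_true(all(diff(co["trans:rew", ]) > 0))
  expect_true(all(diff(co["rew", ]) < 0))
  expect_gt(co["rew", 1], 0.2)        # pure MF: strong reward effect
  expect_gt(co["trans:rew", 3], 0.2)  # pure MB: strong interaction
})

test_that("the regression generator matches its nominal model", {
  # all coefficients zero: stay frequency 0.5
  rows0 <- null_rows(30, 101, seed = 51)
  expect_equal(mean(rows0$stay), 0.5, tolerance = 0.03 / 0.5)
  # saturated intercept: stay nearly always
  rows6 <- simulate_from_regression(
    regression_gen_spec(fixed = c(intercept = 6, trans = 0, rew = 0,
                                  trans_rew = 0),
                        re_sd = rep(0, 4), n_subjects = 20, n_trials = 101),
    seed = 52)
  expect_gt(mean(rows6$stay), 0.99)
  # marginal predictor frequencies follow the spec
  expect_equal(mean(rows0$trans == 1), 0.7, tolerance = 0.03)
  expect_equal(mean(rows0$rew == 1), 0.5, tolerance = 0.05)
  expect_equal(rows0$rewXtrans, rows0$rew * rows0$trans)
  expect_error(regression_gen_spec(re_cor = matrix(c(1, 2, 2, 1), 2)), "re_cor")
})

test_that("moderated generation links covariates to strategy coefficients", {
  spec <- regression_gen_spec(
    n_subjects = 60, n_trials = 201,
    moderator_coefs = list(extra = c(0, 0, -0.3, 0)))
  rows <- simulate_from_regression(spec, seed = 61)
  expect_true("extra" %in% names(rows))
  fit <- glm(stay ~ trans * rew * extra, family = binomial(), data = rows)
  expect_lt(coef(fit)["rew:extra"], -0.1)
})
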