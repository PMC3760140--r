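test_that("task_config validates its invariants", {
  expect_error(task_config(n_trials = 1), "n_trials")
  expect_error(task_config(p_common = 0.5), "p_common")
  expect_error(task_config(walk_sd = 0), "walk_sd")
  expect_error(task_config(lower_bound = 0.8, upper_bound = 0.7), "lower")
  expect_error(task_config(initial_probs = c(0.1, 0.5, 0.5, 0.5)), "initial_probs")
  expect_silent(task_config(p_common = 1))
})

test_that("reward-walk reflection follows the standard reflecting map", {
  cfg <- task_config()
  # single reflection at the upper bound: 0.77 -> 1.5 - 0.77 = 0.73
  expect_equal(step_reward_walk(c(0.74, 0.5, 0.5, 0.5), cfg,
                                noise = c(0.03, 0, 0, 0)),
               c(0.73, 0.5, 0.5, 0.5))
  # lower bound: 0.23 -> 0.27
  expect_equal(step_reward_walk(c(0.26, 0.5, 0.5, 0.5), cfg,
                                noise = c(-0.03, 0, 0, 0)),
               c(0.27, 0.5, 0.5, 0.5))
  # zero noise is the identity
  p <- c(0.3, 0.4, 0.6, 0.7)
  expect_equal(step_reward_walk(p, cfg, noise = rep(0, 4)), p)
  # an excursion past the bound folds back inside: 0.5 + 0.3 -> 0.8 -> 0.7
  expect_equal(step_reward_walk(rep(0.5, 4), cfg, noise = rep(0.3, 4)),
               rep(0.7, 4))
  expect_error(step_reward_walk(c(0.9, 0.5, 0.5, 0.5), cfg), "bounds")
  expect_error(step_reward_walk(c(NaN, 0.5, 0.5, 0.5), cfg), "non-finite")
})

test_that("walk increments have the configured SD and stay within bounds", {
  w <- simulate_reward_walk(200000, task_config(), seed = 11)
  p <- as.matrix(w[, c("p00", "p01", "p10", "p11")])
  expect_true(min(p) >= 0.25)
  expect_true(max(p) <= 0.75)
  # interior steps (away from the reflecting bounds) have increment SD 0.025
  inc <- diff(p[, 1])
  interior <- p[-nrow(p), 1] >= 0.30 & p[-nrow(p), 1] <= 0.70 &
    p[-1, 1] >= 0.30 & p[-1, 1] <= 0.70
  expect_equal(sd(inc[interior]), 0.025, tolerance = 0.002 / 0.025)
  # stationary mean of a reflected symmetric walk is the midpoint 0.5
  expect_equal(colMeans(p), rep(0.5, 4), tolerance = 0.05 / 0.5,
               ignore_attr = TRUE)
  # the four walks are independent: increment cross-correlations near zero
  incs <- apply(p, 2, diff)
  cors <- cor(incs)[upper.tri(diag(4))]
  expect_true(all(abs(cors) < 0.02))
})

test_that("transition sampling matches the 70/30 structure", {
  set.seed(21)
  tr <- sample_transition(rep(0L, 100000), task_config())
  # 99% binomial interval around 0.7 at n = 1e5
  expect_lt(abs(mean(tr$common) - 0.7),
            2.576 * sqrt(0.7 * 0.3 / 100000))
  # common flag is definitionally pair == canonical(choice1)
  set.seed(22)
  ch <- sample(0:1, 5000, replace = TRUE)
  tr2 <- sample_transition(ch, task_config())
  expect_equal(tr2$common, tr2$pair == ch)
  # mirrored mapping: rare transitions from choice 0 land in pair 1
  expect_true(all(tr2$pair[!tr2$common] == 1L - ch[!tr2$common]))
  # degenerate config: always canonical
  tr3 <- sample_transition(rep(1L, 1000), task_config(p_common = 1))
  expect_true(all(tr3$common) && all(tr3$pair == 1L))
  expect_error(sample_transition(2L, task_config()), "choice1")
})

test_that("reward sampling is Bernoulli with input validation", {
  expect_equal(sample_reward(rep(0, 100)), rep(0L, 100))
  expect_equal(sample_reward(rep(1, 100)), rep(1L, 100))
  set.seed(3)
  r <- sample_reward(rep(0.6, 20000))
  expect_lt(abs(mean(r) - 0.6), 2.576 * sqrt(0.6 * 0.4 / 20000))
  expect_error(sample_reward(1.2), "prob")
  expect_error(sample_reward(-0.1), "prob")
})

test_that("simulate_session honours the length contract and record invariants", {
  cfg <- task_config(n_trials = 300)
  trials <- simulate_session(random_agent(), cfg, subject_id = "sub1", seed = 5)
  expect_equal(nrow(trials), 300L)
  expect_equal(trials$trial, 1:300)
  expect_true(all(trials$subject_id == "sub1"))
  expect_true(all(trials$choice1 %in% 0:1))
  expect_equal(trials$common, trials$pair == trials$choice1)
  walk <- attr(trials, "walk")
  expect_true(all(as.matrix(walk) >= 0.25 & as.matrix(walk) <= 0.75))

  # missed trials are masked with null fields
  tm <- simulate_session(random_agent(), cfg, miss_rate = 0.3, seed = 6)
  expect_gt(sum(tm$missed), 0)
  miss <- tm[tm$missed, ]
  expect_true(all(is.na(miss$choice1) & is.na(miss$choice2) &
                    is.na(miss$reward) & is.na(miss$pair) & is.na(miss$common)))

  bad_agent <- random_agent()
  bad_agent$p_choice1 <- function(state) c(2, -1)
  expect_error(simulate_session(bad_agent, cfg, seed = 1), "invalid stage-1")
})

test_that("a random agent earns the walk's symmetric mean reward rate", {
  # the reflected walk is symmetric about 0.5, so an indifferent chooser
  # earns rewards at rate 0.5 in the long run
  set.seed(9)
  rate <- mean(vapply(1:20, function(i) {
    tr <- simulate_session(random_agent(), task_config(n_trials = 300))
    mean(tr$reward)
  }, numeric(1)))
  expect_equal(rate, 0.5, tolerance = 0.02 / 0.5)
})
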