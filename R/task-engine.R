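#' Configuration of the two-step task environment
#'
#' Bundles the parameters of the two-stage sequential decision task: a
#' first-stage choice between two options leads, with probability
#' `p_common`, to its canonically associated pair of second-stage options
#' (a *common* transition) and otherwise to the other pair (*rare*). Each of
#' the four second-stage options pays a unit reward with a probability that
#' drifts across trials according to an independent Gaussian random walk with
#' reflecting bounds, encouraging continual learning.
#'
#' @param n_trials Number of trials in a session (integer, at least 2).
#' @param p_common Probability of the common transition; must lie in
#'   (0.5, 1]. Default 0.7.
#' @param walk_sd Standard deviation of the per-trial Gaussian perturbation
#'   applied to each reward probability, on the probability scale.
#'   Default 0.025.
#' @param lower_bound,upper_bound Reflecting bounds on the reward
#'   probabilities. Defaults 0.25 and 0.75.
#' @param initial_probs Either `NULL` (each walk starts at an independent
#'   uniform draw from `[lower_bound, upper_bound]`) or a numeric vector of
#'   4 starting probabilities, indexed as (pair 0 option 0, pair 0 option 1,
#'   pair 1 option 0, pair 1 option 1).
#' @param seed Optional integer seed recorded in the configuration and used
#'   by simulation helpers when no explicit seed is given to them.
#'
#' @return An object of class `task_config` (a named list).
#' @examples
#' cfg <- task_config(n_trials = 300)
#' cfg$p_common
#' @export
task_config <- function(n_trials = 300L,
                        p_common = 0.7,
                        walk_sd = 0.025,
                        lower_bound = 0.25,
                        upper_bound = 0.75,
                        initial_probs = NULL,
                        seed = NULL) {
  if (!is_scalar_number(n_trials) || n_trials < 2 || n_trials != round(n_trials)) {
    abort_bad_arg("n_trials", "must be an integer >= 2")
  }
  if (!is_scalar_number(p_common) || p_common <= 0.5 || p_common > 1) {
    abort_bad_arg("p_common", "must lie in (0.5, 1]")
  }
  if (!is_scalar_number(walk_sd) || walk_sd <= 0) {
    abort_bad_arg("walk_sd", "must be > 0")
  }
  if (!is_scalar_number(lower_bound) || !is_scalar_number(upper_bound) ||
      lower_bound < 0 || upper_bound > 1 || lower_bound >= upper_bound) {
    abort_bad_arg("lower_bound/upper_bound", "must satisfy 0 <= lower < upper <= 1")
  }
  if (!is.null(initial_probs)) {
    if (length(initial_probs) != 4L || !is.numeric(initial_probs) ||
        any(!is.finite(initial_probs))) {
      abort_bad_arg("initial_probs", "must be 4 finite probabilities or NULL")
    }
    if (any(initial_probs < lower_bound | initial_probs > upper_bound)) {
      abort_bad_arg("initial_probs", "must lie within [lower_bound, upper_bound]")
    }
  }
  structure(
    list(
      n_trials = as.integer(n_trials),
      p_common = p_common,
      walk_sd = walk_sd,
      lower_bound = lower_bound,
      upper_bound = upper_bound,
      initial_probs = initial_probs,
      seed = seed
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  trials: %d, p(common): %.2f\n", x$n_trials, x$p_common))
  cat(sprintf("  reward walk: N(0, %.3f^2) reflected into [%.2f, %.2f]\n",
              x$walk_sd, x$lower_bound, x$upper_bound))
  invisible(x)
}

init_reward_walk <- function(config) {
  if (is.null(config$initial_probs)) {
    runif(4, config$lower_bound, config$upper_bound)
  } else {
    as.numeric(config$initial_probs)
  }
}

#' Advance the reward-probability random walk by one trial
#'
#' Perturbs each of the four second-stage reward probabilities independently
#' by Gaussian noise with mean zero and SD `config$walk_sd`, then reflects
#' any value that leaves `[lower_bound, upper_bound]` back inside
#' (`p' > U` maps to `2U - p'`, `p' < L` to `2L - p'`, applied repeatedly
#' until the value is in range).
#'
#' @param probs Numeric vector of 4 current reward probabilities.
#' @param config A [task_config()].
#' @param noise Optional numeric vector of 4 perturbations, mainly for
#'   testing; when `NULL` the perturbations are drawn from the current RNG.
#'
#' @return Numeric vector of 4 updated probabilities, all within the bounds.
#' @examples
#' cfg <- task_config()
#' step_reward_walk(rep(0.5, 4), cfg, noise = c(0.3, 0, 0, 0))
#' @export
step_reward_walk <- function(probs, config, noise = NULL) {
  stopifnot(length(probs) == 4L, is.numeric(probs))
  if (any(!is.finite(probs))) stop("non-finite reward probability", call. = FALSE)
  if (any(probs < config$lower_bound | probs > config$upper_bound)) {
    stop("reward probabilities outside the reflecting bounds", call. = FALSE)
  }
  noise <- noise %||% rnorm(4, 0, config$walk_sd)
  out <- reflect_into_bounds(probs + noise, config$lower_bound, config$upper_bound)
  if (any(!is.finite(out))) stop("non-finite reward probability", call. = FALSE)
  out
}

#' Simulate a reward-probability walk over many trials
#'
#' @param n_steps Number of steps to simulate.
#' @param config A [task_config()].
#' @param seed Optional seed (defaults to `config$seed` when set).
#'
#' @return A tibble with columns `step` (0-based; row 0 is the initial
#'   state) and `p00`, `p01`, `p10`, `p11`, the reward probabilities of
#'   (pair, option) combinations.
#' @export
simulate_reward_walk <- function(n_steps, config = task_config(), seed = NULL) {
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  p <- init_reward_walk(config)
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 4L)
  out[1L, ] <- p
  noise <- matrix(rnorm(4L * n_steps, 0, config$walk_sd), ncol = 4L)
  lo <- config$lower_bound
  hi <- config$upper_bound
  for (i in seq_len(n_steps)) {
    p <- reflect_into_bounds(p + noise[i, ], lo, hi)
    out[i + 1L, ] <- p
  }
  tibble::tibble(
    step = 0:n_steps,
    p00 = out[, 1], p01 = out[, 2], p10 = out[, 3], p11 = out[, 4]
  )
}

canonical_pair <- function(choice1) choice1

#' Sample the first-stage to second-stage transition
#'
#' Each first-stage option has a fixed canonically associated second-stage
#' pair reached with probability `p_common`; the mapping for option 1 is the
#' mirror of option 0 and stays constant across the session.
#'
#' @param choice1 Integer vector of first-stage choices (0 or 1).
#' @param config A [task_config()].
#'
#' @return A tibble with one row per choice and columns `pair` (0/1) and
#'   `common` (logical).
#' @export
sample_transition <- function(choice1, config = task_config()) {
  if (!all(choice1 %in% c(0L, 1L))) abort_bad_arg("choice1", "must be 0 or 1")
  n <- length(choice1)
  common <- runif(n) < config$p_common
  pair <- ifelse(common, canonical_pair(choice1), 1L - canonical_pair(choice1))
  tibble::tibble(pair = as.integer(pair), common = common)
}

#' Sample Bernoulli rewards
#'
#' @param prob Numeric vector of reward probabilities in `[0, 1]`.
#' @return Integer vector of 0/1 rewards.
#' @export
sample_reward <- function(prob) {
  if (!is.numeric(prob) || any(!is.finite(prob)) || any(prob < 0 | prob > 1)) {
    abort_bad_arg("prob", "must be probabilities in [0, 1]")
  }
  rbinom(length(prob), 1L, prob)
}

validate_agent <- function(agent) {
  need <- c("init", "p_choice1", "p_choice2", "update")
  if (!is.list(agent) || !all(need %in% names(agent)) ||
      !all(vapply(agent[need], is.function, logical(1)))) {
    stop("`agent` must be a list with functions init, p_choice1, p_choice2, update",
         call. = FALSE)
  }
  agent
}

check_choice_probs <- function(p, where) {
  if (length(p) != 2L || any(!is.finite(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-8) {
    stop(sprintf("agent returned invalid %s choice probabilities", where),
         call. = FALSE)
  }
  p
}

#' Simulate one session of the two-step task
#'
#' Plays an agent against the task environment for `config$n_trials` trials.
#' On each trial the agent supplies stage-1 and stage-2 choice probabilities,
#' the environment samples the transition and reward, the agent observes the
#' outcome, and the reward-probability walk advances by one step. Missed
#' trials are emulated by masking completed trials at random at rate
#' `miss_rate`: masked rows have `missed = TRUE` and `NA` choice, transition
#' and reward fields.
#'
#' @param agent An agent object such as [hybrid_agent()] or
#'   [random_agent()]: a list of functions `init()`, `p_choice1(state)`,
#'   `p_choice2(state, pair)` and
#'   `update(state, choice1, pair, common, choice2, reward)`.
#' @param config A [task_config()].
#' @param subject_id Identifier recorded on every trial row.
#' @param miss_rate Proportion of trials masked as missed. Default 0.
#' @param seed Optional seed (defaults to `config$seed` when set).
#'
#' @return A tibble of trial records with columns `subject_id`, `trial`,
#'   `choice1`, `pair`, `common`, `choice2`, `reward`, `missed`, carrying the
#'   latent reward-probability walk as attribute `"walk"`.
#' @examples
#' trials <- simulate_session(random_agent(), task_config(n_trials = 50), seed = 1)
#' head(trials)
#' @export
simulate_session <- function(agent, config = task_config(), subject_id = "s001",
                             miss_rate = 0, seed = NULL) {
  validate_agent(agent)
  if (!is_scalar_number(miss_rate) || miss_rate < 0 || miss_rate >= 1) {
    abort_bad_arg("miss_rate", "must lie in [0, 1)")
  }
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)

  n <- config$n_trials
  probs <- init_reward_walk(config)
  state <- agent$init()
  choice1 <- integer(n); pair <- integer(n); common <- logical(n)
  choice2 <- integer(n); reward <- integer(n)
  walk <- matrix(NA_real_, nrow = n, ncol = 4L)

  for (t in seq_len(n)) {
    walk[t, ] <- probs
    p1 <- check_choice_probs(agent$p_choice1(state), "stage-1")
    c1 <- if (runif(1) < p1[1L]) 0L else 1L
    tr <- sample_transition(c1, config)
    p2 <- check_choice_probs(agent$p_choice2(state, tr$pair), "stage-2")
    c2 <- if (runif(1) < p2[1L]) 0L else 1L
    r <- sample_reward(probs[2L * tr$pair + c2 + 1L])
    state <- agent$update(state, c1, tr$pair, tr$common, c2, r)
    choice1[t] <- c1; pair[t] <- tr$pair; common[t] <- tr$common
    choice2[t] <- c2; reward[t] <- r
    probs <- step_reward_walk(probs, config)
  }

  missed <- runif(n) < miss_rate
  out <- tibble::tibble(
    subject_id = subject_id,
    trial = seq_len(n),
    choice1 = ifelse(missed, NA_integer_, choice1),
    pair = ifelse(missed, NA_integer_, pair),
    common = ifelse(missed, NA, common),
    choice2 = ifelse(missed, NA_integer_, choice2),
    reward = ifelse(missed, NA_integer_, reward),
    missed = missed
  )
  attr(out, "walk") <- tibble::as_tibble(
    setNames(as.data.frame(walk), c("p00", "p01", "p10", "p11"))
  )
  attr(out, "seed") <- seed
  out
}
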