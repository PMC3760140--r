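#' Parameters of the hybrid model-based/model-free agent
#'
#' The agent mixes two stage-1 valuations: model-free values learned by
#' SARSA(lambda) temporal-difference updates, and model-based values computed
#' by a one-step Bellman lookahead through the known transition
#' probabilities. Choices are softmax in the mixed values, with a
#' perseveration bonus for repeating the previous first-stage choice.
#'
#' @param w Model-based mixing weight in `[0, 1]`; `w = 0` is a pure
#'   model-free learner, `w = 1` pure model-based.
#' @param alpha Learning rate in `(0, 1]`.
#' @param lam Eligibility-trace parameter lambda in `[0, 1]`; controls how
#'   directly the terminal reward updates stage-1 values.
#' @param beta1,beta2 Softmax inverse temperatures (>= 0) for the stage-1
#'   and stage-2 choices.
#' @param persev Perseveration bonus added to the utility of the previously
#'   chosen stage-1 option (any real number; negative values produce
#'   switching).
#'
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(w = 0.5, alpha = 0.4, lam = 0.6,
                         beta1 = 4, beta2 = 4, persev = 0.1) {
  if (!is_scalar_number(w) || w < 0 || w > 1) abort_bad_arg("w", "must lie in [0, 1]")
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1) {
    abort_bad_arg("alpha", "must lie in (0, 1]")
  }
  if (!is_scalar_number(lam) || lam < 0 || lam > 1) {
    abort_bad_arg("lam", "must lie in [0, 1]")
  }
  if (!is_scalar_number(beta1) || beta1 < 0) abort_bad_arg("beta1", "must be >= 0")
  if (!is_scalar_number(beta2) || beta2 < 0) abort_bad_arg("beta2", "must be >= 0")
  if (!is_scalar_number(persev)) abort_bad_arg("persev", "must be a finite number")
  structure(
    list(w = w, alpha = alpha, lam = lam, beta1 = beta1, beta2 = beta2,
         persev = persev),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "<agent_params> w=%.2f alpha=%.2f lambda=%.2f beta1=%.2f beta2=%.2f persev=%.2f\n",
    x$w, x$alpha, x$lam, x$beta1, x$beta2, x$persev))
  invisible(x)
}

#' SARSA(lambda) model-free update after one trial
#'
#' Applies the two temporal-difference updates of one completed trial. With
#' `delta2 = reward - q2[pair, choice2]`, the stage-2 value moves by
#' `alpha * delta2`; with `delta1 = q2_pre[pair, choice2] - q1[choice1]`
#' (using the stage-2 value *before* its update), the stage-1 value moves by
#' `alpha * delta1 + alpha * lam * delta2`, so the eligibility trace passes
#' a fraction `lam` of the terminal prediction error straight to stage 1.
#'
#' @param q1 Numeric vector of 2 stage-1 model-free values.
#' @param q2 2 x 2 numeric matrix of stage-2 values, rows = pair, cols = option.
#' @param choice1,pair,choice2 Trial events (0/1 each).
#' @param reward Reward received (0/1).
#' @param params An [agent_params()].
#'
#' @return A list with updated `q1` and `q2`.
#' @export
mf_update <- function(q1, q2, choice1, pair, choice2, reward, params) {
  stopifnot(length(q1) == 2L, all(dim(q2) == c(2L, 2L)),
            all(is.finite(q1)), all(is.finite(q2)))
  i1 <- choice1 + 1L; ip <- pair + 1L; i2 <- choice2 + 1L
  delta2 <- reward - q2[ip, i2]
  q2_pre <- q2[ip, i2]
  q2[ip, i2] <- q2[ip, i2] + params$alpha * delta2
  delta1 <- q2_pre - q1[i1]
  q1[i1] <- q1[i1] + params$alpha * delta1 + params$alpha * params$lam * delta2
  list(q1 = q1, q2 = q2)
}

#' Model-based stage-1 values from stage-2 values
#'
#' Evaluates each first-stage action prospectively through the true
#' transition probabilities:
#' `Q_MB(a) = p_common * max(q2[canonical(a), ]) + (1 - p_common) * max(q2[other(a), ])`.
#' The agent is assumed to know the (fixed) transition structure.
#'
#' @param q2 2 x 2 matrix of stage-2 values (rows = pair, cols = option).
#' @param config A [task_config()] supplying `p_common`.
#'
#' @return Numeric vector of 2 model-based stage-1 values.
#' @export
mb_values <- function(q2, config = task_config()) {
  stopifnot(all(dim(q2) == c(2L, 2L)), all(is.finite(q2)))
  best <- c(max(q2[1L, ]), max(q2[2L, ]))
  p <- config$p_common
  c(p * best[1L] + (1 - p) * best[2L],
    p * best[2L] + (1 - p) * best[1L])
}

#' Stage-1 choice probability of the hybrid agent
#'
#' Mixes model-based and model-free stage-1 values as
#' `Q = w * Q_MB + (1 - w) * Q_MF`, adds the perseveration bonus to the
#' previously chosen option, and returns the softmax probability (inverse
#' temperature `beta1`) of choosing option 0.
#'
#' @param q_mb,q_mf Numeric vectors of 2 stage-1 values.
#' @param prev_choice Previous first-stage choice (0/1) or `NA`/`NULL` when
#'   there is none (no perseveration applied).
#' @param params An [agent_params()].
#'
#' @return Probability of choosing option 0.
#' @export
hybrid_choice_prob <- function(q_mb, q_mf, prev_choice, params) {
  stopifnot(length(q_mb) == 2L, length(q_mf) == 2L,
            all(is.finite(q_mb)), all(is.finite(q_mf)))
  q <- params$w * q_mb + (1 - params$w) * q_mf
  u <- params$beta1 * q
  if (!is.null(prev_choice) && length(prev_choice) == 1L && !is.na(prev_choice)) {
    u[prev_choice + 1L] <- u[prev_choice + 1L] + params$persev
  }
  softmax2(u)[1L]
}

#' Construct a hybrid model-based/model-free agent
#'
#' Returns the agent interface consumed by [simulate_session()]: internal
#' state holds the model-free stage-1 values, the stage-2 value table and
#' the previous first-stage choice; learning follows [mf_update()] and
#' stage-1 valuation mixes [mb_values()] with the model-free values via
#' [hybrid_choice_prob()]. Stage-2 choices are softmax in the stage-2 values
#' of the presented pair with inverse temperature `beta2`.
#'
#' @param params An [agent_params()].
#' @param config A [task_config()]; supplies the transition probability used
#'   by the model-based valuation.
#' @return An agent object (list of `init`, `p_choice1`, `p_choice2`,
#'   `update` functions).
#' @export
hybrid_agent <- function(params = agent_params(), config = task_config()) {
  stopifnot(inherits(params, "agent_params"))
  list(
    init = function() {
      list(q1 = c(0, 0), q2 = matrix(0, 2L, 2L), prev_choice = NA_integer_)
    },
    p_choice1 = function(state) {
      p0 <- hybrid_choice_prob(mb_values(state$q2, config), state$q1,
                               state$prev_choice, params)
      c(p0, 1 - p0)
    },
    p_choice2 = function(state, pair) {
      softmax2(params$beta2 * state$q2[pair + 1L, ])
    },
    update = function(state, choice1, pair, common, choice2, reward) {
      upd <- mf_update(state$q1, state$q2, choice1, pair, choice2, reward, params)
      list(q1 = upd$q1, q2 = upd$q2, prev_choice = choice1)
    }
  )
}

#' A uniformly random agent
#'
#' Chooses both stages uniformly at random; useful as a behavioural null.
#' @return An agent object for [simulate_session()].
#' @export
random_agent <- function() {
  list(
    init = function() list(),
    p_choice1 = function(state) c(0.5, 0.5),
    p_choice2 = function(state, pair) c(0.5, 0.5),
    update = function(state, choice1, pair, common, choice2, reward) state
  )
}
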