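---
title: "Dissociating model-based and model-free learning in the two-step task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating model-based and model-free learning in the two-step task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepr)
```

## The task and its generative model

The two-step task is a sequential decision paradigm built to separate two
reinforcement-learning strategies that ordinary bandit tasks confound. Each
trial has two stages: a first-stage choice between two options, then a
second-stage choice within one of two option pairs. Which pair is offered
depends stochastically on the first choice — each option leads to its
canonically associated pair with probability `p_common = 0.7` (a *common*
transition) and to the other pair otherwise (*rare*); the mapping for one
option is the mirror of the other and never changes. Each of the four
second-stage options pays a unit reward with a latent probability that
drifts across trials as an independent Gaussian random walk: per trial a
N(0, 0.025²) perturbation, reflected back into [0.25, 0.75] whenever it
leaves the bounds. The drift forces continual learning; the bounds keep all
options worth tracking.

`task_config()` holds these constants. The reflection map is the standard
reflecting-walk construction (`p' > U` becomes `2U − p'`, `p' < L` becomes
`2L − p'`, iterated), under which the walk's stationary distribution is
symmetric about 0.5. With a step SD of 0.025 against a band of width 0.5,
double reflections are vanishingly rare, but the iterated map makes the
update total regardless. Initial probabilities are drawn uniformly within
the bounds (configurable); the walk advances once per trial, including
missed trials, since the drift is time-driven rather than event-driven.

## Why stay/switch behaviour identifies the strategy

A *model-free* learner (temporal-difference learning with an eligibility
trace) reinforces first-stage choices that ended in reward, wherever the
reward occurred: its fingerprint is a positive main effect of previous
reward on the probability of repeating (*staying with*) the previous
first-stage choice. A *model-based* learner evaluates first-stage options
prospectively through the transition model, so a reward collected after a
*rare* transition makes the *other* first-stage option more attractive: its
fingerprint is a positive reward × transition interaction. Real
participants show a mixture of both.

`encode_trials()` turns raw trial sequences into this factorial design: one
row per consecutive pair of completed trials, outcome `stay`, predictors
from the earlier trial with the ±1 coding (reward: +1/−1; transition:
common +1, rare −1; and their product). Pairs touching a missed trial are
dropped — the conservative choice, since the intervening events are
unobserved.

## The hybrid agent

`hybrid_agent()` implements the standard hybrid account used with this
task. Model-free stage values follow SARSA(λ):
`δ₂ = r − Q₂(pair, c₂)` updates the stage-2 value with learning rate α, and
the stage-1 value moves by `α·δ₁ + α·λ·δ₂` with
`δ₁ = Q₂(pair, c₂) − Q₁(c₁)` (stage-2 value taken before its own update).
Model-based stage-1 values are the one-step Bellman lookahead through the
*true* transition probabilities,
`Q_MB(a) = 0.7·max Q₂(canonical(a), ·) + 0.3·max Q₂(other(a), ·)`;
transition learning is omitted deliberately because the mapping is fixed
for the whole session and quickly learned. Choice follows a softmax over
the mixture `w·Q_MB + (1−w)·Q_MF` with inverse temperature β₁ plus a
perseveration bonus for the previously chosen option; stage 2 is a softmax
in the presented pair's values with β₂. `w` is the quantity of scientific
interest: 0 is pure model-free, 1 pure model-based.

## The synthetic cohort

No behavioural data are deposited with the study this package emulates, so
`simulate_population()` generates cohorts that match its reported study
conditions: two subsamples (48 subjects × 350 trials and 49 × 300 — the
original had 48 + 50 with one exclusion leaving 97, which subsample
unstated), about 1.4% of trials masked as missed, and a questionnaire-scale
covariate (normal with mean 16, SD 5, truncated to [0, 23] and rounded,
matching the reported subsample means near 16.5/15.2 and SDs near 4.7/5.1).
Per-subject agent parameters are drawn on scales that respect their ranges
— logit-normal for `w`, `alpha`, `lam`; log-normal for `beta1`, `beta2`;
normal for `persev` — which also lets a standardized latent trait shift
`logit(w)` and `log(beta1)` linearly (`link_w`, `link_beta1`). The
functional form of any real trait–strategy link is unknown; this one is a
device for power and recovery studies, not a mechanistic claim. The default
`link_beta1 = −0.3` (higher trait → noisier choices, i.e. generally weaker
learning effects of both kinds) mirrors the qualitative finding the
pipeline is designed to detect; `link_w` defaults to 0. Missed trials are
masked *after* simulation, so the agent's learning history includes them —
adequate for an emulation whose misses are rare and random.

What the generator does **not** emulate: reaction times and deadline
pressure, within-session fatigue or drift in strategy, transition-model
learning early in the session, and any true mechanism linking personality
to learning. Passing tests therefore demonstrate that the *pipeline*
recovers what the generator planted at realistic scale — not that the
substantive findings would replicate in people.

`simulate_from_regression()` is the second generator: it samples directly
from the factorial logistic model that the analysis fits (per-subject
random effects from a 4-dimensional normal, iid ±1 predictors with the
task's marginal frequencies, Bernoulli stay outcomes). Being the exact
generative counterpart of the estimator, it is the right tool for
self-consistency and coverage studies, and its defaults encode the
recovery study's ground truth: fixed effects (1.0, 0, 0.198, 0.132) —
intercept and transition set by convention, reward and reward × transition
at the group-level values the original analysis reports — with
uncorrelated random-effect SDs of 0.3.

## Inference

`fit_multilevel()` fits `stay ~ trans * rew * extra + (1 + trans*rew | subID)`
(and the `* engage` extension) with a binomial response by maximizing the
Laplace-approximated marginal likelihood over the fixed effects and the
unstructured, Cholesky-parameterized 4 × 4 random-effect covariance. Two
engines are offered — `glmmTMB` (default) and `lme4::glmer`, both Laplace —
which agree to ~10⁻⁵ on cohort-scale fits; the default is roughly thirty
times faster here. Wald statistics use the two-sided normal reference
(`p = 2(1 − Φ(|Z|))`), matching how such coefficients are conventionally
reported, and `wald_contrast()` tests linear combinations of fixed effects
with the 1-df chi-square `(c'β)²/(c'Vc)`.

The test suite verifies the Laplace machinery two ways on small instances:
the engine's objective equals a textbook Laplace approximation (mode +
curvature of the integrand) to ~10⁻⁶, and the approximation itself agrees
with 4-dimensional adaptive Gauss–Hermite quadrature to better than 10⁻²
on 2-subject toys with random-effect SD 0.15 — the scale at which the
Laplace error for Bernoulli clusters of ~40 trials is demonstrably below
that tolerance. In the zero-variance limit the marginal likelihood
collapses to the pooled single-level logistic likelihood, checked against
`glm()` to 10⁻³.

`fit_subject_logistic()` is a self-contained Newton/IRLS fitter for the
per-subject factorial model with an optional L2 penalty on the
non-intercept terms (default 10⁻⁴ where used) so that separated subjects —
e.g. deterministic win-stay players — still yield finite coefficients. It
always reports the *unpenalized* deviance at the optimum, which keeps
deviance differences interpretable as likelihood-ratio statistics.
Convergence uses a relative objective change below 10⁻⁸ and a gradient
norm below 10⁻⁵, with step halving; non-convergence is flagged, not
thrown.

## The engagement score and cross-fitting

`engagement_score()` quantifies a subject's overall responsiveness to trial
events without committing to either strategy: the deviance of the
intercept-only stay model minus the deviance of the full factorial model,
i.e. the 3-df likelihood-ratio statistic for *any* dependence of staying on
the previous trial's events. For unresponsive subjects the score is
approximately χ²₃ (mean 3) — verified against the asymptotic reference by
simulation in the tests — so it is a calibrated null scale. The full model
is fit unpenalized where its optimum is finite and falls back to the small
ridge under separation (the fallback is recorded per subject); the
intercept-only fit cannot separate.

The score is computed on odd-numbered trials only, while every model that
*uses* the score — the top-20% subgroup re-fit and the
engagement-interaction model — is fit on even-numbered trials only. This
cross-fitting removes the selection bias of defining and testing an effect
on the same data. The split is enforced structurally: `analysis_config()`
rejects any configuration in which the two parities coincide, and
`run_analysis()` re-asserts disjointness at run time. Each encoded row
spans two trials, so "trial parity" is ambiguous by one position; the
package takes the parity of the outcome trial (n+1) by default and exposes
`parity_on = "previous"` as the alternative, with tests confirming the
pipeline behaves equivalently under both conventions.

Subgroup selection uses the ceiling rule, `⌈fraction·N⌉` — for 97 subjects
and fraction 0.20 that is exactly 20 — with ties broken deterministically
by subject-id order. The engagement moderator entering model (c) is
z-scored across the full included sample; the subgroup analysis uses raw
ranks.

## The three analysis variants and the contrast

`run_analysis()` executes the full sequence: (a) the
extraversion-moderation model on all encoded rows; (b) the same model
restricted to the even-trial rows of the top-20% subgroup; (c) the full
factorial with both moderators, `stay ~ trans*rew*extra*engage + (1 +
trans*rew | subID)`, on everyone's even-trial rows; then the Wald contrast
`(rew:extra:engage) − (trans:rew:extra:engage)`, asking whether engagement
moderates the extraversion link to model-free learning more strongly than
its link to model-based learning. An optional fourth variant adds a ±1
subsample indicator interacted with all effects. All randomness flows from
the single config seed, so reports are exactly reproducible.

## Numerical and design choices

- **Engine default**: `glmmTMB`, for speed at identical (Laplace) results;
  `lme4` retained as the cross-checking engine since the model formulas are
  native to it.
- **Problem sizes**: tests run cohorts of 20–100 subjects and the full
  97-subject recovery study at 20 replicates; these sizes give Monte-Carlo
  error comfortably inside the assertion tolerances while keeping the
  default suite fast.
- **Separation handling**: per-subject ridge 10⁻⁴ on slopes only;
  engagement scores prefer the unpenalized optimum (fallback logged).
- **Degenerate inputs**: constant covariates, empty row sets, non-PSD
  random-effect specifications, out-of-range probabilities and duplicate
  trial keys are all rejected with named errors; singular random-effect
  *estimates* (common in pure-strategy cohorts where some variances are
  truly zero) are flagged via `converged` rather than thrown.
- **Ties and counts**: top-fraction size by ceiling; rank ties by id order.

## Limitations

The package infers strategy from stay/switch regression signatures; it does
not fit the hybrid RL model to data by likelihood maximization, estimate
`w` per subject, or model reaction times. Group-level conclusions about
moderation rest on the linear-interaction form of the multilevel model; the
generator can plant nonlinear links the analysis would only partially
detect, which is precisely the kind of robustness question the simulators
are meant to make easy to ask.
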