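# Independent numerical oracles used by the inference tests.

# Gauss-Hermite nodes/weights by the Golub-Welsch eigenvalue construction.
gh_nodes <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

subject_design <- function(d) {
  list(X = cbind(1, d$trans, d$rew, d$trans * d$rew), y = d$stay)
}

re_mode <- function(X, y, beta, Sinv) {
  eta0 <- drop(X %*% beta)
  nli <- function(b) {
    eta <- eta0 + drop(X %*% b)
    -sum(y * eta - log1p(exp(eta))) + 0.5 * drop(t(b) %*% Sinv %*% b)
  }
  gnl <- function(b) {
    eta <- eta0 + drop(X %*% b)
    -drop(crossprod(X, y - plogis(eta))) + drop(Sinv %*% b)
  }
  opt <- stats::optim(rep(0, 4), nli, gnl, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  mu <- plogis(eta0 + drop(X %*% opt$par))
  H <- crossprod(X, X * (mu * (1 - mu))) + Sinv
  list(mode = opt$par, value = -opt$value, H = H, nli = nli)
}

# Marginal log-likelihood of stay ~ trans*rew + (1 + trans*rew | subject) by
# adaptive Gauss-Hermite product quadrature over the 4-dim random effect.
agq_loglik <- function(rows, beta, Sigma, n_nodes = 9) {
  gh <- gh_nodes(n_nodes)
  grid <- as.matrix(expand.grid(gh$x, gh$x, gh$x, gh$x))
  wlog <- rowSums(log(as.matrix(expand.grid(gh$w, gh$w, gh$w, gh$w))))
  Sinv <- solve(Sigma)
  ld_sigma <- determinant(Sigma)$modulus[1]
  total <- 0
  for (id in unique(rows$subject_id)) {
    des <- subject_design(rows[rows$subject_id == id, ])
    md <- re_mode(des$X, des$y, beta, Sinv)
    A <- t(chol(solve(md$H)))
    B <- grid %*% t(sqrt(2) * A)
    logg <- apply(B, 1, function(off) -md$nli(md$mode + off))
    terms <- logg + rowSums(grid^2) + wlog
    m <- max(terms)
    log_int <- 2 * log(2) + sum(log(diag(A))) + m + log(sum(exp(terms - m)))
    total <- total + log_int - 2 * log(2 * pi) - 0.5 * ld_sigma
  }
  total
}

# Textbook Laplace approximation to the same marginal log-likelihood.
laplace_loglik <- function(rows, beta, Sigma) {
  Sinv <- solve(Sigma)
  ld_sigma <- determinant(Sigma)$modulus[1]
  total <- 0
  for (id in unique(rows$subject_id)) {
    des <- subject_design(rows[rows$subject_id == id, ])
    md <- re_mode(des$X, des$y, beta, Sinv)
    total <- total + md$value - 0.5 * determinant(md$H)$modulus[1] -
      0.5 * ld_sigma
  }
  total
}

# Laplace marginal log-likelihood as computed by the glmmTMB engine with all
# parameters held fixed (diagonal random-effect SDs `sds`).
glmmtmb_laplace_at <- function(rows, beta, sds) {
  d <- as.data.frame(rows)
  d$subject_id <- factor(d$subject_id)
  m <- glmmTMB::glmmTMB(
    stay ~ trans * rew + (1 + trans * rew | subject_id),
    data = d, family = stats::binomial(),
    start = list(beta = beta, theta = c(log(sds), rep(0, 6))),
    map = list(beta = factor(rep(NA, 4)), theta = factor(rep(NA, 10)))
  )
  as.numeric(stats::logLik(m))
}

# Fixed effects of the Laplace engine with the random-effect SDs pinned in
# the zero-variance limit (SD 1e-4); the marginal likelihood then collapses
# to the pooled single-level logistic likelihood.
glmmtmb_pooled_limit <- function(rows) {
  d <- as.data.frame(rows)
  d$subject_id <- factor(d$subject_id)
  m <- glmmTMB::glmmTMB(
    stay ~ trans * rew + (1 + trans * rew | subject_id),
    data = d, family = stats::binomial(),
    start = list(theta = c(rep(log(1e-4), 4), rep(0, 6))),
    map = list(theta = factor(rep(NA, 10)))
  )
  unname(glmmTMB::fixef(m)$cond)
}

# Hand-built trial table for coding tests.
make_trials <- function(subject_id, choice1, common, reward,
                        missed = rep(FALSE, length(choice1))) {
  n <- length(choice1)
  tibble::tibble(
    subject_id = subject_id,
    trial = seq_len(n),
    choice1 = ifelse(missed, NA_integer_, choice1),
    pair = ifelse(missed, NA_integer_, ifelse(common, choice1, 1L - choice1)),
    common = ifelse(missed, NA, common),
    choice2 = ifelse(missed, NA_integer_, 0L),
    reward = ifelse(missed, NA_integer_, reward),
    missed = missed
  )
}

# Null-cohort design rows: stay outcomes independent of all predictors.
null_rows <- function(n_subjects, n_trials, seed) {
  simulate_from_regression(
    regression_gen_spec(fixed = c(intercept = 0, trans = 0, rew = 0,
                                  trans_rew = 0),
                        re_sd = rep(0, 4), n_subjects = n_subjects,
                        n_trials = n_trials),
    seed = seed
  )
}
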