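# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written as plain double loops / closed forms
# so they exercise none of the package's likelihood code paths.

make_session <- function(pump_counts, bursts, id = "s1") {
  trials <- Map(function(np, b) {
    if (b) list(actions = rep(1L, np), burst = TRUE)
    else list(actions = c(rep(1L, np), 0L), burst = FALSE)
  }, pump_counts, bursts)
  bart_session(id, trials)
}

random_session <- function(n_trials = 6L, id = "r1") {
  repeat {
    np <- sample(1:8, n_trials, replace = TRUE)
    b <- runif(n_trials) < 0.4
    ses <- make_session(np, b, id)
    return(ses)
  }
}

random_params <- function() {
  cognitive_params(gamma = runif(1, 0.1, 1.5), beta = runif(1, 0.1, 3),
                   alpha0 = runif(1, 0.5, 3.5), alpha1 = runif(1, -0.05, 0.05))
}

# --- independent oracles ------------------------------------------------

oracle_action_loglik <- function(session, p) {
  ll <- 0
  for (tr in session$trials) {
    mu <- 1 / (1 + exp(-(p$alpha0 + p$alpha1 * tr$k)))
    omega <- -p$gamma / log(mu)        # log(1 - p*) = log(mu)
    for (j in seq_along(tr$actions)) {
      theta <- 1 / (1 + exp(p$beta * (j - omega)))
      theta <- min(max(theta, 1e-12), 1 - 1e-12)
      y <- tr$actions[j]
      ll <- ll + y * log(theta) + (1 - y) * log(1 - theta)
    }
  }
  ll
}

oracle_csr_loglik <- function(session, alpha0, alpha1, sigma_alpha) {
  ll <- 0
  K <- session$n_trials
  if (K < 2) return(0)
  for (k in 2:K) {
    s <- 0; n <- 0
    for (kk in 1:(k - 1)) {
      tr <- session$trials[[kk]]
      s <- s + tr$n_pumps - as.integer(tr$burst)
      n <- n + tr$n_pumps
    }
    if (n == 0) next
    ck <- min(max(s / n, 1e-3), 1 - 1e-3)
    mu <- 1 / (1 + exp(-(alpha0 + alpha1 * k)))
    ll <- ll + dbeta(ck, mu * sigma_alpha, (1 - mu) * sigma_alpha, log = TRUE)
  }
  ll
}

oracle_fa_loglik <- function(fa, delta, sigma) {
  ll <- 0
  for (f in fa) {
    z <- log(f / (1 - f))
    ll <- ll - 0.5 * log(2 * pi) - log(sigma) - (z - delta)^2 / (2 * sigma^2)
  }
  ll
}

oracle_mvt_logpdf <- function(x, mu, Sigma, nu) {
  d <- length(mu)
  qf <- drop(t(x - mu) %*% solve(Sigma) %*% (x - mu))
  lgamma((nu + d) / 2) - lgamma(nu / 2) - d / 2 * log(nu * pi) -
    0.5 * determinant(Sigma, logarithm = TRUE)$modulus[1] -
    (nu + d) / 2 * log(1 + qf / nu)
}

oracle_rhat <- function(draws) {
  # textbook split-chain potential scale reduction
  n2 <- floor(nrow(draws) / 2)
  ch <- list()
  for (c in seq_len(ncol(draws))) {
    ch[[length(ch) + 1]] <- draws[1:n2, c]
    ch[[length(ch) + 1]] <- draws[(n2 + 1):(2 * n2), c]
  }
  m <- length(ch); n <- n2
  means <- sapply(ch, mean)
  B <- n / (m - 1) * sum((means - mean(means))^2)
  W <- mean(sapply(ch, var))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# --- small cohort fixture ----------------------------------------------

tiny_cohort <- function(S = 3L, seed = 11L, n_trials = 8L) {
  simulate_cohort(default_hyperparams(), S = S,
                  config = task_config(n_trials = n_trials), seed = seed)
}

# --- shared full-scale recovery fit (computed once, reused by the
#     acceptance criteria on the fit, the ppc calibration and the
#     structural-zero check) ---------------------------------------------

.acceptance_cache <- new.env(parent = emptyenv())

acceptance_recovery <- function() {
  if (is.null(.acceptance_cache$rec)) {
    .acceptance_cache$rec <- recovery_experiment(
      default_hyperparams(), S = 23L, seed = 42L,
      chains = 4L, iter = 2000L, warmup = 1000L)
  }
  .acceptance_cache$rec
}
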