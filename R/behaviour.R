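## The BART cognitive model.
##
## On each trial k the agent holds a subjective belief about the success
## rate of a pump, regresses it on the trial number through a logistic
## trend, converts it to a subjective burst probability p*_k, fixes an
## optimal pump target omega_k before acting, and then emits pump/cash
## decisions with logistic response noise governed by the behavioural
## consistency beta.

#' Cognitive parameters of the BART agent
#'
#' Bundles the four subject-level parameters of the behavioural model:
#' risk-taking propensity `gamma` (scales the optimal pump target),
#' behavioural consistency `beta` (inverse response variability), and the
#' intercept `alpha0` and slope `alpha1` of the logistic trend of the
#' subjective success rate across trials.
#'
#' @param gamma risk-taking propensity, `>= 0`.
#' @param beta behavioural consistency, `>= 0`; `beta = 0` makes every
#'   pump/cash decision a coin flip.
#' @param alpha0 baseline success-belief logit.
#' @param alpha1 per-trial change of the success-belief logit; negative
#'   values mean the perceived burst probability grows as trials unfold.
#' @return an object of class `cognitive_params`.
#' @examples
#' cognitive_params(0.442, 1.471, 2.653, -0.004)
#' @export
cognitive_params <- function(gamma, beta, alpha0, alpha1) {
  check_finite(gamma, "gamma"); check_finite(beta, "beta")
  check_finite(alpha0, "alpha0"); check_finite(alpha1, "alpha1")
  if (gamma < 0) stop_invalid("`gamma` must be >= 0")
  if (beta < 0) stop_invalid("`beta` must be >= 0")
  structure(list(gamma = gamma, beta = beta,
                 alpha0 = alpha0, alpha1 = alpha1),
            class = "cognitive_params")
}

#' @export
print.cognitive_params <- function(x, ...) {
  cat("BART cognitive parameters:\n")
  cat(sprintf("  gamma (risk propensity)      %.4f\n", x$gamma))
  cat(sprintf("  beta  (consistency)          %.4f\n", x$beta))
  cat(sprintf("  alpha0 (belief intercept)    %.4f\n", x$alpha0))
  cat(sprintf("  alpha1 (belief slope/trial)  %.4f\n", x$alpha1))
  invisible(x)
}

as_cognitive_params <- function(x) {
  if (inherits(x, "cognitive_params")) return(x)
  x <- unlist(x)
  cognitive_params(x[["gamma"]], x[["beta"]], x[["alpha0"]], x[["alpha1"]])
}

#' Construct a BART session
#'
#' A session is one subject's ordered collection of trials.  Each trial
#' holds the observed binary action sequence (1 = pump, 0 = cash) and the
#' burst outcome.  On a burst trial every observed action is a pump (the
#' burst truncates the trial); on a cashed trial the single terminating 0
#' is the last action.
#'
#' @param subject_id subject label.
#' @param trials list of trials; each a list with elements `actions`
#'   (integer vector of 0/1) and `burst` (logical).
#' @return an object of class `bart_session` with elements `subject_id`,
#'   `trials` (each augmented with trial index `k`, `n_pumps`, successful
#'   pumps `s` and attempts `n`), and `n_trials`.
#' @export
bart_session <- function(subject_id, trials) {
  if (!length(trials)) {
    return(structure(list(subject_id = subject_id, trials = list(),
                          n_trials = 0L), class = "bart_session"))
  }
  trials <- lapply(seq_along(trials), function(k) {
    tr <- trials[[k]]
    a <- as.integer(tr$actions)
    if (!length(a) || anyNA(a) || any(!a %in% c(0L, 1L)))
      stop_invalid(sprintf("trial %d: actions must be a non-empty 0/1 sequence", k))
    burst <- isTRUE(as.logical(tr$burst))
    if (burst) {
      if (any(a == 0L))
        stop_invalid(sprintf("trial %d: burst trials must contain only pumps", k))
    } else {
      if (a[length(a)] != 0L || sum(a == 0L) != 1L)
        stop_invalid(sprintf(
          "trial %d: cashed trials must end with exactly one cash (0)", k))
    }
    n_pumps <- sum(a == 1L)
    list(k = k, actions = a, burst = burst, n_pumps = n_pumps,
         s = if (burst) n_pumps - 1L else n_pumps,
         n = n_pumps,
         capped = isTRUE(tr$capped))
  })
  structure(list(subject_id = subject_id, trials = trials,
                 n_trials = length(trials)),
            class = "bart_session")
}

#' @export
print.bart_session <- function(x, ...) {
  np <- vapply(x$trials, `[[`, integer(1), "n_pumps")
  nb <- sum(vapply(x$trials, `[[`, logical(1), "burst"))
  cat(sprintf("BART session '%s': %d trials, mean pumps %.2f, %d bursts\n",
              x$subject_id, x$n_trials,
              if (x$n_trials) mean(np) else NA_real_, nb))
  invisible(x)
}

#' Expected success rate of a pump at trial k
#'
#' The subjective success rate follows a logistic trend in the trial
#' number: `mu_k = logit^-1(alpha0 + alpha1 * k)`.  With `alpha1 = 0` the
#' belief is constant across the task.
#'
#' @inheritParams cognitive_params
#' @param k trial index (1-based); may be a vector.
#' @return values strictly inside (0, 1), one per element of `k`.
#' @export
burst_belief_mean <- function(alpha0, alpha1, k) {
  check_finite(alpha0, "alpha0"); check_finite(alpha1, "alpha1")
  check_finite(k, "k")
  if (any(k < 1)) stop_invalid("`k` must be >= 1")
  plogis(alpha0 + alpha1 * k)
}

#' Subjective burst probability
#'
#' The complement of the expected pump success rate: `p* = 1 - mu`.
#'
#' @param mu_alpha_k expected success rate(s) in (0, 1).
#' @return burst probabilities in (0, 1).
#' @export
subjective_burst_prob <- function(mu_alpha_k) {
  check_finite(mu_alpha_k, "mu_alpha_k")
  if (any(mu_alpha_k <= 0 | mu_alpha_k >= 1))
    stop_invalid("`mu_alpha_k` must lie strictly in (0, 1)")
  1 - mu_alpha_k
}

#' Optimal number of pumps for a trial
#'
#' The pump target the agent fixes before acting,
#' `omega = -gamma / log(1 - p*)`: proportional to risk propensity and
#' shrunk toward zero as the subjective burst probability grows.
#'
#' @param gamma risk-taking propensity, `>= 0`.
#' @param p_star subjective burst probability in (0, 1).
#' @return nonnegative pump target (vectorised).
#' @export
optimal_pumps <- function(gamma, p_star) {
  check_finite(gamma, "gamma"); check_finite(p_star, "p_star")
  if (any(gamma < 0)) stop_invalid("`gamma` must be >= 0")
  if (any(p_star <= 0 | p_star >= 1))
    stop_invalid("`p_star` must lie strictly in (0, 1)")
  -gamma / log1p(-p_star)
}

#' Probability of pumping at a choice occasion
#'
#' Logistic decay in the occasion index `j`, centred at the pump target
#' `omega` with slope `beta`: `theta = [1 + exp(beta * (j - omega))]^-1`.
#' At `j = omega` the probability is exactly 0.5, and `beta = 0` gives
#' 0.5 everywhere (random responding).
#'
#' @param j choice-occasion index within a trial, `>= 1`.
#' @param omega pump target for the trial.
#' @param beta behavioural consistency, `>= 0`.
#' @return pump probabilities in (0, 1).
#' @export
pump_probability <- function(j, omega, beta) {
  check_finite(j, "j"); check_finite(omega, "omega")
  check_finite(beta, "beta")
  if (any(j < 1)) stop_invalid("`j` must be >= 1")
  if (any(beta < 0)) stop_invalid("`beta` must be >= 0")
  plogis(-beta * (j - omega))
}

#' Cumulative success rate before trial k
#'
#' `C_k` is the ratio of successful (non-bursting) pumps to pump attempts
#' accumulated over trials `1 .. k-1`.  It is the statistic the belief
#' sub-model regresses on the trial number.  `C_1` has an empty history
#' and is undefined.
#'
#' @param session a [bart_session()].
#' @param k trial index, `>= 2`.
#' @return a value in \[0, 1\] (unclamped; the likelihood clamps).
#' @export
cumulative_success_rate <- function(session, k) {
  stopifnot(inherits(session, "bart_session"))
  if (length(k) != 1L || !is.finite(k)) stop_invalid("`k` must be a single index")
  if (k < 2) stop_invalid("C_k is undefined at k = 1 (empty history)")
  if (k > session$n_trials) stop_invalid("`k` exceeds the number of trials")
  prior <- session$trials[seq_len(k - 1L)]
  s <- sum(vapply(prior, `[[`, integer(1), "s"))
  n <- sum(vapply(prior, `[[`, integer(1), "n"))
  if (n == 0L) stop_invalid("degenerate session: no pump attempts before trial k")
  s / n
}

## Flatten a session for the C++ likelihood kernels: concatenated action
## stream with per-action trial/occasion indices, plus the clamped C_k
## series (NA where undefined -- k = 1 or no prior attempts).
compile_session <- function(session) {
  K <- session$n_trials
  y <- integer(0); kk <- integer(0); jj <- integer(0)
  for (tr in session$trials) {
    J <- length(tr$actions)
    y <- c(y, tr$actions)
    kk <- c(kk, rep.int(tr$k, J))
    jj <- c(jj, seq_len(J))
  }
  Ck <- rep(NA_real_, K)
  if (K >= 2L) {
    s <- cumsum(vapply(session$trials, `[[`, integer(1), "s"))
    n <- cumsum(vapply(session$trials, `[[`, integer(1), "n"))
    idx <- 2:K
    ok <- n[idx - 1L] > 0L
    Ck[idx[ok]] <- s[idx - 1L][ok] / n[idx - 1L][ok]
  }
  Ck_clamped <- pmin(pmax(Ck, .CSR_EPS), 1 - .CSR_EPS)
  list(y = y, kk = kk, jj = jj, K = K,
       ck = Ck_clamped, ck_use = which(!is.na(Ck)))
}

#' Log-likelihood of a session's action sequence
#'
#' The Bernoulli likelihood of all observed pump/cash actions, with the
#' pump probability built from the belief trend, the burst-probability
#' complement, the pump-target rule and the logistic response rule.
#' Probabilities are clamped to `[1e-12, 1 - 1e-12]` inside the log to
#' survive extreme `beta * (j - omega)`.
#'
#' @param session a [bart_session()].
#' @param params a [cognitive_params()] object (or coercible named vector).
#' @return the log-likelihood (0 for an empty session).
#' @export
action_loglik <- function(session, params) {
  stopifnot(inherits(session, "bart_session"))
  p <- as_cognitive_params(params)
  if (session$n_trials == 0L) return(0)
  cs <- compile_session(session)
  cohort_action_loglik_cpp(list(cs), p$gamma, p$beta, p$alpha0, p$alpha1)[1L]
}

#' Log-likelihood of the cumulative success rates
#'
#' Beta likelihood of the clamped `C_k` series for `k = 2..K` under the
#' mean/concentration parameterisation: `C_k ~ Beta(mu_k * sigma_alpha,
#' (1 - mu_k) * sigma_alpha)` with `mu_k` the logistic belief trend.
#'
#' @inheritParams action_loglik
#' @inheritParams cognitive_params
#' @param sigma_alpha Beta concentration, `> 0`.
#' @return the log-likelihood (0 when fewer than two trials).
#' @export
beta_success_loglik <- function(session, alpha0, alpha1, sigma_alpha) {
  stopifnot(inherits(session, "bart_session"))
  check_finite(alpha0, "alpha0"); check_finite(alpha1, "alpha1")
  check_finite(sigma_alpha, "sigma_alpha")
  if (sigma_alpha <= 0) stop_invalid("`sigma_alpha` must be > 0")
  if (session$n_trials <= 1L) return(0)
  cs <- compile_session(session)
  cohort_csr_loglik_cpp(list(cs), alpha0, alpha1, sigma_alpha)[1L]
}

#' Earnings of a session at the task's reward schedule
#'
#' Each pump adds `reward_per_pump` cents to the trial's temporary pool;
#' cashing banks the pool, a burst forfeits it.
#'
#' @param session a [bart_session()].
#' @param config a [task_config()].
#' @return numeric vector of per-trial earnings (cents), with attribute
#'   `total`.
#' @export
session_earnings <- function(session, config = task_config()) {
  stopifnot(inherits(session, "bart_session"))
  per_trial <- vapply(session$trials, function(tr) {
    if (tr$burst) 0 else config$reward_per_pump * tr$n_pumps
  }, numeric(1))
  structure(per_trial, total = sum(per_trial))
}
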