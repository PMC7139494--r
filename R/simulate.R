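## Generators for the BART task, the behaving agent, Network-FA
## measurements and full hierarchical cohorts.  Defaults state the task
## design: 36 trials, burst thresholds uniform on {3..9} (mean 6, SD 2),
## 25 cents per pump.

#' Task design of the simulated BART
#'
#' @param n_trials trials per session.
#' @param burst_support inclusive integer support of the discrete-uniform
#'   burst thresholds; the default `3:9` is the unique consecutive-integer
#'   uniform with mean 6 and SD 2.
#' @param reward_per_pump cents added to the temporary pool per pump.
#' @param max_pumps safety cap on pumps per trial; a capped trial is
#'   recorded as a cash at the cap and flagged `capped`.
#' @return an object of class `task_config`.
#' @export
task_config <- function(n_trials = 36L, burst_support = 3:9,
                        reward_per_pump = 25, max_pumps = 50L) {
  burst_support <- as.integer(burst_support)
  if (!length(burst_support) || anyNA(burst_support) || any(burst_support < 1L))
    stop_invalid("`burst_support` must be positive integers")
  if (n_trials < 0L) stop_invalid("`n_trials` must be >= 0")
  if (max_pumps < 1L) stop_invalid("`max_pumps` must be >= 1")
  structure(list(n_trials = as.integer(n_trials),
                 burst_support = burst_support,
                 reward_per_pump = reward_per_pump,
                 max_pumps = as.integer(max_pumps)),
            class = "task_config")
}

#' Draw a schedule of burst thresholds
#'
#' One i.i.d. draw per trial from the discrete uniform on
#' `config$burst_support`.
#'
#' @param config a [task_config()].
#' @param n number of thresholds (defaults to `config$n_trials`).
#' @param seed optional seed (RNG state is restored afterwards).
#' @return integer vector of burst thresholds.
#' @export
burst_schedule <- function(config = task_config(), n = config$n_trials,
                           seed = NULL) {
  with_seed(seed, {
    sup <- config$burst_support
    sup[sample.int(length(sup), n, replace = TRUE)]
  })
}

#' Simulate one BART session from the cognitive model
#'
#' Per trial: the belief trend gives the subjective burst probability,
#' the pump-target rule gives `omega_k`, and pump/cash decisions are
#' drawn sequentially from the logistic response rule until a cash is
#' drawn or the pump count reaches the trial's burst threshold.
#'
#' @param params a [cognitive_params()] object.
#' @param config a [task_config()].
#' @param seed optional seed.
#' @param burst_thresholds optional explicit schedule (one per trial);
#'   drawn from [burst_schedule()] when `NULL`.
#' @param subject_id label for the returned session.
#' @return a [bart_session()].
#' @export
simulate_session <- function(params, config = task_config(), seed = NULL,
                             burst_thresholds = NULL, subject_id = "sim") {
  params <- as_cognitive_params(params)
  with_seed(seed, {
    if (is.null(burst_thresholds))
      burst_thresholds <- burst_schedule(config)
    stopifnot(length(burst_thresholds) == config$n_trials)
    trials <- vector("list", config$n_trials)
    for (k in seq_len(config$n_trials)) {
      mu_k <- burst_belief_mean(params$alpha0, params$alpha1, k)
      p_star <- subjective_burst_prob(mu_k)
      omega <- optimal_pumps(params$gamma, p_star)
      thr <- burst_thresholds[k]
      actions <- integer(0)
      pumps <- 0L
      burst <- FALSE
      capped <- FALSE
      repeat {
        j <- length(actions) + 1L
        theta <- pump_probability(j, omega, params$beta)
        a <- rbinom(1L, 1L, theta)
        actions <- c(actions, a)
        if (a == 0L) break                      # cashed
        pumps <- pumps + 1L
        if (pumps >= thr) { burst <- TRUE; break }
        if (pumps >= config$max_pumps) {        # thr > cap: forced cash
          actions <- c(actions, 0L); capped <- TRUE; break
        }
      }
      trials[[k]] <- list(actions = actions, burst = burst, capped = capped)
    }
    bart_session(subject_id, trials)
  })
}

#' Simulate Network-FA values
#'
#' Inverse-logit of normal draws centred at the latent network location.
#'
#' @param delta network-FA location on the logit scale.
#' @param sigma inter-tract SD on the logit scale, `> 0`.
#' @param n_tracts number of tracts.
#' @param seed optional seed.
#' @return FA values strictly in (0, 1).
#' @export
simulate_network_fa <- function(delta, sigma, n_tracts, seed = NULL) {
  check_finite(delta, "delta"); check_finite(sigma, "sigma")
  if (sigma <= 0) stop_invalid("`sigma` must be > 0")
  with_seed(seed, plogis(rnorm(n_tracts, delta, sigma)))
}

## Draws from the 4-dim multivariate t, rejecting negative gamma/beta.
rmvt_truncated <- function(n, mu, Sigma, nu, max_tries = 1000L) {
  R <- chol(Sigma)
  out <- matrix(NA_real_, n, 4L, dimnames = list(NULL, .COG_NAMES))
  n_draws <- 0L; n_ok <- 0L; n_tries <- 0L
  filled <- 0L
  while (filled < n) {
    m <- max(2L * (n - filled), 16L)
    z <- matrix(rnorm(m * 4L), m, 4L) %*% R
    w <- sqrt(nu / rchisq(m, nu))
    x <- sweep(z * w, 2L, mu, `+`)
    ok <- x[, 1L] >= 0 & x[, 2L] >= 0
    n_draws <- n_draws + m; n_ok <- n_ok + sum(ok); n_tries <- n_tries + 1L
    take <- which(ok)
    if (length(take)) {
      take <- take[seq_len(min(length(take), n - filled))]
      out[filled + seq_along(take), ] <- x[take, , drop = FALSE]
      filled <- filled + length(take)
    }
    if (n_tries > max_tries)
      stop_invalid("truncated multivariate-t rejection failed to converge")
  }
  attr(out, "rejection_rate") <- 1 - n_ok / n_draws
  out
}

#' Simulate a full hierarchical cohort
#'
#' Per subject: `(gamma, beta, delta1, delta2)` from the truncated
#' multivariate Student-t, `(alpha0, alpha1)` from their normal
#' hierarchies, a 36-trial session from the behaving agent, and one FA
#' vector per network assembled into a connectivity matrix (tracts
#' outside the two networks are left at 0).
#'
#' @param hyper a [joint_hyperparams()] object.
#' @param S number of subjects.
#' @param config a [task_config()].
#' @param seed optional seed.
#' @param networks list of two [network_spec()] objects.
#' @return list with `sessions`, `connectivity` (named list of
#'   [connectivity_matrix()]), `truth` (list: `hyper`, per-subject
#'   parameter data frame), and the generating `config`.
#' @export
simulate_cohort <- function(hyper = default_hyperparams(), S = 23L,
                            config = task_config(), seed = NULL,
                            networks = default_networks()) {
  stopifnot(inherits(hyper, "joint_hyperparams"))
  with_seed(seed, {
    Sigma <- build_covariance(hyper$sds, hyper$rhos)
    cog <- rmvt_truncated(S, hyper$mu, Sigma, hyper$nu)
    if (isTRUE(attr(cog, "rejection_rate") > 0.5))
      warning("truncation rejection rate exceeds 50%; ",
              "hyper-means are close to the boundary", call. = FALSE)
    alpha0 <- rnorm(S, hyper$mu_alpha0, hyper$sd_alpha0)
    alpha1 <- rnorm(S, hyper$mu_alpha1, hyper$sd_alpha1)
    ids <- sprintf("sub-%02d", seq_len(S))
    sessions <- vector("list", S)
    connectivity <- vector("list", S)
    for (s in seq_len(S)) {
      sessions[[s]] <- simulate_session(
        cognitive_params(cog[s, "gamma"], cog[s, "beta"], alpha0[s], alpha1[s]),
        config, subject_id = ids[s])
      M <- matrix(0, 12L, 12L, dimnames = list(roi_labels(), roi_labels()))
      for (nx in 1:2) {
        spec <- networks[[nx]]
        dl <- cog[s, paste0("delta", nx)]
        sg <- if (nx == 1L) hyper$sigma1 else hyper$sigma2
        fa <- simulate_network_fa(dl, sg, nrow(spec$pairs))
        for (i in seq_len(nrow(spec$pairs))) {
          p <- spec$pairs[i, ]
          M[p[1], p[2]] <- M[p[2], p[1]] <- fa[i]
        }
      }
      connectivity[[s]] <- connectivity_matrix(M)
    }
    names(connectivity) <- ids
    truth_params <- data.frame(subject_id = ids, cog, alpha0 = alpha0,
                               alpha1 = alpha1, row.names = NULL)
    list(sessions = sessions, connectivity = connectivity,
         truth = list(hyper = hyper, params = truth_params),
         config = config)
  })
}

#' Simulation-based parameter-recovery experiment
#'
#' Simulates a cohort at known hyperparameters, fits the joint model,
#' and reports truth, posterior mean, credible interval, a coverage flag
#' and the interval-width-normalised error for every tracked population
#' parameter.
#'
#' @param hyper generating [joint_hyperparams()].
#' @param S number of subjects.
#' @param config a [task_config()].
#' @param seed seed for both simulation and fitting.
#' @param ... passed on to [bjm_fit()] (e.g. `chains`, `iter`, `warmup`).
#' @return list with the recovery `report` (data frame), the `fit` and
#'   the simulated `cohort`.
#' @export
recovery_experiment <- function(hyper = default_hyperparams(), S = 23L,
                                config = task_config(), seed = 1L, ...) {
  cohort <- simulate_cohort(hyper, S, config, seed = seed)
  data <- bjm_data(cohort$sessions, cohort$connectivity)
  fit <- bjm_fit(data, seed = seed + 1L, ...)
  sm <- summary(fit)
  truth <- c(setNames(hyper$mu, paste0("mu_", names(hyper$mu))),
             setNames(hyper$sds, paste0("sd_", names(hyper$sds))),
             hyper$rhos,
             mu_alpha0 = hyper$mu_alpha0, sd_alpha0 = hyper$sd_alpha0,
             mu_alpha1 = hyper$mu_alpha1, sd_alpha1 = hyper$sd_alpha1,
             sigma1 = hyper$sigma1, sigma2 = hyper$sigma2)
  sm <- sm[sm$parameter %in% names(truth), , drop = FALSE]
  tr <- truth[sm$parameter]
  report <- data.frame(
    parameter = sm$parameter, truth = unname(tr), mean = sm$mean,
    lower = sm$lower, upper = sm$upper, rhat = sm$rhat,
    covered = tr >= sm$lower & tr <= sm$upper,
    norm_error = (sm$mean - tr) / pmax(sm$upper - sm$lower, 1e-12),
    row.names = NULL)
  list(report = report, fit = fit, cohort = cohort)
}
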