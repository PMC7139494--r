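## MCMC fitting of the joint posterior.
##
## Adaptive random-walk Metropolis-within-Gibbs.  Subject-level
## parameters are conditionally independent across subjects given the
## population level, so each of the six subject-level components is
## proposed and accepted for all subjects at once; population-level
## parameters are updated one scalar at a time.  Proposal scales adapt
## toward a 0.44 acceptance rate during warmup (Robbins-Monro) and are
## frozen afterwards.  Support violations (negative gamma/beta,
## non-positive scales, correlations outside (-1,1), non-positive-
## definite covariance) reject the proposal via a -Inf log-ratio.

.HYPER_NAMES <- c("mu_gamma", "mu_beta", "mu_delta1", "mu_delta2",
                  "sd_gamma", "sd_beta", "sd_delta1", "sd_delta2",
                  "rho1", "rho2", "rho3", "rho4",
                  "sigma_alpha", "sigma1", "sigma2",
                  "mu_alpha0", "sd_alpha0", "mu_alpha1", "sd_alpha1")

## vectorised multivariate-t log density given a cached Cholesky factor
mvt_ll_cached <- function(th4, mu, Rchol, nu) {
  z <- backsolve(Rchol, t(th4) - mu, transpose = TRUE)
  qf <- colSums(z^2)
  lgamma((nu + 4) / 2) - lgamma(nu / 2) - 2 * log(nu * pi) -
    sum(log(diag(Rchol))) - (nu + 4) / 2 * log1p(qf / nu)
}

## closed-form sum of normal log densities of cached logit-FA values
fa_ll <- function(delta, sigma, n, sm, ssq) {
  -0.5 * n * log(2 * pi) - n * log(sigma) -
    (ssq - 2 * delta * sm + n * delta^2) / (2 * sigma^2)
}

## data-driven initial values, jittered per chain
bjm_init <- function(data, nu, jitter = 0.1) {
  S <- length(data$subject_ids)
  th <- matrix(NA_real_, S, 6L,
               dimnames = list(NULL, c(.COG_NAMES, "alpha0", "alpha1")))
  for (s in seq_len(S)) {
    ses <- data$sessions[[s]]
    sv <- vapply(ses$trials, `[[`, integer(1), "s")
    nv <- vapply(ses$trials, `[[`, integer(1), "n")
    np <- vapply(ses$trials, `[[`, integer(1), "n_pumps")
    cbar <- min(max(sum(sv) / max(sum(nv), 1L), 0.2), 0.99)
    omega <- max(mean(np), 0.5) + 0.5
    th[s, "alpha0"] <- qlogis(cbar) * exp(rnorm(1, 0, jitter / 2))
    th[s, "alpha1"] <- rnorm(1, 0, 0.002)
    th[s, "gamma"] <- omega * (-log(cbar)) * exp(rnorm(1, 0, jitter))
    th[s, "beta"] <- exp(rnorm(1, 0, jitter))
    for (nx in 1:2) {
      lf <- data$fa_logit[[nx]][[s]]
      th[s, paste0("delta", nx)] <-
        (if (length(lf)) mean(lf) else 0) + rnorm(1, 0, jitter / 2)
    }
  }
  pooled_sd <- function(nx) {
    r <- unlist(lapply(data$fa_logit[[nx]], function(lf)
      if (length(lf) > 1L) lf - mean(lf) else numeric(0)))
    max(sd(r), 0.05)
  }
  mu0 <- colMeans(th[, .COG_NAMES, drop = FALSE])
  mu0[1:2] <- pmax(mu0[1:2], 0.05)      # gamma/beta hyper-means are >= 0
  hy <- list(
    mu = setNames(mu0, .COG_NAMES),
    sds = setNames(pmax(apply(th[, .COG_NAMES, drop = FALSE], 2L, sd),
                        0.05), .COG_NAMES),
    rhos = setNames(rep(0, 4L), .RHO_NAMES),
    nu = nu,
    sigma_alpha = 20 * exp(rnorm(1, 0, jitter)),
    sigma1 = pooled_sd(1L), sigma2 = pooled_sd(2L),
    mu_alpha0 = mean(th[, "alpha0"]),
    sd_alpha0 = max(sd(th[, "alpha0"]), 0.05),
    mu_alpha1 = 0, sd_alpha1 = 0.005)
  list(th = th, hy = hy)
}

#' Fit the joint neuro-behavioural model
#'
#' Samples the joint posterior of all subject-level cognitive and neural
#' parameters and the population-level hyperparameters with an adaptive
#' Metropolis-within-Gibbs scheme.  Runs are reproducible: the same
#' `seed` and configuration give identical draws.
#'
#' @param data a [bjm_data()] cohort.
#' @param chains number of chains, `>= 2`.
#' @param iter post-warmup iterations per chain.
#' @param warmup adaptation iterations discarded from the output.
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed integer seed.
#' @param nu Student-t degrees of freedom (fixed tuning parameter).
#' @param priors a [bjm_priors()] object.
#' @param hyper_sweeps population-level update sweeps per iteration
#'   (they are cheap; extra sweeps improve mixing of the hierarchy).
#' @param progress print a note at the start of each chain.
#' @return an object of class `bjm_fit`: per-chain draw matrices (one
#'   column per scalar parameter plus the unnormalised log posterior
#'   `lp__`), the data, and a `meta` list recording the full sampling
#'   configuration.
#' @seealso [summary.bjm_fit()], [rhat()], [posterior_predictive()]
#' @export
bjm_fit <- function(data, chains = 4L, iter = 2000L, warmup = 1000L,
                    thin = 1L, seed = 1L, nu = 4, priors = bjm_priors(),
                    hyper_sweeps = 2L, progress = FALSE) {
  stopifnot(inherits(data, "bjm_data"))
  if (chains < 2L) stop_invalid("at least 2 chains are required")
  if (iter < 1L || warmup < 0L || thin < 1L) stop_invalid("bad iteration plan")
  S <- length(data$subject_ids)
  compiled <- data$compiled

  ## cached logit-FA sufficient statistics per network
  fa_n <- fa_sm <- fa_ssq <- vector("list", 2L)
  for (nx in 1:2) {
    fa_n[[nx]] <- vapply(data$fa_logit[[nx]], length, integer(1))
    fa_sm[[nx]] <- vapply(data$fa_logit[[nx]], sum, numeric(1))
    fa_ssq[[nx]] <- vapply(data$fa_logit[[nx]], function(x) sum(x^2), numeric(1))
  }

  param_names <- c(.HYPER_NAMES,
                   paste0(rep(c(.COG_NAMES, "alpha0", "alpha1"), each = S),
                          "[", rep(seq_len(S), 6L), "]"))
  n_keep <- floor(iter / thin)
  draws <- vector("list", chains)
  accept <- vector("list", chains)

  set.seed(as.integer(seed))
  chain_seeds <- sample.int(.Machine$integer.max, chains)

  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    if (progress)
      message(sprintf("chain %d/%d (seed %d)", ch, chains, chain_seeds[ch]))
    init <- bjm_init(data, nu)
    th <- init$th
    hy <- init$hy

    ## --- caches -------------------------------------------------------
    Sigma <- build_covariance(hy$sds, hy$rhos)
    Rchol <- chol(Sigma)
    ll_act <- cohort_action_loglik_cpp(compiled, th[, "gamma"], th[, "beta"],
                                       th[, "alpha0"], th[, "alpha1"])
    ll_csr <- cohort_csr_loglik_cpp(compiled, th[, "alpha0"], th[, "alpha1"],
                                    hy$sigma_alpha)
    ll_fa1 <- fa_ll(th[, "delta1"], hy$sigma1, fa_n[[1]], fa_sm[[1]], fa_ssq[[1]])
    ll_fa2 <- fa_ll(th[, "delta2"], hy$sigma2, fa_n[[2]], fa_sm[[2]], fa_ssq[[2]])
    ll_mvt <- mvt_ll_cached(th[, .COG_NAMES, drop = FALSE], hy$mu, Rchol, nu)
    lp_a0 <- dnorm(th[, "alpha0"], hy$mu_alpha0, hy$sd_alpha0, log = TRUE)
    lp_a1 <- dnorm(th[, "alpha1"], hy$mu_alpha1, hy$sd_alpha1, log = TRUE)
    lp_total <- function() {
      hp <- hyper_log_prior(hy, priors)
      sum(ll_act) + sum(ll_csr) + sum(ll_fa1) + sum(ll_fa2) + sum(ll_mvt) +
        sum(lp_a0) + sum(lp_a1) + hp
    }
    if (!is.finite(lp_total()))
      stop_invalid(paste0(
        "initialization error: non-finite initial log posterior ",
        "(check session/connectivity validity and prior settings)"))

    ## --- adaptive step sizes ------------------------------------------
    ls_sub <- matrix(log(c(0.10, 0.20, 0.10, 0.10, 0.10, 0.003)),
                     S, 6L, byrow = TRUE)
    colnames(ls_sub) <- c(.COG_NAMES, "alpha0", "alpha1")
    ls_hyp <- setNames(log(c(0.05, 0.08, 0.06, 0.06,
                             0.05, 0.06, 0.05, 0.05,
                             0.15, 0.15, 0.15, 0.15,
                             0.20, 0.05, 0.05,
                             0.08, 0.05, 0.002, 0.001)), .HYPER_NAMES)
    target_acc <- 0.44
    n_acc_sub <- matrix(0, S, 6L, dimnames = dimnames(ls_sub))
    n_acc_hyp <- setNames(numeric(length(.HYPER_NAMES)), .HYPER_NAMES)

    out <- matrix(NA_real_, n_keep, length(param_names) + 1L,
                  dimnames = list(NULL, c(param_names, "lp__")))
    keep_row <- 0L
    total_iter <- warmup + iter

    for (t in seq_len(total_iter)) {
      adapting <- t <= warmup
      rate <- if (adapting) min(0.25, 2 / sqrt(t)) else 0

      ## ---- subject-level vectorised updates --------------------------
      for (cn in c("gamma", "beta", "alpha0", "alpha1", "delta1", "delta2")) {
        cur <- th[, cn]
        prop <- cur + exp(ls_sub[, cn]) * rnorm(S)
        thp <- th; thp[, cn] <- prop
        bad <- if (cn %in% c("gamma", "beta")) prop < 0 else rep(FALSE, S)

        if (cn %in% c("gamma", "beta", "alpha0", "alpha1")) {
          ll_act_p <- cohort_action_loglik_cpp(compiled, thp[, "gamma"],
                                               thp[, "beta"], thp[, "alpha0"],
                                               thp[, "alpha1"])
        } else ll_act_p <- ll_act
        ll_csr_p <- if (cn %in% c("alpha0", "alpha1"))
          cohort_csr_loglik_cpp(compiled, thp[, "alpha0"], thp[, "alpha1"],
                                hy$sigma_alpha) else ll_csr
        ll_mvt_p <- if (cn %in% .COG_NAMES)
          mvt_ll_cached(thp[, .COG_NAMES, drop = FALSE], hy$mu, Rchol, nu)
          else ll_mvt
        ll_fa1_p <- if (cn == "delta1")
          fa_ll(prop, hy$sigma1, fa_n[[1]], fa_sm[[1]], fa_ssq[[1]]) else ll_fa1
        ll_fa2_p <- if (cn == "delta2")
          fa_ll(prop, hy$sigma2, fa_n[[2]], fa_sm[[2]], fa_ssq[[2]]) else ll_fa2
        lp_a0_p <- if (cn == "alpha0")
          dnorm(prop, hy$mu_alpha0, hy$sd_alpha0, log = TRUE) else lp_a0
        lp_a1_p <- if (cn == "alpha1")
          dnorm(prop, hy$mu_alpha1, hy$sd_alpha1, log = TRUE) else lp_a1

        logr <- (ll_act_p - ll_act) + (ll_csr_p - ll_csr) +
          (ll_mvt_p - ll_mvt) + (ll_fa1_p - ll_fa1) + (ll_fa2_p - ll_fa2) +
          (lp_a0_p - lp_a0) + (lp_a1_p - lp_a1)
        logr[bad] <- -Inf
        acc <- log(runif(S)) < logr
        if (any(acc)) {
          th[acc, cn] <- prop[acc]
          ll_act[acc] <- ll_act_p[acc]; ll_csr[acc] <- ll_csr_p[acc]
          ll_mvt[acc] <- ll_mvt_p[acc]
          ll_fa1[acc] <- ll_fa1_p[acc]; ll_fa2[acc] <- ll_fa2_p[acc]
          lp_a0[acc] <- lp_a0_p[acc]; lp_a1[acc] <- lp_a1_p[acc]
        }
        if (adapting)
          ls_sub[, cn] <- ls_sub[, cn] +
            rate * (pmin(1, exp(logr)) - target_acc)
        else n_acc_sub[, cn] <- n_acc_sub[, cn] + acc
      }

      ## ---- population-level scalar updates ---------------------------
      for (sweep in seq_len(hyper_sweeps)) {
        for (hn in .HYPER_NAMES) {
          step <- exp(ls_hyp[[hn]])
          eps <- step * rnorm(1)
          logr <- -Inf
          commit <- NULL

          if (hn %in% paste0("mu_", .COG_NAMES)) {
            j <- match(sub("mu_", "", hn), .COG_NAMES)
            mu_p <- hy$mu; mu_p[j] <- mu_p[j] + eps
            ok <- !(j <= 2L && mu_p[j] < 0)
            if (ok) {
              ll_mvt_p <- mvt_ll_cached(th[, .COG_NAMES, drop = FALSE],
                                        mu_p, Rchol, nu)
              logr <- sum(ll_mvt_p - ll_mvt) +
                dnorm(mu_p[j], 0, priors$mu_loc_sd, log = TRUE) -
                dnorm(hy$mu[j], 0, priors$mu_loc_sd, log = TRUE)
              commit <- function() {
                hy$mu <<- mu_p; ll_mvt <<- ll_mvt_p
              }
            }
          } else if (hn %in% paste0("sd_", .COG_NAMES) || hn %in% .RHO_NAMES) {
            sds_p <- hy$sds; rhos_p <- hy$rhos
            if (startsWith(hn, "sd_")) {
              j <- match(sub("sd_", "", hn), .COG_NAMES)
              sds_p[j] <- sds_p[j] + eps
              ok <- sds_p[j] > 0
              dpr <- if (ok) half_normal_lpdf(sds_p[j], priors$sd_scale) -
                half_normal_lpdf(hy$sds[j], priors$sd_scale) else -Inf
            } else {
              j <- match(hn, .RHO_NAMES)
              rhos_p[j] <- rhos_p[j] + eps
              ok <- abs(rhos_p[j]) < 1
              dpr <- if (ok) 0 else -Inf
            }
            if (ok) {
              Sp <- build_covariance(sds_p, rhos_p, check_pd = FALSE)
              Rp <- try(chol(Sp), silent = TRUE)
              if (!inherits(Rp, "try-error")) {
                ll_mvt_p <- mvt_ll_cached(th[, .COG_NAMES, drop = FALSE],
                                          hy$mu, Rp, nu)
                logr <- sum(ll_mvt_p - ll_mvt) + dpr
                commit <- function() {
                  hy$sds <<- sds_p; hy$rhos <<- rhos_p
                  Rchol <<- Rp; ll_mvt <<- ll_mvt_p
                }
              }
            }
          } else if (hn == "sigma_alpha") {
            sa_p <- hy$sigma_alpha + eps
            if (sa_p > 0) {
              ll_csr_p <- cohort_csr_loglik_cpp(compiled, th[, "alpha0"],
                                                th[, "alpha1"], sa_p)
              logr <- sum(ll_csr_p - ll_csr) +
                half_normal_lpdf(sa_p, priors$sd_scale) -
                half_normal_lpdf(hy$sigma_alpha, priors$sd_scale)
              commit <- function() {
                hy$sigma_alpha <<- sa_p; ll_csr <<- ll_csr_p
              }
            }
          } else if (hn %in% c("sigma1", "sigma2")) {
            nx <- if (hn == "sigma1") 1L else 2L
            sg_p <- hy[[hn]] + eps
            if (sg_p > 0) {
              ll_fa_p <- fa_ll(th[, paste0("delta", nx)], sg_p,
                               fa_n[[nx]], fa_sm[[nx]], fa_ssq[[nx]])
              ll_fa_c <- if (nx == 1L) ll_fa1 else ll_fa2
              logr <- sum(ll_fa_p - ll_fa_c) +
                half_normal_lpdf(sg_p, priors$sd_scale) -
                half_normal_lpdf(hy[[hn]], priors$sd_scale)
              commit <- function() {
                hy[[hn]] <<- sg_p
                if (nx == 1L) ll_fa1 <<- ll_fa_p else ll_fa2 <<- ll_fa_p
              }
            }
          } else {                              # alpha hierarchies
            a <- if (hn %in% c("mu_alpha0", "sd_alpha0")) "alpha0" else "alpha1"
            mu_c <- hy[[paste0("mu_", a)]]; sd_c <- hy[[paste0("sd_", a)]]
            mu_p <- mu_c; sd_p <- sd_c
            if (startsWith(hn, "mu_")) mu_p <- mu_p + eps else sd_p <- sd_p + eps
            if (sd_p > 0) {
              lp_p <- dnorm(th[, a], mu_p, sd_p, log = TRUE)
              lp_c <- if (a == "alpha0") lp_a0 else lp_a1
              pr_sd <- priors$sd_scale
              pr_mu_sd <- if (a == "alpha0") priors$mu_loc_sd else priors$mu_alpha1_sd
              logr <- sum(lp_p - lp_c) +
                dnorm(mu_p, 0, pr_mu_sd, log = TRUE) -
                dnorm(mu_c, 0, pr_mu_sd, log = TRUE) +
                half_normal_lpdf(sd_p, pr_sd) - half_normal_lpdf(sd_c, pr_sd)
              commit <- function() {
                hy[[paste0("mu_", a)]] <<- mu_p
                hy[[paste0("sd_", a)]] <<- sd_p
                if (a == "alpha0") lp_a0 <<- lp_p else lp_a1 <<- lp_p
              }
            }
          }

          acc <- is.finite(logr) && log(runif(1)) < logr
          if (acc) commit()
          if (adapting)
            ls_hyp[[hn]] <- ls_hyp[[hn]] +
              rate * (min(1, exp(logr)) - target_acc)
          else n_acc_hyp[[hn]] <- n_acc_hyp[[hn]] + acc / hyper_sweeps
        }
      }

      ## ---- store -----------------------------------------------------
      if (!adapting && (t - warmup) %% thin == 0L) {
        keep_row <- keep_row + 1L
        hp <- hyper_log_prior(hy, priors)
        lp <- sum(ll_act) + sum(ll_csr) + sum(ll_fa1) + sum(ll_fa2) +
          sum(ll_mvt) + sum(lp_a0) + sum(lp_a1) + hp
        out[keep_row, ] <- c(hy$mu, hy$sds, hy$rhos, hy$sigma_alpha,
                             hy$sigma1, hy$sigma2,
                             hy$mu_alpha0, hy$sd_alpha0,
                             hy$mu_alpha1, hy$sd_alpha1,
                             th[, "gamma"], th[, "beta"],
                             th[, "delta1"], th[, "delta2"],
                             th[, "alpha0"], th[, "alpha1"], lp)
      }
    }
    draws[[ch]] <- out
    accept[[ch]] <- list(subject = n_acc_sub / iter, hyper = n_acc_hyp / iter)
  }

  structure(list(
    draws = draws,
    param_names = param_names,
    subject_ids = data$subject_ids,
    data = data,
    accept = accept,
    meta = list(chains = as.integer(chains), iter = as.integer(iter),
                warmup = as.integer(warmup), thin = as.integer(thin),
                seed = as.integer(seed), nu = nu, priors = priors,
                hyper_sweeps = as.integer(hyper_sweeps),
                chain_seeds = chain_seeds,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "bjm_fit")
}
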