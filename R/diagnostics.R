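## Convergence diagnostics, posterior summaries and posterior
## predictive checks for bjm_fit objects.

#' Gelman-Rubin potential scale reduction (split chains)
#'
#' Each chain is split in half; `R-hat` compares between- and
#' within-chain variance of the resulting half-chains.  Values near 1
#' indicate convergence.
#'
#' @param draws matrix of posterior draws, iterations x chains (at least
#'   2 chains of at least 10 draws).
#' @return scalar `R-hat` (1 for perfectly degenerate but identical
#'   chains).
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop_invalid("at least 2 chains are required")
  n2 <- floor(nrow(draws) / 2L)
  if (n2 < 5L) stop_invalid("at least 10 draws per chain are required")
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(ch)
    cbind(draws[seq_len(n2), ch], draws[n2 + seq_len(n2), ch])))
  m <- ncol(halves); n <- nrow(halves)
  mu_j <- colMeans(halves)
  s2_j <- apply(halves, 2L, var)
  W <- mean(s2_j)
  B <- n * var(mu_j)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## combined post-warmup draws, iterations x chains, for one parameter
par_draws <- function(fit, par) {
  stopifnot(inherits(fit, "bjm_fit"))
  if (!par %in% c(fit$param_names, "lp__"))
    stop_invalid(sprintf("unknown parameter '%s'", par))
  sapply(fit$draws, function(d) d[, par])
}

#' @export
as.matrix.bjm_fit <- function(x, ...) {
  do.call(rbind, x$draws)
}

#' Posterior summary table
#'
#' Posterior mean, central credible interval and split-chain `R-hat` per
#' parameter, mirroring the usual reporting of hierarchical-model fits.
#'
#' @param object a [bjm_fit()].
#' @param pars parameters to summarise; defaults to the population-level
#'   parameters.
#' @param interval the two credible-bound quantiles.  The default is the
#'   central 95% interval `(0.025, 0.975)`; set `c(0.05, 0.975)` to
#'   mimic reporting that pairs a 5% lower with a 97.5% upper quantile.
#' @param ... unused.
#' @return data frame with columns `parameter, mean, lower, upper, rhat`.
#' @export
summary.bjm_fit <- function(object, pars = NULL,
                            interval = c(0.025, 0.975), ...) {
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  if (is.null(pars)) pars <- .HYPER_NAMES
  rows <- lapply(pars, function(p) {
    d <- par_draws(object, p)
    q <- quantile(d, interval, names = FALSE)
    data.frame(parameter = p, mean = mean(d), lower = q[1], upper = q[2],
               rhat = rhat(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.bjm_fit <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Joint BART-FA model fit: %d subjects, %d chains x %d draws (warmup %d, thin %d)\n",
              length(x$subject_ids), m$chains, m$iter, m$warmup, m$thin))
  cat(sprintf("Student-t df nu = %g, seed = %d\n", m$nu, m$seed))
  sm <- summary(x, pars = c("mu_gamma", "mu_beta", "mu_alpha0", "mu_alpha1",
                            .RHO_NAMES))
  sm[, -1] <- round(sm[, -1], 3)
  print(sm, row.names = FALSE)
  invisible(x)
}

#' @export
coef.bjm_fit <- function(object, level = c("population", "subject"), ...) {
  level <- match.arg(level)
  all_draws <- as.matrix(object)
  if (level == "population") {
    colMeans(all_draws[, .HYPER_NAMES, drop = FALSE])
  } else {
    S <- length(object$subject_ids)
    nm <- c(.COG_NAMES, "alpha0", "alpha1")
    out <- sapply(nm, function(p)
      colMeans(all_draws[, paste0(p, "[", seq_len(S), "]"), drop = FALSE]))
    rownames(out) <- object$subject_ids
    out
  }
}

#' Trace plots of posterior draws
#'
#' @param x a [bjm_fit()].
#' @param pars parameters to plot (default: the four hyper-means and the
#'   log posterior).
#' @param ... unused.
#' @export
plot.bjm_fit <- function(x, pars = c("mu_gamma", "mu_beta", "rho2", "lp__"),
                         ...) {
  op <- graphics::par(mfrow = c(length(pars), 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (p in pars) {
    d <- par_draws(x, p)
    graphics::matplot(d, type = "l", lty = 1, ylab = p, xlab = "",
                      main = "")
    graphics::mtext(p, side = 3, line = 0.2, cex = 0.8)
  }
  invisible(x)
}

#' Posterior predictive check of pump behaviour
#'
#' For each subject, draws `n_rep` cognitive-parameter sets from that
#' subject's joint posterior, simulates a full session per draw with the
#' task generator, and compares the observed per-session mean and SD of
#' pumps per trial with the predictive distribution.
#'
#' @param fit a [bjm_fit()].
#' @param n_rep predictive replicates per subject.
#' @param seed optional seed for the replicate simulations.
#' @param config the [task_config()] used for replicate sessions.
#' @param interval central predictive-interval probability bounds.
#' @return a data frame of class `bjm_ppc`: per subject the observed
#'   mean/SD of pumps, the predictive mean of both statistics, the
#'   central predictive interval of the mean, and a coverage flag.
#' @export
posterior_predictive <- function(fit, n_rep = 1000L, seed = NULL,
                                 config = task_config(),
                                 interval = c(0.025, 0.975)) {
  stopifnot(inherits(fit, "bjm_fit"), n_rep >= 1L)
  all_draws <- as.matrix(fit)
  S <- length(fit$subject_ids)
  with_seed(seed, {
    idx <- sample.int(nrow(all_draws), n_rep, replace = n_rep > nrow(all_draws))
    rows <- lapply(seq_len(S), function(s) {
      obs <- vapply(fit$data$sessions[[s]]$trials, `[[`, integer(1), "n_pumps")
      pg <- all_draws[idx, paste0("gamma[", s, "]")]
      pb <- all_draws[idx, paste0("beta[", s, "]")]
      p0 <- all_draws[idx, paste0("alpha0[", s, "]")]
      p1 <- all_draws[idx, paste0("alpha1[", s, "]")]
      stat <- vapply(seq_len(n_rep), function(r) {
        ses <- simulate_session(cognitive_params(pg[r], pb[r], p0[r], p1[r]),
                                config)
        np <- vapply(ses$trials, `[[`, integer(1), "n_pumps")
        c(mean(np), sd(np))
      }, numeric(2))
      qs <- quantile(stat[1, ], interval, names = FALSE)
      data.frame(subject_id = fit$subject_ids[s],
                 observed_mean = mean(obs), observed_sd = sd(obs),
                 pred_mean = mean(stat[1, ]), pred_sd = mean(stat[2, ]),
                 pred_lower = qs[1], pred_upper = qs[2],
                 covered = mean(obs) >= qs[1] & mean(obs) <= qs[2])
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("bjm_ppc", "data.frame")
    out
  })
}

#' @export
print.bjm_ppc <- function(x, ...) {
  cat(sprintf("Posterior predictive check: %d/%d subjects inside the central predictive interval\n",
              sum(x$covered), nrow(x)))
  print.data.frame(cbind(x[1], round(x[-1][-7], 2), covered = x$covered),
                   row.names = FALSE)
  invisible(x)
}

#' @export
plot.bjm_ppc <- function(x, ...) {
  n <- nrow(x)
  graphics::plot(seq_len(n), x$observed_mean, pch = 16,
                 ylim = range(c(x$pred_lower, x$pred_upper, x$observed_mean)),
                 xlab = "subject", ylab = "mean pumps per trial",
                 main = "Posterior predictive check")
  graphics::segments(seq_len(n), x$pred_lower, seq_len(n), x$pred_upper,
                     col = "red")
  graphics::points(seq_len(n) + 0.15, x$pred_mean, col = "red", pch = 1)
  graphics::legend("topright", legend = c("observed", "predictive"),
                   pch = c(16, 1), col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Simulate replicate cohort data from a fitted model
#'
#' `simulate()` draws `nsim` parameter sets from the posterior and
#' generates one full set of replicate sessions per draw.
#'
#' @param object a [bjm_fit()].
#' @param nsim number of replicate cohorts.
#' @param seed optional seed.
#' @param config the [task_config()] for replicate sessions.
#' @param ... unused.
#' @return list of length `nsim`; each element a list of
#'   [bart_session()] objects (one per subject).
#' @export
simulate.bjm_fit <- function(object, nsim = 1L, seed = NULL,
                             config = task_config(), ...) {
  all_draws <- as.matrix(object)
  S <- length(object$subject_ids)
  with_seed(seed, {
    idx <- sample.int(nrow(all_draws), nsim, replace = nsim > nrow(all_draws))
    lapply(idx, function(r) {
      lapply(seq_len(S), function(s) {
        simulate_session(cognitive_params(
          all_draws[r, paste0("gamma[", s, "]")],
          all_draws[r, paste0("beta[", s, "]")],
          all_draws[r, paste0("alpha0[", s, "]")],
          all_draws[r, paste0("alpha1[", s, "]")]), config,
          subject_id = object$subject_ids[s])
      })
    })
  })
}
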