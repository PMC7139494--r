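## The hierarchical joint structure.
##
## Individual-level (gamma, beta, delta1, delta2) share a multivariate
## Student-t prior whose covariance carries the confirmatory structure:
## free cognitive-neural covariances (rho1..rho4), structural zeros
## between the two cognitive parameters and between the two networks.
## alpha0 and alpha1 sit outside the covariance structure with their own
## normal hierarchies.

.COG_NAMES <- c("gamma", "beta", "delta1", "delta2")
.RHO_NAMES <- c("rho1", "rho2", "rho3", "rho4")

#' Population-level parameters of the joint model
#'
#' Bundles the hyper-means and hyper-SDs of the four covarying
#' individual-level parameters, the four free correlations, the fixed
#' Student-t degrees of freedom, the normal hierarchies of `alpha0` and
#' `alpha1`, and the three residual scales (`sigma_alpha` for the Beta
#' success-rate model, `sigma1`/`sigma2` for tract FA noise).
#'
#' @param mu hyper-means `(mu_gamma, mu_beta, mu_delta1, mu_delta2)`;
#'   the first two on the natural (nonnegative) scale.
#' @param sds hyper-SDs of the same four parameters, `> 0`.
#' @param rhos correlations `(rho1, rho2, rho3, rho4)` in (-1, 1):
#'   rho1 = (gamma, delta1), rho2 = (gamma, delta2),
#'   rho3 = (beta, delta1), rho4 = (beta, delta2).
#' @param nu Student-t degrees of freedom, `> 2`; a fixed tuning value,
#'   never sampled.
#' @param mu_alpha0,sd_alpha0 normal hierarchy of the belief intercept.
#' @param mu_alpha1,sd_alpha1 normal hierarchy of the belief slope.
#' @param sigma_alpha Beta concentration of the success-rate model.
#' @param sigma1,sigma2 inter-tract FA SDs (logit scale) of the two
#'   networks.
#' @return an object of class `joint_hyperparams`.
#' @export
joint_hyperparams <- function(mu, sds, rhos, nu = 4,
                              mu_alpha0 = 2.6, sd_alpha0 = 0.3,
                              mu_alpha1 = -0.005, sd_alpha1 = 0.003,
                              sigma_alpha = 40, sigma1 = 0.25, sigma2 = 0.25) {
  mu <- setNames(as.numeric(mu), .COG_NAMES)
  sds <- setNames(as.numeric(sds), .COG_NAMES)
  rhos <- setNames(as.numeric(rhos), .RHO_NAMES)
  check_finite(mu, "mu"); check_finite(sds, "sds"); check_finite(rhos, "rhos")
  if (any(sds <= 0)) stop_invalid("hyper-SDs must be > 0")
  if (any(abs(rhos) >= 1)) stop_invalid("correlations must lie in (-1, 1)")
  if (mu[["gamma"]] < 0 || mu[["beta"]] < 0)
    stop_invalid("mu_gamma and mu_beta must be >= 0")
  if (!is.finite(nu) || nu <= 2)
    stop_invalid("`nu` must be > 2 (finite prior covariance)")
  for (v in c(sd_alpha0, sd_alpha1, sigma_alpha, sigma1, sigma2))
    if (!is.finite(v) || v <= 0) stop_invalid("scale parameters must be > 0")
  structure(list(mu = mu, sds = sds, rhos = rhos, nu = nu,
                 mu_alpha0 = mu_alpha0, sd_alpha0 = sd_alpha0,
                 mu_alpha1 = mu_alpha1, sd_alpha1 = sd_alpha1,
                 sigma_alpha = sigma_alpha, sigma1 = sigma1, sigma2 = sigma2),
            class = "joint_hyperparams")
}

#' Default population parameters of the synthetic cohort
#'
#' The stated world of the generator: moderate risk propensity and high
#' behavioural consistency, a high and slowly decaying success belief, a
#' single negative cognitive-neural correlation (`rho2`, between risk
#' propensity and the cortico-striatal-thalamic network), the others
#' zero.
#'
#' @param ... overrides passed to [joint_hyperparams()].
#' @return a `joint_hyperparams` object.
#' @export
default_hyperparams <- function(...) {
  args <- modifyList(
    list(mu = c(0.45, 1.5, -0.3, -0.1),
         sds = c(0.15, 0.4, 0.3, 0.3),
         rhos = c(0, -0.5, 0, 0),
         nu = 4),
    list(...))
  do.call(joint_hyperparams, args)
}

#' @export
print.joint_hyperparams <- function(x, ...) {
  cat("Joint-model hyperparameters:\n")
  cat("  mu   :", paste(sprintf("%s=%.3f", names(x$mu), x$mu), collapse = "  "), "\n")
  cat("  sds  :", paste(sprintf("%s=%.3f", names(x$sds), x$sds), collapse = "  "), "\n")
  cat("  rhos :", paste(sprintf("%s=%.3f", names(x$rhos), x$rhos), collapse = "  "), "\n")
  cat(sprintf("  nu=%.1f  alpha0~N(%.3f, %.3f)  alpha1~N(%.4f, %.4f)\n",
              x$nu, x$mu_alpha0, x$sd_alpha0, x$mu_alpha1, x$sd_alpha1))
  cat(sprintf("  sigma_alpha=%.1f  sigma1=%.3f  sigma2=%.3f\n",
              x$sigma_alpha, x$sigma1, x$sigma2))
  invisible(x)
}

#' Assemble the structured 4x4 covariance matrix
#'
#' Diagonal `sds^2`; free entries `sd_i * sd_j * rho` between each
#' cognitive parameter and each network location; structural zeros at
#' (gamma, beta) and (delta1, delta2).
#'
#' @param sds 4-vector of SDs `(gamma, beta, delta1, delta2)`, `> 0`.
#' @param rhos 4-vector `(rho1, rho2, rho3, rho4)`, each in (-1, 1).
#' @param check_pd error (class `bartjoint_not_pd`) if the result is not
#'   positive definite; the sampler instead rejects such proposals.
#' @return symmetric 4x4 matrix with dimnames
#'   `gamma, beta, delta1, delta2`.
#' @export
build_covariance <- function(sds, rhos, check_pd = TRUE) {
  check_finite(sds, "sds"); check_finite(rhos, "rhos")
  if (length(sds) != 4L || length(rhos) != 4L)
    stop_invalid("`sds` and `rhos` must have length 4")
  if (any(sds <= 0)) stop_invalid("`sds` must be > 0")
  if (any(abs(rhos) >= 1)) stop_invalid("`rhos` must lie in (-1, 1)")
  S <- diag(sds^2)
  S[1, 3] <- S[3, 1] <- sds[1] * sds[3] * rhos[1]
  S[1, 4] <- S[4, 1] <- sds[1] * sds[4] * rhos[2]
  S[2, 3] <- S[3, 2] <- sds[2] * sds[3] * rhos[3]
  S[2, 4] <- S[4, 2] <- sds[2] * sds[4] * rhos[4]
  dimnames(S) <- list(.COG_NAMES, .COG_NAMES)
  if (check_pd && inherits(try(chol(S), silent = TRUE), "try-error"))
    stop_invalid("covariance matrix is not positive definite",
                 class = "bartjoint_not_pd")
  S
}

#' Multivariate Student-t log-density
#'
#' Standard d-dimensional Student-t with location `mu`, scale matrix
#' `Sigma` and `nu` degrees of freedom.
#'
#' @param x numeric vector of length d, or a matrix with one observation
#'   per row.
#' @param mu location vector.
#' @param Sigma positive-definite scale matrix.
#' @param nu degrees of freedom, `> 0`.
#' @return log-density, one value per observation.
#' @export
mvt_logpdf <- function(x, mu, Sigma, nu) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  d <- length(mu)
  stopifnot(ncol(x) == d, all(dim(Sigma) == d))
  if (!is.finite(nu) || nu <= 0) stop_invalid("`nu` must be > 0")
  R <- try(chol(Sigma), silent = TRUE)
  if (inherits(R, "try-error"))
    stop_invalid("`Sigma` must be positive definite",
                 class = "bartjoint_not_pd")
  z <- backsolve(R, t(x) - mu, transpose = TRUE)   # R' z = (x - mu)
  qf <- colSums(z^2)
  lgamma((nu + d) / 2) - lgamma(nu / 2) - (d / 2) * log(nu * pi) -
    sum(log(diag(R))) - (nu + d) / 2 * log1p(qf / nu)
}

#' Weakly informative hyperpriors
#'
#' Normal priors on the hyper-means (truncated at zero for `mu_gamma`
#' and `mu_beta`, tighter for the belief slope `mu_alpha1`), half-normal
#' priors on every scale parameter, and uniform(-1, 1) priors on the
#' correlations subject to positive definiteness of the assembled
#' covariance.
#'
#' @param mu_loc_sd SD of the normal prior on `mu_gamma`, `mu_beta`,
#'   `mu_delta1`, `mu_delta2` and `mu_alpha0`.
#' @param mu_alpha1_sd SD of the normal prior on `mu_alpha1`.
#' @param sd_scale scale of the half-normal prior on all SD-type
#'   parameters (`sds`, `sd_alpha0`, `sd_alpha1`, `sigma_alpha`,
#'   `sigma1`, `sigma2`).
#' @return an object of class `bjm_priors`.
#' @export
bjm_priors <- function(mu_loc_sd = 10, mu_alpha1_sd = 1, sd_scale = 5) {
  for (v in c(mu_loc_sd, mu_alpha1_sd, sd_scale))
    if (!is.finite(v) || v <= 0) stop_invalid("prior scales must be > 0")
  structure(list(mu_loc_sd = mu_loc_sd, mu_alpha1_sd = mu_alpha1_sd,
                 sd_scale = sd_scale),
            class = "bjm_priors")
}

half_normal_lpdf <- function(x, scale) {
  ifelse(x > 0, log(2) + dnorm(x, 0, scale, log = TRUE), -Inf)
}

## Log hyperprior; -Inf outside support (incl. non-PD covariance).
hyper_log_prior <- function(hyper, priors) {
  mu <- hyper$mu
  if (mu[["gamma"]] < 0 || mu[["beta"]] < 0) return(-Inf)
  if (any(hyper$sds <= 0) || any(abs(hyper$rhos) >= 1)) return(-Inf)
  sc <- c(hyper$sd_alpha0, hyper$sd_alpha1, hyper$sigma_alpha,
          hyper$sigma1, hyper$sigma2)
  if (any(sc <= 0)) return(-Inf)
  S <- try(build_covariance(hyper$sds, hyper$rhos), silent = TRUE)
  if (inherits(S, "try-error")) return(-Inf)
  sum(dnorm(mu, 0, priors$mu_loc_sd, log = TRUE)) +
    dnorm(hyper$mu_alpha0, 0, priors$mu_loc_sd, log = TRUE) +
    dnorm(hyper$mu_alpha1, 0, priors$mu_alpha1_sd, log = TRUE) +
    sum(half_normal_lpdf(c(hyper$sds, sc), priors$sd_scale))
}

#' Bundle a cohort of behavioural sessions and connectivity matrices
#'
#' Aligns sessions and matrices by subject, compiles the action streams
#' for the likelihood kernels and extracts each subject's Network-FA
#' vectors (tracts with FA = 0 are dropped from the likelihood with a
#' warning).
#'
#' @param sessions list of [bart_session()] objects.
#' @param connectivity named list of [connectivity_matrix()] objects
#'   (names = subject ids), or `NULL` for a behaviour-only cohort (not
#'   supported by the joint fit).
#' @param networks list of two [network_spec()] objects.
#' @return an object of class `bjm_data`.
#' @export
bjm_data <- function(sessions, connectivity, networks = default_networks()) {
  stopifnot(length(networks) == 2L,
            all(vapply(networks, inherits, logical(1), "network_spec")))
  ids <- vapply(sessions, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop_invalid("duplicated subject ids in sessions")
  if (!setequal(names(connectivity), ids))
    stop_invalid("connectivity subjects must match behavioural subjects")
  connectivity <- connectivity[ids]
  fa <- lapply(seq_along(networks), function(nx) {
    lapply(connectivity, function(F) {
      v <- extract_network_fa(F, networks[[nx]])
      v[v > 0]
    })
  })
  structure(list(
    subject_ids = ids,
    sessions = sessions,
    compiled = lapply(sessions, compile_session),
    connectivity = connectivity,
    networks = networks,
    fa_logit = lapply(fa, function(per_net) lapply(per_net, qlogis))
  ), class = "bjm_data")
}

#' @export
print.bjm_data <- function(x, ...) {
  K <- vapply(x$sessions, `[[`, integer(1), "n_trials")
  cat(sprintf("Joint-model cohort: %d subjects, %s trials each\n",
              length(x$subject_ids),
              if (length(unique(K)) == 1L) K[1] else paste(range(K), collapse = "-")))
  cat(sprintf("Networks: %s (%d tracts), %s (%d tracts)\n",
              x$networks[[1]]$name, nrow(x$networks[[1]]$pairs),
              x$networks[[2]]$name, nrow(x$networks[[2]]$pairs)))
  invisible(x)
}

as_param_matrix <- function(params, S) {
  nm <- c(.COG_NAMES, "alpha0", "alpha1")
  params <- as.matrix(as.data.frame(params))
  if (nrow(params) != S) stop_invalid("one parameter row per subject required")
  if (!all(nm %in% colnames(params)))
    stop_invalid(paste("parameter columns must include:", paste(nm, collapse = ", ")))
  params[, nm, drop = FALSE]
}

#' Unnormalised log joint posterior
#'
#' The sum, over subjects, of the action likelihood, the Beta
#' success-rate likelihood, the two network-FA likelihoods, the
#' multivariate Student-t prior of `(gamma, beta, delta1, delta2)` and
#' the normal priors of `alpha0`/`alpha1`, plus the hyperprior
#' log-densities.  Returns `-Inf` for any support violation (negative
#' `gamma`/`beta`, non-positive scales, non-positive-definite
#' covariance).
#'
#' @param data a [bjm_data()] cohort.
#' @param params subject-level parameters: a data frame or matrix with
#'   one row per subject and columns `gamma, beta, delta1, delta2,
#'   alpha0, alpha1`.
#' @param hyper a [joint_hyperparams()] object (including `sigma_alpha`,
#'   `sigma1`, `sigma2`).
#' @param priors a [bjm_priors()] object.
#' @return scalar log-posterior (up to an additive constant).
#' @export
joint_log_posterior <- function(data, params, hyper, priors = bjm_priors()) {
  stopifnot(inherits(data, "bjm_data"), inherits(hyper, "joint_hyperparams"))
  S <- length(data$subject_ids)
  th <- as_param_matrix(params, S)
  if (any(!is.finite(th))) return(-Inf)
  if (any(th[, "gamma"] < 0) || any(th[, "beta"] < 0)) return(-Inf)
  lp0 <- hyper_log_prior(hyper, priors)
  if (!is.finite(lp0)) return(-Inf)
  Sigma <- build_covariance(hyper$sds, hyper$rhos)
  ll_act <- sum(cohort_action_loglik_cpp(data$compiled, th[, "gamma"],
                                         th[, "beta"], th[, "alpha0"],
                                         th[, "alpha1"]))
  ll_csr <- sum(cohort_csr_loglik_cpp(data$compiled, th[, "alpha0"],
                                      th[, "alpha1"], hyper$sigma_alpha))
  ll_fa <- 0
  for (nx in 1:2) {
    sg <- if (nx == 1L) hyper$sigma1 else hyper$sigma2
    dl <- th[, paste0("delta", nx)]
    for (s in seq_len(S)) {
      lf <- data$fa_logit[[nx]][[s]]
      if (length(lf)) ll_fa <- ll_fa + sum(dnorm(lf, dl[s], sg, log = TRUE))
    }
  }
  lp_mvt <- sum(mvt_logpdf(th[, .COG_NAMES, drop = FALSE], hyper$mu, Sigma,
                           hyper$nu))
  lp_alpha <- sum(dnorm(th[, "alpha0"], hyper$mu_alpha0, hyper$sd_alpha0,
                        log = TRUE)) +
    sum(dnorm(th[, "alpha1"], hyper$mu_alpha1, hyper$sd_alpha1, log = TRUE))
  ll_act + ll_csr + ll_fa + lp_mvt + lp_alpha + lp0
}
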