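test_that("burst schedules are i.i.d. uniform on the configured support", {
  cfg <- task_config()
  expect_identical(cfg$burst_support, 3:9)     # mean 6, SD 2
  b <- burst_schedule(cfg, n = 500, seed = 5)
  expect_true(all(b %in% 3:9))
  expect_identical(burst_schedule(cfg, n = 500, seed = 5), b)
  # degenerate support is a point mass
  expect_true(all(burst_schedule(task_config(burst_support = c(5, 5)),
                                 n = 50, seed = 1) == 5L))
  expect_error(task_config(burst_support = integer(0)), "positive integers")
})

test_that("the agent's sessions follow the pump-target rule", {
  # zero risk propensity with a consistent agent: immediate cash
  ses <- simulate_session(cognitive_params(0, 50, 2.6, 0), seed = 9)
  expect_true(all(vapply(ses$trials, `[[`, integer(1), "n_pumps") == 0L))
  expect_true(all(!vapply(ses$trials, `[[`, logical(1), "burst")))

  # deterministic limit: beta huge, omega = 3.4 -> exactly 3 pumps + cash
  a0 <- qlogis(0.8)
  g <- -3.4 * log(0.8)
  ses <- simulate_session(cognitive_params(g, 1e6, a0, 0), seed = 10,
                          burst_thresholds = rep(9L, 36L))
  expect_true(all(vapply(ses$trials, `[[`, integer(1), "n_pumps") == 3L))
  expect_true(all(vapply(ses$trials, function(t) t$actions[4], integer(1)) == 0L))

  # mean pumps increases with gamma (Monte-Carlo)
  mp <- function(gamma, seed) {
    mean(vapply(1:40, function(i) {
      s <- simulate_session(cognitive_params(gamma, 1.5, 2.6, 0),
                            seed = seed + i)
      mean(vapply(s$trials, `[[`, integer(1), "n_pumps"))
    }, numeric(1)))
  }
  expect_gt(mp(0.9, 1000), mp(0.3, 2000))
})

test_that("network FA generator is a logit-normal sampler", {
  v <- simulate_network_fa(-0.3, 1e-8, 10, seed = 2)
  expect_equal(v, rep(plogis(-0.3), 10), tolerance = 1e-6)
  v <- simulate_network_fa(0, 0.5, 4001, seed = 3)
  expect_true(all(v > 0 & v < 1))
  expect_equal(median(v), 0.5, tolerance = 0.03)
  expect_equal(mean(qlogis(v)), 0, tolerance = 3 * 0.5 / sqrt(4001))
})

test_that("cohort generator honours the hierarchy and its shapes", {
  co <- simulate_cohort(default_hyperparams(), S = 5, seed = 77)
  expect_length(co$sessions, 5L)
  expect_length(co$connectivity, 5L)
  expect_true(all(vapply(co$sessions, `[[`, integer(1), "n_trials") == 36L))
  expect_s3_class(co$connectivity[[1]], "connectivity_matrix")
  expect_identical(co$truth$params$subject_id, names(co$connectivity))

  # degenerate hierarchy: everyone at the hyper-means
  hy0 <- default_hyperparams(sds = rep(1e-9, 4), sd_alpha0 = 1e-9,
                             sd_alpha1 = 1e-9)
  co0 <- simulate_cohort(hy0, S = 4, seed = 5)
  expect_equal(co0$truth$params$gamma, rep(0.45, 4), tolerance = 1e-6)
  expect_equal(co0$truth$params$beta, rep(1.5, 4), tolerance = 1e-6)
  expect_equal(co0$truth$params$alpha0, rep(2.6, 4), tolerance = 1e-6)
})

test_that("simulated cognitive-neural correlation matches rho2", {
  hy <- default_hyperparams()
  S <- build_covariance(hy$sds, hy$rhos)
  # near-Gaussian df: the t correlation is rho2 up to sampling error
  set.seed(88)
  xg <- bartjoint:::rmvt_truncated(10000, hy$mu, S, nu = 100)
  expect_equal(cor(xg[, "gamma"], xg[, "delta2"]), -0.5, tolerance = 0.03 / 0.5)
  # heavy tails (nu = 4) plus zero-truncation attenuate the Pearson
  # estimate slightly; it must stay close and strongly negative
  x <- bartjoint:::rmvt_truncated(10000, hy$mu, S, hy$nu)
  expect_equal(cor(x[, "gamma"], x[, "delta2"]), -0.5, tolerance = 0.06 / 0.5)
  expect_lt(abs(cor(x[, "gamma"], x[, "beta"])), 0.05)
  expect_true(all(x[, "gamma"] >= 0) && all(x[, "beta"] >= 0))
})

test_that("the generative model is self-consistent under the action likelihood", {
  set.seed(99)
  p_true <- cognitive_params(0.5, 1.5, 2.6, -0.005)
  p_pert <- cognitive_params(0.75, 1.5, 2.6, -0.005)   # gamma + 50%
  diffs <- vapply(1:100, function(i) {
    ses <- simulate_session(p_true, config = task_config(n_trials = 12L))
    action_loglik(ses, p_true) - action_loglik(ses, p_pert)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("recovery experiment bookkeeping is faithful", {
  hy <- default_hyperparams()
  rec <- recovery_experiment(hy, S = 4, config = task_config(n_trials = 10L),
                             seed = 3, chains = 2, iter = 100, warmup = 100)
  rep <- rec$report
  expect_identical(rep$truth[rep$parameter == "mu_gamma"], 0.45)
  expect_identical(rep$truth[rep$parameter == "rho2"], -0.5)
  expect_true(is.logical(rep$covered))
  expect_identical(nrow(rep), 18L)    # 4 mu + 4 sd + 4 rho + 2 sigma + 4 alpha
  expect_true(all(rep$lower <= rep$upper))
})
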