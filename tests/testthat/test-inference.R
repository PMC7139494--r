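# Small-scale sampler checks; the full-scale recovery protocol lives in
# test-acceptance.R.

smoke_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- tiny_cohort(S = 4L, seed = 61L, n_trials = 12L)
      d <- bjm_data(co$sessions, co$connectivity)
      cache <<- list(fit = bjm_fit(d, chains = 2, iter = 150, warmup = 150,
                                   seed = 8), data = d, cohort = co)
    }
    cache
  }
})

test_that("split-chain R-hat matches the textbook formula", {
  set.seed(12)
  draws <- matrix(rnorm(400), 100, 4)
  expect_equal(rhat(draws), oracle_rhat(draws), tolerance = 1e-10)
  # identical chains: no between-chain variance beyond the split floor
  one <- rnorm(100)
  expect_equal(rhat(cbind(one, one, one)), oracle_rhat(cbind(one, one, one)),
               tolerance = 1e-10)
  expect_equal(rhat(cbind(one, one, one)), 1, tolerance = 0.02)
  # far-offset chains must be flagged
  expect_gt(rhat(cbind(one, one + 50)), 5)
  expect_error(rhat(matrix(rnorm(100), 100, 1)), "2 chains")
  expect_error(rhat(matrix(rnorm(8), 4, 2)), "10 draws")
})

test_that("posterior summaries have the reported shape and quantiles", {
  sf <- smoke_fit()
  sm <- summary(sf$fit)
  expect_identical(sm$parameter, bartjoint:::.HYPER_NAMES)
  expect_true(all(sm$lower <= sm$upper))
  expect_true(all(sm$lower <= sm$mean & sm$mean <= sm$upper))
  sm2 <- summary(sf$fit, pars = c("mu_gamma", "rho2"),
                 interval = c(0.05, 0.975))
  expect_identical(nrow(sm2), 2L)
  expect_true(all(sm2$lower >= sm[sm$parameter %in% sm2$parameter, "lower"]))

  # degenerate and standard-normal draws through the same machinery
  fake <- function(draws) structure(list(draws = draws, param_names = "x"),
                                    class = "bjm_fit")
  const <- fake(list(matrix(2, 50, 1, dimnames = list(NULL, "x")),
                     matrix(2, 50, 1, dimnames = list(NULL, "x"))))
  smc <- summary(const, pars = "x")
  expect_equal(smc$mean, 2)
  expect_equal(c(smc$lower, smc$upper), c(2, 2))
  set.seed(99)
  std <- fake(list(matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "x")),
                   matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "x"))))
  sms <- summary(std, pars = "x")
  expect_equal(c(sms$lower, sms$upper), c(-1.96, 1.96), tolerance = 0.03)
})

test_that("fits are seed-reproducible and respect parameter support", {
  sf <- smoke_fit()
  co <- sf$cohort
  f2 <- bjm_fit(sf$data, chains = 2, iter = 150, warmup = 150, seed = 8)
  expect_identical(sf$fit$draws, f2$draws)
  f3 <- bjm_fit(sf$data, chains = 2, iter = 150, warmup = 150, seed = 9)
  expect_false(identical(sf$fit$draws, f3$draws))

  all_draws <- as.matrix(sf$fit)
  expect_identical(nrow(all_draws), 300L)
  gcols <- grep("^(gamma|beta)\\[", colnames(all_draws))
  expect_true(all(all_draws[, gcols] >= 0))
  rcols <- paste0("rho", 1:4)
  expect_true(all(abs(all_draws[, rcols]) < 1))
  sdcols <- c(paste0("sd_", c("gamma", "beta", "delta1", "delta2")),
              "sigma_alpha", "sigma1", "sigma2", "sd_alpha0", "sd_alpha1")
  expect_true(all(all_draws[, sdcols] > 0))
  expect_true(all(is.finite(all_draws[, "lp__"])))
  expect_error(bjm_fit(sf$data, chains = 1), "2 chains")
})

test_that("model methods expose coefficients and predictive simulations", {
  sf <- smoke_fit()
  cm <- coef(sf$fit)
  expect_named(cm, bartjoint:::.HYPER_NAMES)
  cs <- coef(sf$fit, "subject")
  expect_identical(rownames(cs), sf$fit$subject_ids)
  expect_identical(colnames(cs), c("gamma", "beta", "delta1", "delta2",
                                   "alpha0", "alpha1"))
  sims <- simulate(sf$fit, nsim = 2, seed = 4,
                   config = task_config(n_trials = 12L))
  expect_length(sims, 2L)
  expect_length(sims[[1]], 4L)
  expect_s3_class(sims[[1]][[1]], "bart_session")
})

test_that("posterior predictive table reports observed statistics unchanged", {
  sf <- smoke_fit()
  ppc <- posterior_predictive(sf$fit, n_rep = 30, seed = 2,
                              config = task_config(n_trials = 12L))
  expect_identical(nrow(ppc), 4L)
  obs <- vapply(sf$data$sessions, function(s)
    mean(vapply(s$trials, `[[`, integer(1), "n_pumps")), numeric(1))
  expect_equal(ppc$observed_mean, unname(obs))
  expect_true(all(ppc$pred_lower <= ppc$pred_upper))
  expect_identical(posterior_predictive(sf$fit, n_rep = 30, seed = 2,
                                        config = task_config(n_trials = 12L)),
                   ppc)
})
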