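test_that("burst-belief trend and its complement behave as specified", {
  # logit-inverse at zero, constancy when the slope is zero
  expect_identical(burst_belief_mean(0, 0, 5), 0.5)
  expect_equal(burst_belief_mean(1.2, 0, 1:30), rep(plogis(1.2), 30))
  # hand evaluation of logit^-1(2.653 - 0.004)
  expect_equal(burst_belief_mean(2.653, -0.004, 1), 0.93394, tolerance = 1e-4)
  expect_error(burst_belief_mean(NA, 0, 1), "finite")
  expect_error(burst_belief_mean(0, 0, 0), ">= 1")

  expect_identical(subjective_burst_prob(0.5), 0.5)
  expect_equal(subjective_burst_prob(0.9342), 0.0658)
  eps <- 1e-9
  expect_equal(subjective_burst_prob(1 - eps), eps)
  expect_error(subjective_burst_prob(1), "strictly")

  # alpha1 < 0 makes the belief strictly decreasing in k
  mu <- burst_belief_mean(2.6, -0.01, 1:36)
  expect_true(all(diff(mu) < 0))
  expect_true(all(diff(subjective_burst_prob(mu)) > 0))
})

test_that("pump-target rule is a shrunken linear function of risk propensity", {
  expect_identical(optimal_pumps(0, 0.3), 0)
  # -0.442 / log(1 - 0.0658), high-precision scalar evaluation
  expect_equal(optimal_pumps(0.442, 0.0658), 6.49397, tolerance = 1e-4)
  # p* -> 1 collapses the target toward zero (log term diverges)
  expect_lt(optimal_pumps(2, 1 - 1e-12), 0.1)
  expect_gt(optimal_pumps(2, 0.5), optimal_pumps(2, 1 - 1e-12))
  # linear in gamma at fixed p*
  g <- runif(20, 0, 3)
  expect_equal(optimal_pumps(g, 0.2), g * optimal_pumps(1, 0.2))
  # monotone decreasing in p*
  expect_true(all(diff(optimal_pumps(1, seq(0.05, 0.95, 0.05))) < 0))
  expect_error(optimal_pumps(-1, 0.3), ">= 0")
  expect_error(optimal_pumps(1, 0), "strictly")
})

test_that("pump probability is a logistic decay centred at the target", {
  expect_identical(pump_probability(3.7, 3.7, 2.2), 0.5)
  expect_equal(pump_probability(1:10, 4, 0), rep(0.5, 10))
  expect_equal(pump_probability(1, 6.49, 1.471), 0.99969, tolerance = 1e-4)
  th <- pump_probability(1:12, 5, 0.8)
  expect_true(all(diff(th) < 0))
})

test_that("cumulative success rate counts prior trials only", {
  s1 <- make_session(4, FALSE)             # 4 pumps then cash
  s1 <- make_session(c(4, 2), c(FALSE, FALSE))
  expect_identical(cumulative_success_rate(s1, 2), 1)
  s2 <- make_session(c(5, 2), c(TRUE, FALSE))  # burst on 5th pump
  expect_identical(cumulative_success_rate(s2, 2), 4 / 5)
  expect_error(cumulative_success_rate(s2, 1), "empty history")
  expect_error(cumulative_success_rate(s2, 3), "exceeds")
})

test_that("session constructor enforces the action-sequence invariants", {
  expect_error(bart_session("x", list(list(actions = c(1, 0, 1), burst = FALSE))),
               "exactly one cash")
  expect_error(bart_session("x", list(list(actions = c(1, 0), burst = TRUE))),
               "only pumps")
  expect_error(bart_session("x", list(list(actions = integer(0), burst = FALSE))),
               "non-empty")
  ses <- make_session(c(3, 5), c(FALSE, TRUE))
  expect_identical(vapply(ses$trials, `[[`, integer(1), "n_pumps"), c(3L, 5L))
  expect_identical(vapply(ses$trials, `[[`, integer(1), "s"), c(3L, 4L))
  expect_identical(vapply(ses$trials, `[[`, integer(1), "n"), c(3L, 5L))
})

test_that("action likelihood matches a brute-force double loop", {
  expect_identical(action_loglik(bart_session("e", list()),
                                 cognitive_params(1, 1, 2, 0)), 0)
  # one trial [1, 1, 0]: per-action summation by hand
  p <- cognitive_params(0.6, 1.2, 2.2, -0.01)
  ses1 <- make_session(2, FALSE)
  mu <- plogis(2.2 - 0.01)
  om <- -0.6 / log(mu)
  th <- plogis(-1.2 * (1:3 - om))
  expect_equal(action_loglik(ses1, p),
               log(th[1]) + log(th[2]) + log(1 - th[3]), tolerance = 1e-12)

  set.seed(101)
  for (i in 1:100) {
    ses <- random_session(sample(2:8, 1))
    pp <- random_params()
    expect_equal(action_loglik(ses, pp), oracle_action_loglik(ses, pp),
                 tolerance = 1e-10)
    expect_lte(action_loglik(ses, pp), 0)   # product of probabilities
  }
})

test_that("Beta success-rate likelihood matches independent density evaluation", {
  p <- cognitive_params(1, 1, 0, 0)
  expect_identical(beta_success_loglik(make_session(3, FALSE), 2, 0, 10), 0)
  # single usable C_2 = 0.8 with matched mean: log Beta(8, 2) at 0.8
  ses <- make_session(c(5, 3), c(TRUE, FALSE))
  a0 <- qlogis(0.8)
  expect_equal(beta_success_loglik(ses, a0, 0, 10),
               dbeta(0.8, 8, 2, log = TRUE), tolerance = 1e-10)
  expect_error(beta_success_loglik(ses, a0, 0, 0), "> 0")

  set.seed(202)
  for (i in 1:50) {
    ses <- random_session(sample(3:9, 1))
    a0 <- runif(1, 0.5, 3); a1 <- runif(1, -0.05, 0.05)
    sa <- runif(1, 2, 60)
    expect_equal(beta_success_loglik(ses, a0, a1, sa),
                 oracle_csr_loglik(ses, a0, a1, sa), tolerance = 1e-9)
  }
})

test_that("success-rate likelihood peaks near the logit mean success rate", {
  set.seed(7)
  ses <- random_session(20)
  cks <- vapply(2:20, function(k) cumulative_success_rate(ses, k), numeric(1))
  cks <- pmin(pmax(cks, 1e-3), 1 - 1e-3)
  opt <- optimize(function(a0) beta_success_loglik(ses, a0, 0, 50),
                  c(-4, 6), maximum = TRUE)
  # the exact maximiser, from an independent 1-D numerical oracle
  opt_oracle <- optimize(function(a0) oracle_csr_loglik(ses, a0, 0, 50),
                         c(-4, 6), maximum = TRUE)
  expect_equal(opt$maximum, opt_oracle$maximum, tolerance = 1e-6)
  # and it sits near the logit mean success rate (digamma-vs-log gap
  # at concentration 50 keeps them within ~0.2)
  expect_equal(opt$maximum, mean(qlogis(cks)), tolerance = 0.1)
})

test_that("earnings bookkeeping pays per pump and forfeits on burst", {
  ses <- make_session(c(4, 6, 2), c(FALSE, TRUE, FALSE))
  e <- session_earnings(ses)
  expect_equal(as.numeric(e), c(100, 0, 50))
  expect_equal(attr(e, "total"), 150)
})
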