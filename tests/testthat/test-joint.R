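test_that("structured covariance has the confirmatory zero pattern", {
  S <- build_covariance(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_equal(S, diag(c(1, 4, 9, 16)), ignore_attr = TRUE)
  S <- build_covariance(c(0.5, 1, 0.8, 1.2), c(0.3, -0.5, 0.2, 0.1))
  expect_identical(S, t(S))
  expect_identical(S["gamma", "beta"], 0)       # structural zeros
  expect_identical(S["delta1", "delta2"], 0)
  expect_equal(S["gamma", "delta1"], 0.5 * 0.8 * 0.3)
  expect_equal(S["gamma", "delta2"], 0.5 * 1.2 * -0.5)
  expect_equal(S["beta", "delta1"], 1 * 0.8 * 0.2)
  expect_equal(S["beta", "delta2"], 1 * 1.2 * 0.1)

  # positive definiteness decided by the smallest eigenvalue
  sds <- rep(1, 4); rhos <- rep(0.9, 4)
  Sfree <- diag(4)
  Sfree[1, 3] <- Sfree[3, 1] <- rhos[1]; Sfree[1, 4] <- Sfree[4, 1] <- rhos[2]
  Sfree[2, 3] <- Sfree[3, 2] <- rhos[3]; Sfree[2, 4] <- Sfree[4, 2] <- rhos[4]
  pd <- min(eigen(Sfree, symmetric = TRUE)$values) > 0
  if (pd) expect_silent(build_covariance(sds, rhos))
  else expect_error(build_covariance(sds, rhos), class = "bartjoint_not_pd")
})

test_that("multivariate-t log density: closed-form centre, oracle, Gaussian limit", {
  mu <- c(0.4, 1.5, -0.3, -0.1)
  S <- build_covariance(c(0.2, 0.4, 0.3, 0.3), c(0.1, -0.5, 0, 0.2))
  nu <- 4
  centre <- lgamma((nu + 4) / 2) - lgamma(nu / 2) - 2 * log(nu * pi) -
    0.5 * determinant(S, logarithm = TRUE)$modulus[1]
  expect_equal(mvt_logpdf(mu, mu, S, nu), centre, tolerance = 1e-12,
               ignore_attr = TRUE)

  set.seed(55)
  for (i in 1:30) {
    x <- mu + rnorm(4)
    expect_equal(mvt_logpdf(x, mu, S, nu), oracle_mvt_logpdf(x, mu, S, nu),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }

  # nu -> large recovers the multivariate normal log density
  x <- c(0.6, 1.1, 0.2, -0.5)
  gauss <- -2 * log(2 * pi) -
    0.5 * determinant(S, logarithm = TRUE)$modulus[1] -
    0.5 * drop(t(x - mu) %*% solve(S) %*% (x - mu))
  expect_equal(mvt_logpdf(x, mu, S, 1e6), gauss, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_error(mvt_logpdf(x, mu, matrix(0, 4, 4), 4),
               class = "bartjoint_not_pd")
})

test_that("bivariate-t density integrates to one on a coarse grid", {
  S2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  g <- seq(-30, 30, by = 0.06)
  xy <- expand.grid(g, g)
  dens <- exp(mvt_logpdf(as.matrix(xy), c(0, 0), S2, nu = 5))
  expect_equal(sum(dens) * 0.06^2, 1, tolerance = 0.01)
})

test_that("joint log posterior is the sum of its parts and respects support", {
  co <- tiny_cohort(S = 3L, seed = 21L)
  d <- bjm_data(co$sessions, co$connectivity)
  hy <- co$truth$hyper
  th <- co$truth$params[-1]
  lp <- joint_log_posterior(d, th, hy)
  expect_true(is.finite(lp))

  # additivity: dropping a subject removes exactly its contribution
  d2 <- bjm_data(co$sessions[-3], co$connectivity[-3])
  lp2 <- joint_log_posterior(d2, th[-3, ], hy)
  S <- build_covariance(hy$sds, hy$rhos)
  contrib <- action_loglik(co$sessions[[3]],
                           cognitive_params(th$gamma[3], th$beta[3],
                                            th$alpha0[3], th$alpha1[3])) +
    beta_success_loglik(co$sessions[[3]], th$alpha0[3], th$alpha1[3],
                        hy$sigma_alpha) +
    network_fa_loglik(d$fa_logit[[1]][[3]] |> plogis(), th$delta1[3], hy$sigma1) +
    network_fa_loglik(d$fa_logit[[2]][[3]] |> plogis(), th$delta2[3], hy$sigma2) +
    mvt_logpdf(unlist(th[3, 1:4]), hy$mu, S, hy$nu) +
    dnorm(th$alpha0[3], hy$mu_alpha0, hy$sd_alpha0, log = TRUE) +
    dnorm(th$alpha1[3], hy$mu_alpha1, hy$sd_alpha1, log = TRUE)
  expect_equal(lp - lp2, contrib, tolerance = 1e-9, ignore_attr = TRUE)

  thbad <- th; thbad$gamma[1] <- -0.1
  expect_identical(joint_log_posterior(d, thbad, hy), -Inf)
  thbad <- th; thbad$beta[2] <- -1
  expect_identical(joint_log_posterior(d, thbad, hy), -Inf)
})

test_that("hyperparameter container validates its support", {
  expect_error(default_hyperparams(nu = 2), "> 2")
  expect_error(default_hyperparams(sds = c(0.1, -1, 0.3, 0.3)), "> 0")
  expect_error(default_hyperparams(rhos = c(0, 1, 0, 0)), "\\(-1, 1\\)")
  expect_error(default_hyperparams(mu = c(-0.1, 1.5, 0, 0)), ">= 0")
  hy <- default_hyperparams()
  expect_equal(unname(hy$mu), c(0.45, 1.5, -0.3, -0.1))
  expect_equal(unname(hy$rhos), c(0, -0.5, 0, 0))
})
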