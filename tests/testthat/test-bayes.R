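test_that("gamma prior kernel matches textbook gamma log-densities", {
  set.seed(21)
  for (rep in 1:5) {
    a <- runif(4, 0.5, 3); b <- runif(4, 0.5, 3)
    th <- runif(4, 0.2, 4)
    prior <- tihlb_prior(a, b)
    oracle <- sum(stats::dgamma(th, shape = b, rate = a, log = TRUE)) -
      sum(b * log(a) - lgamma(b))          # drop the normalizers
    expect_equal(log_prior(th, prior), oracle, tolerance = 1e-12)
  }
})

test_that("shape-1 priors reduce to exponential kernels", {
  prior <- tihlb_prior(a = c(1, 2, 3, 4), b = rep(1, 4))
  th <- c(0.5, 1, 1.5, 2)
  expect_equal(log_prior(th, prior), -sum(c(1, 2, 3, 4) * th))
  expect_equal(log_prior(rep(1, 4), tihlb_prior(rep(1, 4), rep(1, 4))), -4)
  expect_identical(log_prior(c(-1, 1, 1, 1), prior), -Inf)
})

test_that("log-posterior is exactly loglik plus log-prior", {
  x <- rtihlbw(30, 1.2, 0.5, 1.5, 1.5, seed = 22)
  prior <- elicit_priors(c(1.2, 0.5, 1.5, 1.5), 2)
  th <- c(1.1, 0.6, 1.4, 1.6)
  expect_identical(log_posterior(th, x, prior),
                   tihlbw_loglik(x, th[1], th[2], th[3], th[4]) +
                     log_prior(th, prior))
  ## near-flat prior: posterior minus likelihood is constant in theta
  flat <- tihlb_prior(a = rep(1e-8, 4), b = rep(1, 4))
  d1 <- log_posterior(th, x, flat) - tihlbw_loglik(x, th[1], th[2], th[3], th[4])
  th2 <- c(2, 1.5, 0.8, 0.9)
  d2 <- log_posterior(th2, x, flat) -
    tihlbw_loglik(x, th2[1], th2[2], th2[3], th2[4])
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("prior elicitation centres on the truth with the stated variance", {
  th <- c(1.2, 0.5, 1.5, 1.5)
  pr2 <- elicit_priors(th, 2)
  expect_equal(pr2$b / pr2$a, th, tolerance = 1e-12)
  ## gamma variance b/a^2 = theta / concentration; scales as 1/concentration
  pr4 <- elicit_priors(th, 4)
  pr1 <- elicit_priors(th, 1)
  expect_equal(pr4$b / pr4$a^2, (pr1$b / pr1$a^2) / 4, tolerance = 1e-12)
  expect_error(elicit_priors(th, -1), "positive")
})

test_that("the sampler is deterministic under a fixed seed", {
  x <- rtihlbw(40, 1.2, 0.5, 1.5, 1.5, seed = 23)
  prior <- elicit_priors(c(1.2, 0.5, 1.5, 1.5), 2)
  p1 <- sample_posterior(x, prior, n_iter = 800, burn_in = 200, seed = 6,
                         start = c(1.2, 0.5, 1.5, 1.5))
  p2 <- sample_posterior(x, prior, n_iter = 800, burn_in = 200, seed = 6,
                         start = c(1.2, 0.5, 1.5, 1.5))
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$self_estimate, colMeans(p1$draws))
  expect_true(all(p1$draws > 0))
})

test_that("posterior recovers the truth within 3 posterior SDs at n = 200", {
  truth <- c(1.2, 0.5, 1.5, 1.5)
  x <- rtihlbw(200, truth[1], truth[2], truth[3], truth[4], seed = 99)
  post <- sample_posterior(x, elicit_priors(truth, 2), n_iter = 6000,
                           burn_in = 1500, seed = 7, start = truth)
  z <- abs(post$self_estimate - truth) / post$posterior_sd
  expect_true(all(z < 3))
  expect_true(all(post$acceptance_rate > 0.15 & post$acceptance_rate < 0.6))
})

test_that("an extremely tight prior dominates the posterior", {
  truth <- c(1.2, 0.5, 1.5, 1.5)
  x <- rtihlbw(60, truth[1], truth[2], truth[3], truth[4], seed = 24)
  tight <- tihlb_prior(a = rep(5000, 4), b = 5000 * truth)
  post <- sample_posterior(x, tight, n_iter = 3000, burn_in = 800, seed = 8,
                           start = truth)
  expect_equal(unname(post$self_estimate), truth, tolerance = 0.05)
})

test_that("with a constant likelihood the sampler recovers the prior", {
  ## detailed-balance smoke test on the internal chain kernel
  prior <- elicit_priors(c(1.2, 0.5, 1.5, 1.5), 2)
  set.seed(25)
  res <- tihlbw:::mwg_chain(function(th) log_prior(th, prior),
                            start = c(1.2, 0.5, 1.5, 1.5),
                            n_iter = 30000, burn_in = 5000, thin = 1,
                            proposal_sd = rep(0.5, 4))
  pm <- colMeans(res$draws)
  pv <- apply(res$draws, 2, var)
  expect_equal(unname(pm), c(1.2, 0.5, 1.5, 1.5), tolerance = 0.12)
  expect_equal(unname(pv), c(1.2, 0.5, 1.5, 1.5) / 2, tolerance = 0.25)
})

test_that("non-finite starting posterior is reported with guidance", {
  x <- rtihlbw(30, 1.2, 0.5, 1.5, 1.5, seed = 26)
  prior <- elicit_priors(c(1.2, 0.5, 1.5, 1.5), 2)
  expect_error(sample_posterior(x, prior, n_iter = 500, burn_in = 100,
                                start = c(1e9, 1e9, 1e9, 1e9)),
               "start")
})

test_that("Heidelberger-Welch diagnostic calibrates under the null", {
  pass <- vapply(1:20, function(s) {
    set.seed(s)
    hw_diagnostic(rnorm(5000))$stationarity
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("Heidelberger-Welch diagnostic detects a linear drift", {
  fails <- vapply(1:10, function(s) {
    set.seed(s)
    y <- rnorm(5000)
    y <- y + seq(0, 3 * sd(y), length.out = 5000)
    !hw_diagnostic(y)$stationarity
  }, logical(1))
  expect_gte(mean(fails), 0.8)
})

test_that("degenerate and short chains are handled", {
  out <- hw_diagnostic(rep(2.5, 500))
  expect_true(out$stationarity)
  expect_true(out$halfwidth_passed)
  expect_identical(out$halfwidth, 0)
  expect_error(hw_diagnostic(rnorm(50)), "short")
})
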