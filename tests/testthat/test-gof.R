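test_that("KS distance equals 0.5/n in the equioscillation case", {
  n <- 8
  u <- (seq_len(n) - 0.5) / n
  expect_equal(ks_statistic(u, cdf = identity), 0.5 / n, tolerance = 1e-14)
})

test_that("KS distance matches a dense grid search over |F_n - F|", {
  pr <- tihlbw_params(1.2, 0.5, 1.5, 1.5)
  x <- rtihlb(23, pr, seed = 31)
  d <- ks_statistic(x, pr)
  grid <- seq(1e-4, max(x) * 2, length.out = 1e6)
  Fn <- stats::ecdf(x)
  d_grid <- max(abs(Fn(grid) - ptihlb(grid, pr)))
  expect_lt(abs(d - d_grid), 1e-6)
})

test_that("Cramer-von Mises attains its 1/(12n) lower bound and matches quadrature", {
  n <- 10
  u <- (2 * seq_len(n) - 1) / (2 * n)
  expect_equal(cvm_statistic(u, cdf = identity), 1 / (12 * n),
               tolerance = 1e-14)
  ## integral definition: W^2 = n * int (F_n(F^-1(t)) - t)^2 dt
  pr <- tihlbw_params(1.2, 0.5, 1.5, 1.5)
  x <- rtihlb(17, pr, seed = 32)
  uu <- sort(ptihlb(x, pr))
  Fn <- stats::ecdf(uu)
  quad <- 17 * integrate(function(t) (Fn(t) - t)^2, 0, 1,
                         subdivisions = 2000L, rel.tol = 1e-12)$value
  expect_equal(cvm_statistic(x, pr), quad, tolerance = 1e-8)
})

test_that("Anderson-Darling matches its integral definition", {
  pr <- tihlbw_params(1.2, 0.5, 1.5, 1.5)
  x <- rtihlb(15, pr, seed = 33)
  uu <- sort(ptihlb(x, pr))
  Fn <- stats::ecdf(uu)
  quad <- 15 * integrate(function(t) (Fn(t) - t)^2 / (t * (1 - t)), 0, 1,
                         subdivisions = 5000L, rel.tol = 1e-10)$value
  expect_equal(ad_statistic(x, pr), quad, tolerance = 1e-6)
})

test_that("A^2 on a large calibrated uniform sample sits at its null scale", {
  set.seed(34)
  a2 <- ad_statistic(runif(2000), cdf = identity)
  expect_gt(a2, 0.1)      # null mean of A^2 is 1; sanity band, not exact
  expect_lt(a2, 5)
})

test_that("statistics are invariant to sample reordering and to the PIT", {
  pr <- tihlbw_params(1.2, 0.5, 1.5, 1.5)
  x <- rtihlb(25, pr, seed = 35)
  xs <- sample(x)
  expect_identical(ks_statistic(x, pr), ks_statistic(xs, pr))
  expect_identical(cvm_statistic(x, pr), cvm_statistic(xs, pr))
  expect_identical(ad_statistic(x, pr), ad_statistic(xs, pr))
  u <- ptihlb(x, pr)
  expect_equal(ks_statistic(u, cdf = identity), ks_statistic(x, pr),
               tolerance = 1e-14)
  expect_equal(cvm_statistic(u, cdf = identity), cvm_statistic(x, pr),
               tolerance = 1e-14)
  expect_equal(ad_statistic(u, cdf = identity), ad_statistic(x, pr),
               tolerance = 1e-12)
})

test_that("exact KS p-value agrees with the order-statistic polytope volume", {
  for (n in 1:5) {
    for (d in c(0.25, 0.4, 0.6, 0.8)) {
      expect_equal(ks_pvalue(d, n), 1 - ks_cdf_polytope(d, n),
                   tolerance = 1e-8,
                   info = sprintf("n=%d d=%g", n, d))
    }
  }
})

test_that("exact KS p-value agrees with stats::ks.test", {
  set.seed(36)
  for (n in c(10, 37, 80)) {
    u <- runif(n)
    kt <- suppressWarnings(stats::ks.test(u, "punif", exact = TRUE))
    expect_equal(ks_pvalue(unname(kt$statistic), n), kt$p.value,
                 tolerance = 1e-10)
  }
  ## asymptotic convention above n = 100
  u <- runif(150)
  kt <- suppressWarnings(stats::ks.test(u, "punif", exact = FALSE))
  expect_equal(ks_pvalue(unname(kt$statistic), 150), kt$p.value,
               tolerance = 1e-7)
})

test_that("KS p-value is 1 at d = 0 and decreases in d", {
  expect_identical(ks_pvalue(0, 30), 1)
  ds <- seq(0.02, 0.5, by = 0.02)
  ps <- vapply(ds, ks_pvalue, numeric(1), n = 30)
  expect_true(all(diff(ps) <= 0))
  expect_error(ks_pvalue(1.5, 10), "0, 1")
  expect_error(ks_pvalue(0.1, 0), "positive")
})

test_that("gof_report bundles the statistics consistently", {
  pr <- tihlbw_params(1.2, 0.5, 1.5, 1.5)
  x <- rtihlb(30, pr, seed = 37)
  g <- gof_report(x, pr, model = "tihlbw")
  expect_equal(g$ksd, ks_statistic(x, pr))
  expect_equal(g$ks_pvalue, ks_pvalue(g$ksd, 30))
  expect_equal(g$cvmv, cvm_statistic(x, pr))
  expect_equal(g$adv, ad_statistic(x, pr))
  expect_identical(g$n, 30L)
  expect_gte(g$cvmv, 1 / (12 * 30))
})

test_that("published ranking holds at the published parameter rows (Italy)", {
  it <- load_dataset("italy")$values
  w <- gof_report(it, tihlbw_params(1.1716, 0.8199, 0.5148, 1.8929))
  e <- gof_report(it, tihlb_params(6.0662, 0.5177, "exponential",
                                   1 / 0.7225))
  l <- gof_report(it, tihlb_params(1.4204, 0.4813, "lomax",
                                   c(1.0133, 0.2133)))
  for (stat in c("ksd", "cvmv", "adv")) {
    expect_lt(w[[stat]], e[[stat]])
    expect_lt(w[[stat]], l[[stat]])
  }
  expect_gt(w$ks_pvalue, e$ks_pvalue)
  expect_gt(w$ks_pvalue, l$ks_pvalue)
})
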