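test_that("CDF boundary values and monotonicity hold", {
  pr <- tihlbw_params(1.2, 0.5, 1.5, 1.5)
  expect_equal(ptihlb(0, pr), 0)
  expect_equal(ptihlb(1e6, pr), 1)
  x <- seq(0.01, 5, length.out = 200)
  expect_true(all(diff(ptihlb(x, pr)) >= 0))
  expect_true(all(ptihlb(x, pr) >= 0 & ptihlb(x, pr) <= 1))
  expect_error(ptihlb(-1, pr), "nonnegative")
  expect_error(tihlbw_params(-1, 0.5, 1, 1), "positive")
  expect_error(tihlbw_params(1, 1, 0, 1), "positive")
})

test_that("CDF at published Italy estimates matches quadrature of the density", {
  pr <- tihlbw_params(1.1716, 0.8199, 0.5148, 1.8929)
  quad <- integrate(dtihlb, 0, 0.1, params = pr, rel.tol = 1e-12)$value
  expect_equal(ptihlb(0.1, pr), quad, tolerance = 1e-8)
})

test_that("density normalizes to 1 across a parameter grid", {
  for (pr in param_grid()) {
    val <- integrate(dtihlb, 0, Inf, params = pr, rel.tol = 1e-9,
                     subdivisions = 500L)$value
    expect_equal(val, 1, tolerance = 1e-6)
  }
})

test_that("density equals the numerical derivative of the CDF", {
  set.seed(31)
  for (pr in param_grid()[1:10]) {
    xs <- qtihlb(c(0.15, 0.5, 0.85), pr)
    h <- 1e-6 * pmax(xs, 0.05)
    fd <- (ptihlb(xs + h, pr) - ptihlb(xs - h, pr)) / (2 * h)
    expect_equal(dtihlb(xs, pr), fd, tolerance = 1e-5)
  }
})

test_that("log-density stays finite deep into the upper tail", {
  ## no intermediate overflow up to (well beyond) the 1 - 1e-12 quantile
  pr <- tihlbw_params(1.2, 0.5, 1.5, 1.5)
  xq <- qtihlb(1 - 1e-12, pr)
  expect_true(is.finite(dtihlb(xq, pr, log = TRUE)))
  expect_true(is.finite(ptihlb(xq, pr, log.p = TRUE)))
  expect_identical(dtihlb(1e8, pr), 0)        # beyond numerical support
  expect_identical(ptihlb(1e8, pr), 1)
})

test_that("quantile function is the exact inverse of the CDF", {
  ps <- c(1e-6, 1e-4, 0.01, 0.25, 0.5, 0.75, 0.99, 1 - 1e-4, 1 - 1e-6)
  for (pr in param_grid()) {
    expect_equal(ptihlb(qtihlb(ps, pr), pr), ps, tolerance = 1e-10)
  }
})

test_that("quantile agrees with bisection inversion of the CDF", {
  pr <- tihlbw_params(1.2, 0.5, 1.5, 1.5)
  for (p in c(0.1, 0.5, 0.9)) {
    expect_equal(qtihlb(p, pr), quantile_bisect(p, pr), tolerance = 1e-9)
  }
})

test_that("quantile endpoints and monotonicity behave", {
  pr <- tihlbw_params(1.2, 0.5, 1.5, 1.5)
  expect_identical(qtihlb(0, pr), 0)
  expect_identical(qtihlb(1, pr), Inf)
  ps <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(qtihlb(ps, pr)) >= 0))
  expect_error(qtihlb(1.5, pr), "0, 1")
  expect_error(qtihlb(-0.1, pr), "0, 1")
})

test_that("hazard equals pdf/sf and is nonnegative", {
  for (pr in param_grid()[1:10]) {
    xs <- qtihlb(c(0.05, 0.3, 0.6, 0.9, 0.99), pr)
    direct <- htihlb(xs, pr)
    ratio <- dtihlb(xs, pr) / ptihlb(xs, pr, lower.tail = FALSE)
    expect_equal(direct, ratio, tolerance = 1e-10)
    expect_true(all(direct >= 0))
  }
})

test_that("cumulative hazard matches -log of the survival function", {
  pr <- tihlbw_params(1.2, 0.5, 1.5, 1.5)
  for (x1 in c(0.5, 1.2)) {
    ch <- integrate(htihlb, 0, x1, params = pr, rel.tol = 1e-10)$value
    ## the log-scale survival keeps the comparison meaningful even where
    ## 1 - F underflows
    expect_equal(ch, -ptihlb(x1, pr, lower.tail = FALSE, log.p = TRUE),
                 tolerance = 1e-6)
  }
})

test_that("random generation is reproducible and matches the CDF", {
  pr <- tihlbw_params(1.2, 0.5, 1.5, 1.5)
  expect_identical(rtihlb(10, pr, seed = 42), rtihlb(10, pr, seed = 42))
  x <- rtihlb(5000, pr, seed = 1234)
  ks <- suppressWarnings(stats::ks.test(x, function(t) ptihlb(t, pr)))
  expect_gt(ks$p.value, 0.01)
  ## empirical mean within 3 standard errors of the quadrature mean
  mu <- mean_quadrature(pr)
  expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(length(x)))
  expect_error(rtihlb(0, pr), "positive integer")
})

test_that("exponential baseline coincides with Weibull baseline at beta = 1", {
  pe <- tihlb_params(1.3, 0.8, "exponential", 2.2)
  pw <- tihlbw_params(1.3, 0.8, 1, 2.2)
  x <- c(0.05, 0.3, 0.9, 2)
  expect_equal(ptihlb(x, pe), ptihlb(x, pw), tolerance = 1e-12)
  expect_equal(dtihlb(x, pe), dtihlb(x, pw), tolerance = 1e-12)
  expect_equal(qtihlb(c(0.2, 0.8), pe), qtihlb(c(0.2, 0.8), pw),
               tolerance = 1e-12)
})

test_that("Lomax baseline yields a valid distribution", {
  pl <- tihlb_params(1.2, 0.7, "lomax", c(1.5, 0.8))
  expect_equal(integrate(dtihlb, 0, Inf, params = pl,
                         rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  ps <- c(0.1, 0.5, 0.9)
  expect_equal(ptihlb(qtihlb(ps, pl), pl), ps, tolerance = 1e-10)
})

test_that("larger delta shifts mass toward the origin (CDF increases)", {
  ## empirically verified direction: delta scales the cumulative hazard, so
  ## F is nondecreasing in delta pointwise
  x <- c(0.2, 0.5, 1, 2)
  deltas <- c(0.3, 0.8, 1.5, 3, 5)
  for (lam in c(0.5, 1.5)) {
    F_by_delta <- sapply(deltas, function(d) {
      ptihlb(x, tihlbw_params(lam, 0.7, 1.5, d))
    })
    expect_true(all(apply(F_by_delta, 1, function(r) all(diff(r) >= 0))))
  }
})

test_that("baseline and parameter validation rejects bad input", {
  expect_error(tihlb_baseline("weibull", c(1, -1)), "positive")
  expect_error(tihlb_baseline("weibull", 1), "needs 2")
  expect_error(tihlb_baseline("exponential", c(1, 2)), "needs 1")
  expect_error(tihlb_params(1, 1, "nope", 1))
})
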