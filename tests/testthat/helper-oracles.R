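## Shared fixtures and independent oracles used across the test files.

## a spread of valid parameter sets, each component spanning [0.3, 5]
param_grid <- function() {
  vals <- c(0.3, 0.75, 1.5, 3, 5)
  grid <- list()
  set.seed(420)
  for (i in 1:20) {
    grid[[i]] <- tihlbw_params(sample(vals, 1), sample(vals, 1),
                               sample(vals, 1), sample(vals, 1))
  }
  grid
}

## quantile oracle: bisection on the CDF
quantile_bisect <- function(p, params, lower = 1e-12, upper = 100,
                            tol = 1e-12) {
  f <- function(x) ptihlb(x, params) - p
  stats::uniroot(f, c(lower, upper), tol = tol)$root
}

## mean of the distribution by quadrature
mean_quadrature <- function(params) {
  stats::integrate(function(t) t * dtihlb(t, params), 0, Inf,
                   rel.tol = 1e-10)$value
}

poly_eval <- function(cf, x) sum(cf * x^(seq_along(cf) - 1))
poly_add <- function(cf, c0) { cf[1] <- cf[1] + c0; cf }

## ---- exact one-sample KS CDF by order-statistic polytope volume ----
## P(D_n < d) = n! * Vol{0 <= u_1 <= ... <= u_n <= 1, lo_i <= u_i <= hi_i}
## with lo_i = max(0, i/n - d), hi_i = min(1, (i-1)/n + d).  The volume is
## computed exactly by recursive integration of piecewise polynomials
## (f_i(t) = integral of f_{i-1} from lo_i to min(t, hi_i)); this is fully
## independent of the matrix-power algorithm in the package.
ks_cdf_polytope <- function(d, n) {
  lo <- pmax(0, (1:n) / n - d)
  hi <- pmin(1, (0:(n - 1)) / n + d)
  if (any(lo >= hi)) return(0)
  br <- sort(unique(c(0, 1, lo, hi)))
  K <- length(br) - 1
  eps <- 1e-14
  pp <- replicate(K, c(1), simplify = FALSE)     # f_0 = 1
  for (i in 1:n) {
    anti <- lapply(pp, function(cf) c(0, cf / seq_along(cf)))
    Fpp <- vector("list", K)
    acc <- 0
    Ftot <- NA_real_
    for (k in 1:K) {
      a <- br[k]; b <- br[k + 1]
      if (b <= lo[i] + eps) {
        Fpp[[k]] <- 0
      } else if (a >= hi[i] - eps) {
        Fpp[[k]] <- Ftot
      } else {
        cf <- anti[[k]]
        Fpp[[k]] <- poly_add(cf, acc - poly_eval(cf, a))
        acc <- acc + poly_eval(cf, b) - poly_eval(cf, a)
        if (abs(b - hi[i]) < eps) Ftot <- acc
      }
    }
    pp <- Fpp
  }
  min(max(poly_eval(pp[[K]], 1) * exp(lgamma(n + 1)), 0), 1)
}
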