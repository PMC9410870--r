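## Goodness-of-fit statistics for a fully specified fitted model:
## Kolmogorov-Smirnov distance with (exact or asymptotic) p-value,
## Cramer-von Mises W^2, Anderson-Darling A^2.

pit_values <- function(x, params = NULL, cdf = NULL) {
  u <- if (!is.null(cdf)) cdf(x) else if (!is.null(params)) {
    ptihlb(x, params)
  } else {
    stop("supply 'params' or 'cdf'", call. = FALSE)
  }
  if (any(!is.finite(u))) {
    stop("model CDF returned non-finite values on the sample", call. = FALSE)
  }
  sort(u)
}

#' Goodness-of-fit statistics against a fitted distribution
#'
#' Classical empirical-distribution-function discrepancy measures evaluated
#' at plugged-in parameter values (no estimated-parameter adjustment), with
#' \eqn{u_{(i)} = F(x_{(i)})} on the sorted sample:
#' \deqn{D = \max_i \max\left(i/n - u_{(i)},\; u_{(i)} - (i-1)/n\right),}
#' \deqn{W^2 = \frac{1}{12n} + \sum_i \left(u_{(i)} -
#'   \frac{2i-1}{2n}\right)^2,}
#' \deqn{A^2 = -n - \frac{1}{n}\sum_i (2i-1)\left[\log u_{(i)} +
#'   \log\left(1 - u_{(n+1-i)}\right)\right].}
#' For \eqn{A^2} the \eqn{u_{(i)}} are clamped to
#' \eqn{[10^{-12}, 1 - 10^{-12}]} (with a warning) before taking logs.
#'
#' @param x Numeric sample.
#' @param params A [tihlb_params()] object specifying the fitted model.
#' @param cdf Alternatively, any vectorized CDF function (used instead of
#'   `params`; handy for probability-integral-transform checks).
#' @return The statistic value.
#' @examples
#' pr <- tihlbw_params(1.2, 0.5, 1.5, 1.5)
#' x <- rtihlb(50, pr, seed = 3)
#' ks_statistic(x, pr)
#' cvm_statistic(x, pr)
#' ad_statistic(x, pr)
#' @name gof-statistics
NULL

#' @rdname gof-statistics
#' @export
ks_statistic <- function(x, params = NULL, cdf = NULL) {
  u <- pit_values(x, params, cdf)
  n <- length(u)
  i <- seq_len(n)
  max(pmax(i / n - u, u - (i - 1) / n))
}

#' @rdname gof-statistics
#' @export
cvm_statistic <- function(x, params = NULL, cdf = NULL) {
  u <- pit_values(x, params, cdf)
  n <- length(u)
  i <- seq_len(n)
  1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
}

#' @rdname gof-statistics
#' @export
ad_statistic <- function(x, params = NULL, cdf = NULL) {
  u <- pit_values(x, params, cdf)
  n <- length(u)
  if (any(u < 1e-12) || any(u > 1 - 1e-12)) {
    warning("PIT values clamped to [1e-12, 1 - 1e-12] before logs")
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  }
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log1p(-rev(u))))
}

#' One-sample two-sided Kolmogorov-Smirnov p-value
#'
#' Exact p-value by the Marsaglia-Tsang-Wang matrix-power algorithm for
#' `n <= 100`, and the asymptotic Kolmogorov series
#' \eqn{2\sum_{k\ge1}(-1)^{k-1} e^{-2 k^2 n d^2}} (evaluated in its
#' theta-function form) otherwise - the convention of common statistical
#' software, and the one under which the study tables were produced.
#'
#' @param d Observed KS distance in `[0, 1]`.
#' @param n Sample size.
#' @param exact Logical; force the exact (or asymptotic) routine.
#' @return The p-value \eqn{P(D_n \ge d)}.
#' @examples
#' ks_pvalue(0.0936, 37)
#' @export
ks_pvalue <- function(d, n, exact = n <= 100) {
  if (!is.finite(d) || d < 0 || d > 1) stop("'d' must be in [0, 1]",
                                            call. = FALSE)
  if (!is.finite(n) || n < 1) stop("'n' must be a positive integer",
                                   call. = FALSE)
  if (d == 0) return(1)
  if (d >= 1) return(0)
  if (exact) {
    1 - ks_cdf_exact(d, as.integer(n))
  } else {
    ks_pvalue_asymptotic(d, n)
  }
}

## Marsaglia-Tsang-Wang (2003): P(D_n < d) = n!/n^n (H^n)[k, k] with
## H the (2k-1)x(2k-1) matrix built from h = k - n d, k = ceil(n d).
ks_cdf_exact <- function(d, n) {
  k <- ceiling(n * d)
  h <- k - n * d
  m <- 2L * k - 1L
  H <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i - j + 1 >= 0) H[i, j] <- 1
    }
  }
  for (i in seq_len(m)) {
    H[i, 1] <- H[i, 1] - h^i
    H[m, i] <- H[m, i] - h^(m - i + 1)
  }
  H[m, 1] <- H[m, 1] + if (2 * h - 1 > 0) (2 * h - 1)^m else 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i - j + 1 > 0) {
        H[i, j] <- H[i, j] / prod(seq_len(i - j + 1))
      }
    }
  }
  ## H^n with scaling to avoid overflow; track the power of 10^140 factored
  ## out, then multiply by n!/n^n via logs
  eQ <- 0
  Q <- mat_pow_scaled(H, n)
  P <- Q$mat[k, k]
  eQ <- Q$expo
  lp <- log(P) + eQ * log(1e140) + lgamma(n + 1) - n * log(n)
  min(max(exp(lp), 0), 1)
}

mat_pow_scaled <- function(H, n) {
  if (n == 1) return(list(mat = H, expo = 0))
  half <- mat_pow_scaled(H, n %/% 2)
  M <- half$mat %*% half$mat
  e <- 2 * half$expo
  if (n %% 2 == 1) M <- M %*% H
  mx <- max(abs(M))
  if (mx > 1e140) {
    M <- M / 1e140
    e <- e + 1
  }
  list(mat = M, expo = e)
}

ks_pvalue_asymptotic <- function(d, n) {
  t <- sqrt(n) * d
  if (t < 1) {
    ## theta-function form, rapidly convergent for small t
    z <- -pi^2 / (8 * t^2)
    1 - sqrt(2 * pi) / t * (exp(z) + exp(9 * z) + exp(25 * z) + exp(49 * z))
  } else {
    kk <- 1:25
    2 * sum((-1)^(kk - 1) * exp(-2 * kk^2 * t^2))
  }
}

#' Goodness-of-fit report for a fitted model
#'
#' Bundles the KS distance and p-value, Cramer-von Mises and
#' Anderson-Darling statistics for one model on one sample.
#'
#' @param x Numeric sample of positive values.
#' @param params A [tihlb_params()] object (e.g. from a [fit_tihlb()]
#'   `params_hat`, or constructed from published estimates).
#' @param model Optional label stored in the report.
#' @return An object of class `gof_report`: list with `ksd`, `ks_pvalue`,
#'   `cvmv`, `adv`, `n`, `model`, `params_used`.
#' @examples
#' saudi <- load_dataset("saudi_arabia")
#' gof_report(saudi$values, tihlbw_params(48.1999, 2.1852, 1.4615, 67.4952))
#' @export
gof_report <- function(x, params, model = params$baseline$name) {
  d <- ks_statistic(x, params)
  structure(list(
    ksd = d,
    ks_pvalue = ks_pvalue(d, length(x)),
    cvmv = cvm_statistic(x, params),
    adv = ad_statistic(x, params),
    n = length(x),
    model = model,
    params_used = params
  ), class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("Goodness of fit (%s, n = %d)\n", x$model, x$n))
  cat(sprintf("  KSD: %.4f   p(KS): %.4f   CVMV: %.4f   ADV: %.4f\n",
              x$ksd, x$ks_pvalue, x$cvmv, x$adv))
  invisible(x)
}
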