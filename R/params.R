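#' Parameter set of the TIHLBX-G family
#'
#' Bundles the two family shape parameters \eqn{\lambda > 0} and
#' \eqn{\alpha > 0} with a [tihlb_baseline()] specification.  With the Weibull
#' baseline this is the four-parameter TIHLBW model with canonical parameter
#' order \eqn{(\lambda, \alpha, \beta, \delta)}.
#'
#' @param lambda Type I half logistic shape parameter, \eqn{\lambda > 0}.
#' @param alpha Burr X shape parameter, \eqn{\alpha > 0}.
#' @param baseline A [tihlb_baseline()] object (default: Weibull with
#'   `theta`).
#' @param theta Baseline parameters, used only when `baseline` is given as a
#'   name string.
#' @return An object of class `tihlb_params`.
#' @seealso [tihlbw_params()] for the Weibull special case.
#' @export
tihlb_params <- function(lambda, alpha, baseline = "weibull", theta = NULL) {
  if (!inherits(baseline, "tihlb_baseline")) {
    baseline <- tihlb_baseline(baseline, theta)
  }
  lambda <- as.numeric(lambda)[1]
  alpha <- as.numeric(alpha)[1]
  if (!is.finite(lambda) || lambda <= 0 || !is.finite(alpha) || alpha <= 0) {
    stop("'lambda' and 'alpha' must be finite and strictly positive",
         call. = FALSE)
  }
  structure(list(lambda = lambda, alpha = alpha, baseline = baseline),
            class = "tihlb_params")
}

#' TIHLBW parameter set
#'
#' Convenience constructor for the Weibull-baseline member: parameters
#' \eqn{(\lambda, \alpha, \beta, \delta)} with baseline CDF
#' \eqn{G(x) = 1 - \exp(-\delta x^\beta)}.
#'
#' @param lambda,alpha Family shape parameters (positive).
#' @param beta,delta Weibull baseline shape and rate-like parameters
#'   (positive).
#' @return A `tihlb_params` object.
#' @examples
#' tihlbw_params(1.2, 0.5, 1.5, 1.5)
#' @export
tihlbw_params <- function(lambda, alpha, beta, delta) {
  tihlb_params(lambda, alpha, "weibull", c(beta, delta))
}

#' @export
print.tihlb_params <- function(x, ...) {
  cat(sprintf("<tihlb_params: lambda = %g, alpha = %g, baseline %s (%s)>\n",
              x$lambda, x$alpha, x$baseline$name,
              paste(signif(x$baseline$theta, 6), collapse = ", ")))
  invisible(x)
}

## free-parameter vector <-> params object, used by fitting code.
## canonical order: (lambda, alpha, <baseline theta>)
par_vector <- function(params) {
  c(params$lambda, params$alpha, params$baseline$theta)
}

par_names <- function(model) {
  switch(model,
    tihlbw = c("lambda", "alpha", "beta", "delta"),
    tihlbe = c("lambda", "alpha", "delta"),
    tihlbl = c("lambda", "alpha", "a", "b"),
    stop("unknown model '", model, "'", call. = FALSE)
  )
}

model_baseline <- function(model) {
  switch(model,
    tihlbw = "weibull", tihlbe = "exponential", tihlbl = "lomax",
    stop("unknown model '", model, "'", call. = FALSE)
  )
}

params_from_vector <- function(model, th) {
  tihlb_params(th[1], th[2], model_baseline(model), th[-(1:2)])
}

## flat named list for JSON reports
params_to_list <- function(params) {
  model <- switch(params$baseline$name,
                  weibull = "tihlbw", exponential = "tihlbe", lomax = "tihlbl")
  stats::setNames(as.list(par_vector(params)), par_names(model))
}
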