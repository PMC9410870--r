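Package: tihlbw
Title: Type I Half Logistic Burr X Weibull Distribution for Lifetime Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distribution functions, random generation, maximum-likelihood and
    Bayesian (Metropolis-within-Gibbs) estimation, goodness-of-fit statistics
    (Kolmogorov-Smirnov with exact small-sample p-values, Cramer-von Mises,
    Anderson-Darling) and a Monte Carlo bias/MSE simulation harness for the
    four-parameter type I half logistic Burr X Weibull (TIHLBW) lifetime
    distribution and its parent generated family with pluggable Weibull,
    exponential and Lomax baselines. Includes the COVID-19 daily mortality-rate
    study datasets for Saudi Arabia and Italy and a command-line interface for
    fitting, goodness of fit, sampling and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
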