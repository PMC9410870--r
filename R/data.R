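## Embedded study datasets: daily COVID-19 mortality rates.

saudi_values <- c(
  0.0195, 0.0213, 0.0214, 0.0217, 0.0231, 0.0233, 0.0235, 0.0235, 0.0238,
  0.0239, 0.0245, 0.0260, 0.0264, 0.0268, 0.0270, 0.0271, 0.0275, 0.0278,
  0.0278, 0.0282, 0.0282, 0.0285, 0.0287, 0.0294, 0.0296, 0.0300, 0.0301,
  0.0309, 0.0310, 0.0313, 0.0314, 0.0315, 0.0324, 0.0325, 0.0328, 0.0332,
  0.0358)

italy_values <- c(
  0.0107, 0.0490, 0.0601, 0.0460, 0.0533, 0.0630, 0.0297, 0.0885, 0.0540,
  0.1720, 0.0847, 0.0713, 0.0989, 0.0495, 0.1025, 0.1079, 0.0984, 0.1124,
  0.0807, 0.1044, 0.1212, 0.1167, 0.1255, 0.1416, 0.1315, 0.1073, 0.1629,
  0.1485, 0.1453, 0.2000, 0.2070, 0.1520, 0.1628, 0.1666, 0.1417, 0.1221,
  0.1767, 0.1987, 0.1408, 0.1456, 0.1443, 0.1319, 0.1053, 0.1789, 0.2032,
  0.2167, 0.1387, 0.1646, 0.1375, 0.1421, 0.2012, 0.1957, 0.1297, 0.1754,
  0.1390, 0.1761, 0.1119, 0.1915, 0.1827, 0.1548, 0.1522, 0.1369, 0.2495,
  0.1253, 0.1597, 0.2195, 0.2555, 0.1956, 0.1831, 0.1791, 0.2057, 0.2406,
  0.1227, 0.2196, 0.2641, 0.3067, 0.1749, 0.2148, 0.2195, 0.1993, 0.2421,
  0.2430, 0.1994, 0.1779, 0.0942, 0.3067, 0.1965, 0.2003, 0.1180, 0.1686,
  0.2668, 0.2113, 0.3371, 0.1730, 0.2212, 0.4972, 0.1641, 0.2667, 0.2690,
  0.2321, 0.2792, 0.3515, 0.1398, 0.3436, 0.2254, 0.1302, 0.0864, 0.1619,
  0.1311, 0.1994, 0.3176, 0.1856, 0.1071, 0.1041, 0.1593, 0.0537, 0.1149,
  0.1176, 0.0457, 0.1264, 0.0476, 0.1620, 0.1154, 0.1493, 0.0673, 0.0894,
  0.0365, 0.0385, 0.2190, 0.0777, 0.0561, 0.0435, 0.0372, 0.0385, 0.0769,
  0.1491, 0.0802, 0.0870, 0.0476, 0.0562, 0.0138, 0.0684, 0.1172, 0.0321,
  0.0327, 0.0198, 0.0182, 0.0197, 0.0298, 0.0545, 0.0208, 0.0079, 0.0237,
  0.0169, 0.0336, 0.0755, 0.0263, 0.0260, 0.0150, 0.0054, 0.0375, 0.0043,
  0.0154, 0.0146, 0.0210, 0.0115, 0.0052, 0.2512, 0.0084, 0.0125, 0.0125,
  0.0109, 0.0071)

#' Embedded COVID-19 mortality-rate study datasets
#'
#' Daily COVID-19 mortality rates, as published: `"saudi_arabia"` (37 values,
#' 27 June - 2 August 2021) and `"italy"` (printed listing of 173 values,
#' 1 March - 20 August 2020; the accompanying text says "172 days" but the
#' published series contains 173 numbers, all of which are needed to
#' reproduce the published goodness-of-fit statistics).
#'
#' @param name `"saudi_arabia"` or `"italy"`.
#' @return An object of class `named_dataset`: list with `name`, `values`,
#'   `n` and `provenance`.
#' @examples
#' d <- load_dataset("saudi_arabia")
#' d$n
#' range(d$values)
#' @export
load_dataset <- function(name) {
  sets <- list(
    saudi_arabia = list(
      values = saudi_values,
      provenance = "COVID-19 daily mortality rate, Saudi Arabia, 2021-06-27 to 2021-08-02"),
    italy = list(
      values = italy_values,
      provenance = "COVID-19 daily mortality rate, Italy, 2020-03-01 to 2020-08-20")
  )
  if (length(name) != 1 || !name %in% names(sets)) {
    stop("unknown dataset '", paste(name, collapse = ","),
         "'; available: ", paste(names(sets), collapse = ", "),
         call. = FALSE)
  }
  d <- sets[[name]]
  structure(list(name = name, values = d$values, n = length(d$values),
                 provenance = d$provenance),
            class = "named_dataset")
}

#' @export
print.named_dataset <- function(x, ...) {
  cat(sprintf("<dataset %s: n = %d, range [%.4f, %.4f]>\n  %s\n",
              x$name, x$n, min(x$values), max(x$values), x$provenance))
  invisible(x)
}

#' Read a univariate positive sample from a text file
#'
#' Accepts a one-column CSV or whitespace-delimited text file with one value
#' per row/field; a single non-numeric header line is auto-detected and
#' skipped.  Non-numeric or nonpositive entries are rejected with their line
#' numbers.
#'
#' @param path Path to the file.
#' @param format `"auto"` (default), `"csv"` or `"whitespace"`.
#' @return Numeric vector of positive values, in file order.
#' @examples
#' f <- tempfile()
#' writeLines(c("rate", "0.1", "0.2"), f)
#' read_sample(f)
#' @export
read_sample <- function(path, format = c("auto", "csv", "whitespace")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  sep <- switch(format,
    csv = ",",
    whitespace = "[[:space:]]+",
    auto = if (grepl(",", lines[[1]])) "," else "[[:space:]]+")
  toks_by_line <- lapply(lines, function(l) {
    tok <- strsplit(trimws(l), sep)[[1]]
    tok[nzchar(tok)]
  })
  first <- suppressWarnings(as.numeric(toks_by_line[[1]]))
  start_line <- 1L
  if (any(is.na(first))) {          # header line
    start_line <- 2L
    if (length(lines) < 2) stop("no data after header in ", path,
                                call. = FALSE)
  }
  vals <- numeric(0)
  for (i in seq(start_line, length(lines))) {
    v <- suppressWarnings(as.numeric(toks_by_line[[i]]))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric entry on line %d: '%s'", i, lines[[i]]),
           call. = FALSE)
    }
    if (any(v <= 0)) {
      stop(sprintf("nonpositive value on line %d: '%s'", i, lines[[i]]),
           call. = FALSE)
    }
    vals <- c(vals, v)
  }
  vals
}
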