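#' Annual count series
#'
#' Constructs the validated container for a short annual count series
#' \eqn{x^{(0)}(k)}, \eqn{k = 1, \dots, n}: strictly positive values indexed
#' by consecutive integer labels (years). This is the raw input of the grey
#' model; the multiplicative/exponential structure of the model is why zero
#' or negative counts are rejected, and the Markov layer's uniform annual
#' step is why label gaps are rejected.
#'
#' @param labels integer period identifiers, strictly increasing by 1.
#' @param values strictly positive counts, same length as `labels`, n >= 4.
#' @return An object of class `grey_series`: a list with elements `labels`,
#'   `values` and `n`.
#' @examples
#' grey_series(2001:2004, c(10, 9, 8, 7))
#' @export
grey_series <- function(labels, values) {
  labels <- as.numeric(labels)
  values <- as.numeric(values)
  if (length(labels) != length(values)) {
    stop("`labels` and `values` must have equal length", call. = FALSE)
  }
  n <- length(values)
  if (n < 4) {
    stop(sprintf("series too short: n = %d, need n >= 4", n), call. = FALSE)
  }
  bad <- which(!is.finite(values))
  if (length(bad)) {
    stop(sprintf("non-numeric or missing value at row %d", bad[1]), call. = FALSE)
  }
  bad <- which(values <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive value %g at row %d (label %s): the model is multiplicative",
                 values[bad[1]], bad[1], format(labels[bad[1]])), call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    d <- labels[duplicated(labels)][1]
    stop(sprintf("duplicate label %s", format(d)), call. = FALSE)
  }
  if (any(labels != round(labels))) {
    stop("labels must be integers (years)", call. = FALSE)
  }
  steps <- diff(labels)
  if (any(steps != 1)) {
    bad <- which(steps != 1)[1]
    stop(sprintf("gap in labels between %s and %s: labels must be consecutive",
                 format(labels[bad]), format(labels[bad + 1])), call. = FALSE)
  }
  structure(list(labels = as.integer(labels), values = values, n = n),
            class = "grey_series")
}

#' @export
print.grey_series <- function(x, ...) {
  cat(sprintf("Annual count series: n = %d (%d-%d)\n",
              x$n, x$labels[1], x$labels[x$n]))
  print(stats::setNames(x$values, x$labels))
  invisible(x)
}

#' @export
as.data.frame.grey_series <- function(x, ...) {
  data.frame(label = x$labels, value = x$values)
}

#' @export
length.grey_series <- function(x) x$n

#' Read an annual count series from CSV
#'
#' Expects two columns (label, value), comma-separated, UTF-8, with an
#' optional header (`year,deaths` is the canonical form). Each validation
#' failure names the offending row.
#'
#' @param path path to a CSV file.
#' @param format dialect tag; only `"csv"` is supported.
#' @return A [grey_series].
#' @seealso [write_series()], [load_fixture()]
#' @export
read_series <- function(path, format = "csv") {
  if (!identical(format, "csv")) {
    stop(sprintf("unknown format '%s'; supported: csv", format), call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- !grepl("^\\s*-?[0-9]", first)
  raw <- utils::read.csv(path, header = has_header, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) != 2) {
    stop(sprintf("expected 2 columns (label,value), found %d in %s",
                 ncol(raw), path), call. = FALSE)
  }
  lab <- suppressWarnings(as.numeric(raw[[1]]))
  val <- suppressWarnings(as.numeric(raw[[2]]))
  for (col in list(list(v = lab, name = "label", txt = raw[[1]]),
                   list(v = val, name = "value", txt = raw[[2]]))) {
    bad <- which(is.na(col$v))
    if (length(bad)) {
      stop(sprintf("non-numeric %s '%s' at row %d of %s",
                   col$name, col$txt[bad[1]], bad[1], path), call. = FALSE)
    }
  }
  grey_series(lab, val)
}

#' Write an annual count series to CSV
#'
#' Canonical dialect: `year,deaths` header, comma separator, full-precision
#' values. `read_series()` of the written file round-trips the series.
#'
#' @param series a [grey_series].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "grey_series"))
  lines <- c("year,deaths",
             paste(series$labels, format(series$values, digits = 15, trim = TRUE,
                                         scientific = FALSE),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Mean-generated sequence
#'
#' Consecutive-pair means \eqn{\bar{x}^{(0)}(k) = (x^{(0)}(k) + x^{(0)}(k-1))/2}
#' for \eqn{k = 2, \dots, n}. Averaging adjacent years damps single-year
#' spikes while preserving a geometric ratio exactly, which is what makes
#' the development-coefficient estimator exact on noiseless exponential
#' input.
#'
#' @param series a [grey_series].
#' @return Numeric vector of length n - 1; element i corresponds to k = i + 1.
#' @export
mean_generate <- function(series) {
  stopifnot(inherits(series, "grey_series"))
  v <- series$values
  (v[-1] + v[-series$n]) / 2
}

#' Accumulated generating operation
#'
#' Running sums \eqn{\bar{x}^{(1)}(k) = \sum_{m=2}^{k} \bar{x}^{(0)}(m)} of
#' the mean-generated sequence. The accumulated sequence is the smooth,
#' monotone curve the grey model's exponential response is fitted to.
#'
#' @param mean_generated numeric vector (output of [mean_generate()]).
#' @return Numeric vector of the same length; first entry equals the first
#'   input entry, and consecutive differences reproduce the input exactly.
#' @export
accumulate <- function(mean_generated) {
  if (!length(mean_generated)) stop("empty sequence", call. = FALSE)
  cumsum(mean_generated)
}
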