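#' Serialize a pipeline report
#'
#' `report_to_list()` flattens a [run_pipeline()] report into plain lists
#' and data.frames suitable for JSON. The JSON carries full-precision
#' numbers plus a `display` block with table-style rounding (integer
#' counts, whole-percent ratios, 3-decimal relative errors, 1-decimal
#' decline rate); every displayed number is regenerable from the
#' full-precision block.
#'
#' @param report a `grey_markov_report`.
#' @return A plain nested list.
#' @export
report_to_list <- function(report) {
  p <- report$fit$params
  layers <- lapply(report$stack$layers, function(l) {
    list(order = l$order, type = l$type, a = l$a, b = l$b, M = l$M,
         k0 = l$k0, constant = l$constant,
         signs = as.integer(l$signs),
         extrapolation_sign = as.integer(l$extrapolation_sign))
  })
  p1 <- report$models[[1]]
  list(
    parameters = list(a = p$a, b = p$b, c = p$c, U = p$U, M = p$M,
                      anchor = p$anchor),
    stack = list(layers = layers,
                 stopping = report$stack$stopping),
    state_space = as.data.frame(unclass(report$space)),
    transition = list(step = p1$step,
                      labels = rownames(p1$probs),
                      probs = p1$probs,
                      counts = p1$counts,
                      visits = as.integer(p1$visits)),
    rows = report$rows,
    horizon = report$horizon,
    decline = report$decline,
    display = list(
      rows = .display_rows(report$rows),
      decline_rate_percent = round(report$decline$rate_percent, 1)
    )
  )
}

.display_rows <- function(rows) {
  data.frame(
    label = rows$label,
    actual = rows$actual,
    grey_fitted = round(rows$grey_fitted),
    amended = round(rows$amended),
    ratio_percent = round(100 * rows$ratio),
    state = rows$state,
    adjusted = round(rows$adjusted),
    rel_err_amended = round(rows$rel_err_amended, 3),
    rel_err_adjusted = round(rows$rel_err_adjusted, 3)
  )
}

#' Write a pipeline report
#'
#' `"json"` writes the canonical full-precision serialization, `"csv"` the
#' per-year rows with display rounding, `"text"` a plain-text table in the
#' same layout.
#'
#' @param report a `grey_markov_report`.
#' @param path output file path.
#' @param format one of `"json"`, `"csv"`, `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv", "text")) {
  if (!is.character(format) || !format[1] %in% c("json", "csv", "text")) {
    stop(sprintf("unknown format '%s'; choices: json, csv, text",
                 format[1]), call. = FALSE)
  }
  format <- format[1]
  if (format == "json") {
    jsonlite::write_json(report_to_list(report), path,
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE, dataframe = "rows")
  } else if (format == "csv") {
    utils::write.csv(.display_rows(report$rows), path, row.names = FALSE,
                     na = "")
  } else {
    writeLines(report_text(report), path)
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path path written by [write_report()] with `format = "json"`.
#' @return The nested list produced by [report_to_list()].
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

#' Plain-text report table
#'
#' @param report a `grey_markov_report`.
#' @return Character vector of lines (header, one line per year, horizon
#'   block, decline summary).
#' @export
report_text <- function(report) {
  d <- .display_rows(report$rows)
  p <- report$fit$params
  fmt_row <- function(...) sprintf("%-6s %8s %8s %8s %7s %6s %9s %9s %9s", ...)
  num <- function(x) ifelse(is.na(x), "", format(x))
  lines <- c(
    sprintf("Grey-Markov fit: a = %.6f, b = %.2f, M = %.2f (%d residual layer(s), stop: %s)",
            p$a, p$b, p$M, report$stack$stopping$rounds,
            report$stack$stopping$criterion),
    fmt_row("year", "actual", "grey", "amended", "ratio", "state",
            "adjusted", "err.amd", "err.adj"))
  for (i in seq_len(nrow(d))) {
    lines <- c(lines, fmt_row(
      d$label[i], num(d$actual[i]), num(d$grey_fitted[i]), num(d$amended[i]),
      paste0(d$ratio_percent[i], "%"), d$state[i], num(d$adjusted[i]),
      num(sprintf("%.3f", report$rows$rel_err_amended[i])),
      ifelse(is.na(d$adjusted[i]), "",
             sprintf("%.3f", report$rows$rel_err_adjusted[i]))))
  }
  if (!is.null(report$horizon)) {
    h <- report$horizon
    lines <- c(lines, "", "Forecast (frozen parameters):")
    for (i in seq_len(nrow(h))) {
      lines <- c(lines, sprintf(
        "%-6s amended %8d  state %s [%g, %g]  adjusted %8d",
        h$label[i], round(h$amended[i]), h$predicted_state[i],
        h$band_lower[i], h$band_upper[i], round(h$adjusted[i])))
    }
  }
  dec <- report$decline
  c(lines, "", sprintf(
    "Average decline %d-%d: %.1f%% per year; %d projection: %d",
    dec$window[1], dec$window[2], dec$rate_percent, dec$next_label,
    dec$projected))
}

#' @export
print.grey_markov_report <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}
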