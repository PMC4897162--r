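.fixture_registry <- c(
  china_coal_1990_2010 = "china_coal_1990_2010.csv"
)

.table_registry <- c(
  grey_fit    = "china_coal_published_grey_fit.csv",
  amended     = "china_coal_published_amended.csv",
  holdout     = "china_coal_published_holdout.csv",
  state_bands = "china_coal_state_bands.csv"
)

#' Load a packaged series fixture
#'
#' `"china_coal_1990_2010"` is the 21-year annual death toll of coal-mine
#' accidents in China, 1990-2010, as published by the national coal-mine
#' safety administration. Repeated calls return bit-identical series.
#'
#' @param name registered fixture id.
#' @return A [grey_series].
#' @examples
#' s <- load_fixture("china_coal_1990_2010")
#' s$values[1]   # 7185 deaths in 1990
#' @export
load_fixture <- function(name) {
  if (!name %in% names(.fixture_registry)) {
    stop(sprintf("unknown fixture '%s'; available: %s",
                 name, paste(names(.fixture_registry), collapse = ", ")),
         call. = FALSE)
  }
  path <- system.file("extdata", .fixture_registry[[name]],
                      package = "greymarkov", mustWork = TRUE)
  read_series(path)
}

#' Published case-study tables
#'
#' Plain-text copies of the published case-study tables for the
#' china_coal_1990_2010 fixture, used as reference inputs by the
#' reproduction checks: `"grey_fit"` (actuals and grey-model predictions,
#' 1990-2010), `"amended"` (residual-amended predictions and the
#' actual/prediction ratio in whole percent, 1991-2010), `"holdout"`
#' (2004-2013 actuals with amended and Markov-adjusted predictions and
#' their printed relative errors), and `"state_bands"` (the four ratio-band
#' states used for the Markov layer).
#'
#' @param name one of `"grey_fit"`, `"amended"`, `"holdout"`, `"state_bands"`.
#' @return A data.frame.
#' @export
published_table <- function(name) {
  if (!name %in% names(.table_registry)) {
    stop(sprintf("unknown table '%s'; available: %s",
                 name, paste(names(.table_registry), collapse = ", ")),
         call. = FALSE)
  }
  path <- system.file("extdata", .table_registry[[name]],
                      package = "greymarkov", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
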