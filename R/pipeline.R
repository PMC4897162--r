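#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end fit: residual-iteration control,
#' state division, forecast horizon and the restored-fit exponent anchor.
#'
#' @param tol residual-iteration stop threshold on max |relative deviation|
#'   (default 0.10).
#' @param max_rounds maximum residual layers (default 3).
#' @param state_method `"cluster"`, `"equal_width"` or `"fixed"`.
#' @param m number of states for the non-fixed methods (default 4).
#' @param boundaries explicit band edges (implies `state_method = "fixed"`).
#' @param horizon number of future years to forecast (default 0).
#' @param max_step highest transition step kept for tie-breaking (default 3).
#' @param anchor restored-fit exponent anchor (see [scgm_parameters()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(tol = 0.10, max_rounds = 3,
                            state_method = c("cluster", "equal_width", "fixed"),
                            m = 4, boundaries = NULL, horizon = 0,
                            max_step = 3, anchor = c("k-1", "k")) {
  state_method <- match.arg(state_method)
  anchor <- match.arg(anchor)
  if (!is.null(boundaries)) {
    if (any(diff(boundaries) <= 0)) {
      stop("boundaries must be strictly increasing", call. = FALSE)
    }
    state_method <- "fixed"
  }
  if (horizon < 0) stop("horizon must be >= 0", call. = FALSE)
  structure(list(tol = tol, max_rounds = max_rounds,
                 state_method = state_method, m = m, boundaries = boundaries,
                 horizon = horizon, max_step = max_step, anchor = anchor),
            class = "pipeline_config")
}

#' Run the full grey-Markov pipeline
#'
#' Fits the grey trend, iterates residual corrections, divides the
#' actual/amended ratio into states, estimates the transition matrices,
#' Markov-adjusts each in-sample year from the previous year's state, and
#' (if `horizon > 0`) forecasts future years with frozen parameters. The
#' whole path is deterministic: identical inputs give identical reports.
#'
#' @param series a [grey_series].
#' @param config a [pipeline_config()].
#' @return An object of class `grey_markov_report`: list with `series`,
#'   `config`, `fit`, `stack`, `space`, `path`, `models` (transition models
#'   by step), `rows` (per-year data.frame: label, actual, grey fitted,
#'   amended, ratio, state, adjusted value and absolute relative errors of
#'   each model), `horizon` (future rows, or NULL) and `decline` (mean
#'   year-over-year percent decline of the observed actuals and its
#'   one-step extrapolation).
#' @examples
#' rep <- run_pipeline(load_fixture("china_coal_1990_2010"),
#'                     pipeline_config(horizon = 3))
#' rep$rows[rep$rows$label == 2004, ]
#' @export
run_pipeline <- function(series, config = pipeline_config()) {
  stopifnot(inherits(series, "grey_series"), inherits(config, "pipeline_config"))
  fit <- .stage("scgm_core", scgm_fit(series, anchor = config$anchor))
  stack <- .stage("residual_correction",
                  iterate_corrections(series, fit, config$tol, config$max_rounds))
  k_train <- seq.int(2, series$n)
  amended <- apply_corrections(fit$fitted, stack, k_train)
  diag <- scgm_diagnostics(series, amended)
  ratios <- diag$ratio

  space <- .stage("markov_layer", switch(
    config$state_method,
    fixed = state_space_fixed(config$boundaries),
    divide_states(ratios, m = config$m, method = config$state_method)
  ))
  path <- assign_states(ratios, space)
  n_steps <- min(config$max_step, length(path) - 1)
  models <- lapply(seq_len(n_steps), function(r) transition_model(path, r))

  # in-sample Markov adjustment: year k is adjusted by the state predicted
  # from year k-1's observed state (the first diagnosed year has no
  # predecessor and stays unadjusted)
  adj <- rep(NA_real_, length(k_train))
  pred_state <- rep(NA_integer_, length(k_train))
  for (i in seq_along(k_train)[-1]) {
    st <- predict_state(models, path[i - 1])
    pred_state[i] <- st
    adj[i] <- adjust_forecast(amended[i], st, space)$value
  }
  actual <- series$values[-1]
  rows <- data.frame(
    label = series$labels[-1],
    actual = actual,
    grey_fitted = fit$fitted,
    amended = amended,
    ratio = ratios,
    state = space$label[path],
    predicted_state = ifelse(is.na(pred_state), NA, space$label[pred_state]),
    adjusted = adj,
    rel_err_grey = abs(fit$fitted - actual) / actual,
    rel_err_amended = abs(amended - actual) / actual,
    rel_err_adjusted = abs(adj - actual) / actual
  )

  report <- structure(list(series = series, config = config, fit = fit,
                           stack = stack, space = space, path = path,
                           models = models, rows = rows, horizon = NULL,
                           decline = NULL),
                      class = "grey_markov_report")
  if (config$horizon > 0) {
    report$horizon <- .stage("pipeline", forecast_horizon(report, config$horizon))
  }
  rate <- average_decline_rate(series$values)
  report$decline <- list(
    window = c(series$labels[1], series$labels[series$n]),
    rate_percent = rate,
    next_label = series$labels[series$n] + 1L,
    projected = extrapolate_decline(series$values[series$n], rate)
  )
  report
}

# attach the pipeline stage name to propagated errors
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Forecast future years with frozen parameters
#'
#' Extends the amended fit to k = n+1..n+h via the restored exponential and
#' the stacked residual layers (extrapolation signs), propagates the state
#' chain by repeated one-step prediction from the last observed state, and
#' midpoint-adjusts each year. Nothing is refitted.
#'
#' @param report a [run_pipeline()] report.
#' @param h number of future years, h >= 1.
#' @return A data.frame like the report's `rows` for the future years
#'   (columns: label, amended, predicted_state, interval bounds, adjusted).
#' @export
forecast_horizon <- function(report, h) {
  stopifnot(inherits(report, "grey_markov_report"), h >= 1)
  if (report$fit$params$degenerate) {
    stop("degenerate trend (a ~ 0): refusing to extrapolate", call. = FALSE)
  }
  n <- report$series$n
  k_new <- seq.int(n + 1, n + h)
  base <- restored_fit(report$fit$params, k_new)
  amended <- apply_corrections(base, report$stack, k_new)
  st <- report$path[length(report$path)]
  out <- data.frame(label = report$series$labels[n] + seq_len(h),
                    amended = amended, predicted_state = NA_character_,
                    band_lower = NA_real_, band_upper = NA_real_,
                    adjusted = NA_real_)
  for (i in seq_len(h)) {
    st <- predict_state(report$models, st)
    af <- adjust_forecast(amended[i], st, report$space)
    out$predicted_state[i] <- report$space$label[st]
    out$band_lower[i] <- af$interval[1]
    out$band_upper[i] <- af$interval[2]
    out$adjusted[i] <- af$value
  }
  out
}

#' Average year-over-year percent decline
#'
#' Arithmetic mean of `100 * (1 - v(t)/v(t-1))` over consecutive pairs.
#' Returned at full precision; the report writers round to 1 decimal.
#'
#' @param values positive values in time order, length >= 2.
#' @return Mean decline in percent (negative if the series grows).
#' @examples
#' average_decline_rate(c(100, 50, 25))  # 50
#' @export
average_decline_rate <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 2) stop("need at least 2 values", call. = FALSE)
  if (any(v <= 0)) stop("values must be positive", call. = FALSE)
  mean(100 * (1 - v[-1] / v[-length(v)]))
}

#' One-step decline extrapolation
#'
#' Projects the next count from the last observed value and an average
#' decline rate: `round(last_value * (1 - rate/100))`.
#'
#' @param last_value last observed count.
#' @param rate decline rate in percent (< 100).
#' @return Projected integer count.
#' @export
extrapolate_decline <- function(last_value, rate) {
  if (rate > 100) stop("rate must be <= 100 percent", call. = FALSE)
  round(last_value * (1 - rate / 100))
}
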