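#' Ratio-band state space
#'
#' Divides the fit-ratio indicator \eqn{Y(k)} (actual / predicted) into `m`
#' contiguous interval states \eqn{E_i = [\otimes_{1i}, \otimes_{2i})}.
#'
#' Methods:
#' \describe{
#'   \item{fixed}{explicit `boundaries` (length m + 1, strictly increasing);
#'     `m` is taken from them.}
#'   \item{equal_width}{m equal-width bands covering the observed ratio
#'     range, outer bounds padded outward to whole percents.}
#'   \item{cluster}{contiguity-constrained agglomerative clustering of the
#'     sorted ratios (complete linkage: merge the adjacent pair whose union
#'     spans the least) down to m clusters; interior boundaries at midpoints
#'     between adjacent clusters, outer bounds padded to whole percents.}
#' }
#'
#' @param ratios observed ratio values (dimensionless fractions).
#' @param m number of states (ignored for `fixed`).
#' @param method one of `"cluster"`, `"equal_width"`, `"fixed"`.
#' @param boundaries numeric vector of m + 1 band edges for `fixed`.
#' @return An object of class `state_space`: data.frame with columns
#'   `state` (1..m), `label` (E1..Em), `lower`, `upper`.
#' @examples
#' state_space_fixed(c(0.60, 0.75, 0.90, 1.05, 1.20))
#' @export
divide_states <- function(ratios, m = 4,
                          method = c("cluster", "equal_width", "fixed"),
                          boundaries = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(boundaries)) stop("fixed method needs `boundaries`", call. = FALSE)
    return(state_space_fixed(boundaries))
  }
  ratios <- as.numeric(ratios)
  if (!length(ratios)) stop("ratios must be non-empty", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  distinct <- sort(unique(ratios))
  if (m > length(distinct)) {
    stop(sprintf("m = %d exceeds the %d distinct ratio values",
                 m, length(distinct)), call. = FALSE)
  }
  lo <- floor(min(ratios) * 100) / 100
  hi <- ceiling(max(ratios) * 100) / 100
  if (method == "equal_width") {
    return(state_space_fixed(seq(lo, hi, length.out = m + 1)))
  }
  # contiguity-constrained 1-D agglomeration on the sorted distinct values:
  # repeatedly merge the adjacent cluster pair with the smallest combined
  # range (complete linkage in 1-D)
  clusters <- as.list(distinct)
  while (length(clusters) > m) {
    span <- vapply(seq_len(length(clusters) - 1), function(i) {
      max(clusters[[i + 1]]) - min(clusters[[i]])
    }, numeric(1))
    i <- which.min(span)
    clusters[[i]] <- c(clusters[[i]], clusters[[i + 1]])
    clusters[[i + 1]] <- NULL
  }
  inner <- vapply(seq_len(length(clusters) - 1), function(i) {
    (max(clusters[[i]]) + min(clusters[[i + 1]])) / 2
  }, numeric(1))
  state_space_fixed(c(lo, inner, hi))
}

#' @rdname divide_states
#' @export
state_space_fixed <- function(boundaries) {
  b <- as.numeric(boundaries)
  if (length(b) < 2 || any(diff(b) <= 0)) {
    stop("boundaries must be >= 2 strictly increasing values", call. = FALSE)
  }
  m <- length(b) - 1
  structure(data.frame(state = seq_len(m),
                       label = paste0("E", seq_len(m)),
                       lower = b[-length(b)],
                       upper = b[-1]),
            class = c("state_space", "data.frame"))
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("Ratio-band state space (%d states):\n", nrow(x)))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s: [%.0f%%, %.0f%%%s\n", x$label[i],
                100 * x$lower[i], 100 * x$upper[i],
                if (i == nrow(x)) "]" else ")"))
  }
  invisible(x)
}

#' Assign ratios to states
#'
#' Half-open convention: a ratio belongs to \eqn{E_i} if
#' \eqn{\otimes_{1i} \le Y < \otimes_{2i}}; the top interval is closed.
#' Ratios outside the covered range are clipped to the nearest extreme
#' state with a warning.
#'
#' @param ratios numeric ratio values.
#' @param space a [divide_states()] state space.
#' @return An integer vector of state indices (class `state_path`), with
#'   the space attached as attribute `space`.
#' @export
assign_states <- function(ratios, space) {
  stopifnot(inherits(space, "state_space"))
  b <- c(space$lower, space$upper[nrow(space)])
  s <- findInterval(ratios, b, rightmost.closed = TRUE)
  out_of_range <- s == 0 | s > nrow(space)
  if (any(out_of_range)) {
    warning(sprintf("%d ratio(s) outside [%g, %g] clipped to the extreme states",
                    sum(out_of_range), b[1], b[length(b)]), call. = FALSE)
    s <- pmin(pmax(s, 1L), nrow(space))
  }
  structure(as.integer(s), class = "state_path", space = space)
}

#' r-step transition model
#'
#' Counts all ordered index pairs (k, k + r) along the state path:
#' \eqn{M_{ij}(r)} transitions from \eqn{E_i} to \eqn{E_j}, visit counts
#' \eqn{M_i} (occurrences of \eqn{E_i} with an r-step successor) and the
#' row-normalized probabilities \eqn{P_{ij}(r) = M_{ij}(r)/M_i}. Rows with
#' no visits are undefined (`NA`).
#'
#' @param path integer state path (a [assign_states()] result or plain
#'   vector).
#' @param step transition step r >= 1.
#' @param m number of states (taken from the attached space if present).
#' @return An object of class `transition_model`: list with `step`,
#'   `counts` (m x m), `visits` (length m), `probs` (m x m, rows summing to
#'   1 where defined).
#' @export
transition_model <- function(path, step = 1, m = NULL) {
  if (step <= 0) stop("step must be a positive integer", call. = FALSE)
  s <- as.integer(path)
  if (length(s) <= step) {
    stop(sprintf("path of length %d has no %d-step transitions",
                 length(s), step), call. = FALSE)
  }
  if (is.null(m)) {
    sp <- attr(path, "space")
    m <- if (!is.null(sp)) nrow(sp) else max(s)
  }
  counts <- matrix(0L, m, m, dimnames = list(paste0("E", 1:m), paste0("E", 1:m)))
  from <- s[seq_len(length(s) - step)]
  to <- s[seq_len(length(s) - step) + step]
  for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  visits <- rowSums(counts)
  probs <- counts / visits   # rows with 0 visits become NaN -> NA below
  probs[visits == 0, ] <- NA_real_
  structure(list(step = as.integer(step), counts = counts,
                 visits = visits, probs = probs, m = m),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("%d-step transition probabilities (%d states):\n", x$step, x$m))
  print(round(x$probs, 3))
  invisible(x)
}

#' Predict the next state
#'
#' Takes the argmax of the current state's row of the 1-step matrix. Exact
#' ties are broken by consulting the same row of the higher-step models in
#' order; a remaining tie falls back to the state nearest the current one,
#' then the lower index. An undefined row (state never visited with a
#' successor) falls back to a uniform distribution with a warning.
#'
#' @param models a `transition_model` or list of them, ordered by step.
#' @param current current state index.
#' @return The predicted state index.
#' @export
predict_state <- function(models, current) {
  if (inherits(models, "transition_model")) models <- list(models)
  stopifnot(length(models) >= 1)
  m <- models[[1]]$m
  row <- models[[1]]$probs[current, ]
  if (anyNA(row)) {
    warning(sprintf("state E%d has no observed successors; uniform fallback",
                    current), call. = FALSE)
    row <- rep(1 / m, m)
  }
  cand <- which(row >= max(row) - 1e-12)
  for (mod in models[-1]) {
    if (length(cand) == 1) break
    r2 <- mod$probs[current, ]
    if (anyNA(r2)) next
    r2 <- r2[cand]
    cand <- cand[r2 >= max(r2) - 1e-12]
  }
  if (length(cand) > 1) {
    cand <- cand[order(abs(cand - current), cand)]
  }
  as.integer(unname(cand[1]))
}

#' Midpoint adjustment of a forecast
#'
#' Replaces a point forecast by base times the centre of the predicted
#' state's ratio band: \eqn{Y' = (\otimes_{1i} + \otimes_{2i})/2},
#' \eqn{x' = \hat{x}' \cdot Y'}. The adjusted value always lies inside
#' the band scaled by the base.
#'
#' @param base_value positive base prediction.
#' @param state predicted state index.
#' @param space a [divide_states()] state space.
#' @return An object of class `adjusted_forecast`: list with `base`,
#'   `state`, `interval`, `ratio` (the midpoint), `value` (full precision)
#'   and `value_rounded` (integer counts).
#' @examples
#' af <- adjust_forecast(5433, 4, state_space_fixed(c(.6, .75, .9, 1.05, 1.2)))
#' af$ratio          # 1.125
#' af$value_rounded  # 6112
#' @export
adjust_forecast <- function(base_value, state, space) {
  stopifnot(inherits(space, "state_space"), base_value > 0,
            state >= 1, state <= nrow(space))
  lo <- space$lower[state]
  hi <- space$upper[state]
  mid <- (lo + hi) / 2
  structure(list(base = base_value, state = as.integer(state),
                 interval = c(lo, hi), ratio = mid,
                 value = base_value * mid,
                 value_rounded = round(base_value * mid)),
            class = "adjusted_forecast")
}

#' @export
print.adjusted_forecast <- function(x, ...) {
  cat(sprintf("Markov adjustment: state E%d [%g, %g], Y' = %g\n",
              x$state, x$interval[1], x$interval[2], x$ratio))
  cat(sprintf("  %g x %g = %g (~ %d)\n", x$base, x$ratio, x$value,
              x$value_rounded))
  invisible(x)
}
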