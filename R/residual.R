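#' Residual sequence of a grey fit
#'
#' \eqn{\epsilon(k) = \hat{x}^{(0)}(k) - x^{(0)}(k)} for k = 2..n, named by
#' index k. Positive residuals are overpredictions and are corrected
#' downward; negative residuals upward.
#'
#' @param fit an [scgm_fit] (or anything with a `diagnostics` data.frame).
#' @return Named numeric vector of length n - 1.
#' @export
residual_sequence <- function(fit) {
  d <- fit$diagnostics
  stats::setNames(d$residual, d$k)
}

#' Grey model for residual magnitudes
#'
#' Fits the same grey estimators to the magnitudes of a residual sequence,
#' re-indexed from 1, and records the per-index residual signs. Mixed signs
#' are handled by fitting the magnitudes once and applying each index's own
#' training sign; beyond the training window the sign of the latest nonzero
#' training residual is used.
#'
#' Degenerate inputs degrade gracefully: all-zero residuals yield a no-op
#' layer; constant magnitudes (or magnitudes a grey model cannot represent,
#' e.g. containing zeros) yield a constant-correction layer.
#'
#' @param residuals residual sequence, named by original index k (as
#'   returned by [residual_sequence()]); length >= 4.
#' @param order correction level (1 for the first amendment).
#' @return An object of class `residual_model` with fields `order`, `type`
#'   (`"grey"`, `"constant"` or `"noop"`), `a`, `b`, `M`, `k0` (exponent
#'   origin: the modeled magnitude at original index k is
#'   \eqn{2 M e^{a (k - k0)}}), `constant`, `signs`, `extrapolation_sign`.
#' @export
fit_residual_layer <- function(residuals, order = 1) {
  eps <- as.numeric(residuals)
  k_train <- as.integer(names(residuals))
  if (!length(k_train) || anyNA(k_train)) k_train <- seq.int(2, length(eps) + 1)
  if (length(eps) < 4) stop("need at least 4 residuals", call. = FALSE)
  signs <- sign(eps)
  names(signs) <- k_train
  nz <- which(signs != 0)
  extrap_sign <- if (length(nz)) signs[[max(nz)]] else 0

  mk <- function(type, a = 0, b = 0, M = 0, k0 = 2, constant = 0) {
    structure(list(order = order, type = type, a = a, b = b, M = M, k0 = k0,
                   constant = constant, signs = signs,
                   extrapolation_sign = extrap_sign),
              class = "residual_model")
  }
  mag <- abs(eps)
  if (all(mag == 0)) return(mk("noop"))
  if (diff(range(mag)) == 0) return(mk("constant", constant = mag[1]))
  if (any(mag <= 0)) {
    # zeros in the magnitudes: outside the multiplicative model's domain
    return(mk("constant", constant = mean(mag[mag > 0])))
  }
  mg <- (mag[-1] + mag[-length(mag)]) / 2
  a1 <- estimate_development(mg)
  if (abs(a1) < .A_DEGENERATE_TOL) return(mk("constant", constant = mean(mag)))
  b1 <- estimate_amplitude(a1, accumulate(mg))
  M1 <- (1 - exp(-a1)) * b1 / (1 + exp(-a1))
  if (!is.finite(M1) || M1 <= 0) return(mk("constant", constant = mean(mag)))
  # magnitudes re-indexed j = k - 1 carry restored values 2*M1*exp(a1*(j-1)),
  # i.e. origin k0 = 2 on the original index
  mk("grey", a = a1, b = b1, M = M1, k0 = 2)
}

#' Residual model from explicit coefficients
#'
#' Builds a `residual_model` directly from given `(a, b)` — used to apply
#' externally reported residual coefficients, e.g. for reproduction checks
#' against published tables. `k0 = 0` evaluates the correction magnitude as
#' \eqn{2 M e^{a k}} on the original index, the convention the packaged
#' fixture's published amended table follows.
#'
#' @param a,b residual-model coefficients.
#' @param signs named (+1/-1/0) vector of training residual signs, names =
#'   original indices k.
#' @param k0 exponent origin (see [fit_residual_layer()]).
#' @param order correction level.
#' @return A `residual_model`.
#' @export
residual_model <- function(a, b, signs, k0 = 0, order = 1) {
  M <- (1 - exp(-a)) * b / (1 + exp(-a))
  nz <- which(signs != 0)
  structure(list(order = order, type = "grey", a = a, b = b, M = M, k0 = k0,
                 constant = 0, signs = signs,
                 extrapolation_sign = if (length(nz)) signs[[max(nz)]] else 0),
            class = "residual_model")
}

#' @export
print.residual_model <- function(x, ...) {
  cat(sprintf("Residual layer %d (%s)", x$order, x$type))
  if (x$type == "grey") {
    cat(sprintf(": a = %.4f, b = %.2f, M = %.2f, magnitude 2M*exp(a*(k-%g))",
                x$a, x$b, x$M, x$k0))
  } else if (x$type == "constant") {
    cat(sprintf(": constant magnitude %.3f", x$constant))
  }
  cat("\n")
  invisible(x)
}

# modeled correction magnitude at original indices k (always >= 0)
.layer_magnitude <- function(layer, k) {
  switch(layer$type,
         noop = rep(0, length(k)),
         constant = rep(layer$constant, length(k)),
         grey = 2 * layer$M * exp(layer$a * (k - layer$k0)))
}

# per-index signed multiplier: training sign inside the window,
# extrapolation sign beyond it
.layer_sign <- function(layer, k) {
  s <- layer$signs[match(as.character(k), names(layer$signs))]
  s[is.na(s)] <- layer$extrapolation_sign
  unname(s)
}

#' Apply a correction stack to fitted values
#'
#' Subtracts each layer's modeled magnitude where its training residual was
#' positive (overprediction) and adds it where negative:
#' `corrected(k) = base(k) - sum_j sign_j(k) * magnitude_j(k)`. With an
#' empty stack the base is returned unchanged. Applying a frozen stack is
#' deterministic and idempotent.
#'
#' @param base numeric fitted values aligned with `k`.
#' @param stack a [correction_stack] (or list of `residual_model`s).
#' @param k original indices of `base` (default training window 2..n).
#' @return Corrected fitted values (> 0; a correction driving a value
#'   non-positive is an error naming the index).
#' @export
apply_corrections <- function(base, stack, k = seq.int(2, length(base) + 1)) {
  base <- as.numeric(base)
  stopifnot(length(base) == length(k))
  layers <- if (inherits(stack, "correction_stack")) stack$layers else stack
  out <- base
  for (layer in layers) {
    out <- out - .layer_sign(layer, k) * .layer_magnitude(layer, k)
  }
  bad <- which(out <= 0)
  if (length(bad)) {
    stop(sprintf("correction drives fitted value non-positive at index k = %d",
                 k[bad[1]]), call. = FALSE)
  }
  out
}

#' Iterated residual correction
#'
#' Repeatedly fits a residual layer on the current corrected residuals and
#' applies it, until the maximum absolute relative deviation drops to `tol`
#' or `max_rounds` layers have been stacked. The stopping record says which
#' criterion ended the iteration.
#'
#' @param series a [grey_series].
#' @param fit the base [scgm_fit] on that series.
#' @param tol relative-deviation threshold (default 0.10: stop when every
#'   year is within 10 percent).
#' @param max_rounds maximum number of residual layers (default 3).
#' @return An object of class `correction_stack`: list with `layers`,
#'   `stopping = list(criterion, rounds)` and `k_train`.
#' @export
iterate_corrections <- function(series, fit, tol = 0.10, max_rounds = 3) {
  stopifnot(inherits(series, "grey_series"), inherits(fit, "scgm_fit"),
            tol > 0, max_rounds >= 0)
  k_train <- seq.int(2, series$n)
  actual <- series$values[-1]
  layers <- list()
  criterion <- "max_rounds"
  repeat {
    corrected <- apply_corrections(fit$fitted, layers, k_train)
    if (max(abs((corrected - actual) / actual)) <= tol) {
      criterion <- "tol"
      break
    }
    if (length(layers) >= max_rounds) break
    layer <- fit_residual_layer(
      stats::setNames(corrected - actual, k_train),
      order = length(layers) + 1L
    )
    if (layer$type == "noop") {
      criterion <- "tol"
      break
    }
    layers <- c(layers, list(layer))
  }
  structure(list(layers = layers,
                 stopping = list(criterion = criterion,
                                 rounds = length(layers)),
                 k_train = k_train),
            class = "correction_stack")
}

#' @export
print.correction_stack <- function(x, ...) {
  cat(sprintf("Correction stack: %d layer(s), stopped by '%s'\n",
              x$stopping$rounds, x$stopping$criterion))
  for (l in x$layers) print(l)
  invisible(x)
}
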