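#' Synthetic grey-exponential series
#'
#' Generates \eqn{x^{(0)}(k) = 2M e^{a(k-1)} \eta(k)}, k = 1..n, with
#' multiplicative ratio noise \eqn{\eta}: none (`eta = 1`, on which the
#' estimators recover `a` exactly) or uniform on a positive band. Noise is
#' multiplicative on the ratio scale by design — it is the scale on which
#' the model's fit-ratio indicator and the Markov state bands live.
#'
#' The generator uses one seeded RNG stream and restores the caller's RNG
#' state on exit; the fitting path itself consumes no randomness.
#'
#' @param a true development coefficient.
#' @param M true restored amplitude, M > 0.
#' @param n series length, n >= 6.
#' @param noise `"none"` or `"uniform"`.
#' @param band length-2 positive noise band for `"uniform"`.
#' @param start_label first period label (default 1).
#' @param seed integer seed (required for `"uniform"`).
#' @return A [grey_series].
#' @examples
#' s <- generate_grey_series(a = log(2), M = 1, n = 6)
#' s$values  # 2, 4, 8, ... doubling each step
#' @export
generate_grey_series <- function(a, M, n, noise = c("none", "uniform"),
                                 band = c(0.95, 1.05), start_label = 1L,
                                 seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(M > 0, n >= 6)
  eta <- rep(1, n)
  if (noise == "uniform") {
    if (min(band) <= 0) stop("noise band must exclude 0", call. = FALSE)
    eta <- .with_seed(seed, stats::runif(n, band[1], band[2]))
  }
  grey_series(start_label + seq_len(n) - 1L,
              2 * M * exp(a * (seq_len(n) - 1)) * eta)
}

#' Synthetic state-modulated series
#'
#' Samples a hidden state path from a Markov chain, then draws the ratio
#' noise for each year uniformly inside the current state's band:
#' \eqn{x^{(0)}(k) = 2M e^{a(k-1)} \eta(k)}, \eqn{\eta(k) \sim
#' U(\otimes_{1s(k)}, \otimes_{2s(k)})}. Returns the series together with
#' the true path so that state-recovery and transition-estimation tests
#' have ground truth.
#'
#' @param a,M,n as in [generate_grey_series()].
#' @param chain row-stochastic transition matrix (m x m).
#' @param space a [divide_states()] state space with m states.
#' @param start_label first period label.
#' @param seed integer seed.
#' @param init initial state (default 1).
#' @return List with `series` (a [grey_series]) and `path` (integer states).
#' @export
generate_state_series <- function(a, M, n, chain, space, start_label = 1L,
                                  seed = NULL, init = 1L) {
  stopifnot(M > 0, n >= 6, inherits(space, "state_space"))
  m <- nrow(space)
  chain <- as.matrix(chain)
  if (!all(dim(chain) == c(m, m))) stop("chain must be m x m", call. = FALSE)
  if (any(abs(rowSums(chain) - 1) > 1e-8) || any(chain < 0)) {
    stop("chain rows must be probabilities summing to 1", call. = FALSE)
  }
  if (any(space$lower[-1] < space$upper[-m])) {
    stop("state bands must not overlap", call. = FALSE)
  }
  if (space$lower[1] <= 0) stop("ratio bands must be positive", call. = FALSE)
  res <- .with_seed(seed, {
    path <- integer(n)
    path[1] <- as.integer(init)
    for (k in 2:n) {
      path[k] <- sample.int(m, 1, prob = chain[path[k - 1], ])
    }
    eta <- stats::runif(n, space$lower[path], space$upper[path])
    list(path = path, eta = eta)
  })
  list(series = grey_series(start_label + seq_len(n) - 1L,
                            2 * M * exp(a * (seq_len(n) - 1)) * res$eta),
       path = res$path)
}

# evaluate expr under a local seeded RNG stream, restoring global state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  expr
}
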