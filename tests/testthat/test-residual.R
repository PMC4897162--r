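test_that("residual sequence is fitted minus actual over k = 2..n", {
  # published 1991 pair: fitted 7716, actual 6269
  expect_equal(7716 - 6269, 1447)

  s <- load_fixture("china_coal_1990_2010")
  fit <- scgm_fit(s)
  r <- residual_sequence(fit)
  expect_length(r, 20)
  expect_equal(names(r), as.character(2:21))
  expect_equal(unname(r), fit$fitted - s$values[-1])

  d <- scgm_diagnostics(s, s$values[-1])
  expect_equal(unname(residual_sequence(list(diagnostics = d))), rep(0, 20))
})

test_that("a residual layer recovers an exact exponential magnitude model", {
  a1 <- -0.09; M1 <- 250
  k <- 2:15
  signs <- rep(c(1, -1), length.out = length(k))
  mag <- 2 * M1 * exp(a1 * k)
  layer <- fit_residual_layer(stats::setNames(signs * mag, k))
  expect_equal(layer$type, "grey")
  expect_equal(layer$a, a1, tolerance = 1e-10)
  # modeled magnitude function equals the truth on and beyond the window
  expect_equal(greymarkov:::.layer_magnitude(layer, c(k, 16:18)),
               2 * M1 * exp(a1 * c(k, 16:18)), tolerance = 1e-8)
  # sign policy: per-index training signs, latest nonzero sign beyond
  expect_equal(unname(layer$signs), signs)
  expect_equal(layer$extrapolation_sign, signs[length(signs)])
  expect_equal(greymarkov:::.layer_sign(layer, c(2, 3, 99)),
               c(1, -1, signs[length(signs)]))
})

test_that("degenerate residual inputs degrade to constant or no-op layers", {
  k <- 2:9
  layer <- fit_residual_layer(stats::setNames(rep(0, 8), k))
  expect_equal(layer$type, "noop")
  expect_equal(greymarkov:::.layer_magnitude(layer, k), rep(0, 8))

  layer <- fit_residual_layer(stats::setNames(rep(3.5, 8), k))
  expect_equal(layer$type, "constant")
  base <- rep(100, 8)
  expect_equal(apply_corrections(base, list(layer), k), base - 3.5)

  # zero residual at one index: that index gets no correction
  eps <- stats::setNames(c(0, 5, 4, 3, 2, 1, 0.5, 0.25), k)
  layer <- fit_residual_layer(eps)
  expect_equal(unname(layer$signs[1]), 0)
  expect_error(fit_residual_layer(stats::setNames(1:3, 2:4)), "at least 4")
})

test_that("corrections subtract where residuals were positive, add where negative", {
  base <- c(100, 100, 100, 100, 100)
  k <- 2:6
  expect_equal(apply_corrections(base, list(), k), base)

  eps <- stats::setNames(c(10, -10, 10, -10, 10), k)
  layer <- fit_residual_layer(eps)
  corrected <- apply_corrections(base, list(layer), k)
  expect_true(all(corrected[c(1, 3, 5)] < 100))
  expect_true(all(corrected[c(2, 4)] > 100))

  # anti-symmetry: flipping all residual signs flips all corrections
  flipped <- apply_corrections(base, list(fit_residual_layer(-eps)), k)
  expect_equal(corrected - base, -(flipped - base), tolerance = 1e-10)

  # applying a frozen layer twice is deterministic and idempotent per call
  expect_identical(apply_corrections(base, list(layer), k),
                   apply_corrections(base, list(layer), k))
  expect_error(apply_corrections(rep(1, 5), list(layer), k), "k = 2")
})

test_that("one round on exact exponential residuals cancels them", {
  s <- generate_grey_series(-0.06, 2000, 16)
  fit <- scgm_fit(s)
  # perturb the actuals by an exact exponential magnitude with mixed signs
  a1 <- -0.11; M1 <- 40
  k <- 2:16
  eps <- rep(c(1, -1, 1), length.out = 15) * 2 * M1 * exp(a1 * (k - 2))
  perturbed <- grey_series(s$labels, c(s$values[1], fit$fitted - eps))
  pf <- scgm_diagnostics(perturbed, fit$fitted)
  layer <- fit_residual_layer(stats::setNames(pf$residual, pf$k))
  corrected <- apply_corrections(fit$fitted, list(layer), k)
  delta <- (corrected - perturbed$values[-1]) / perturbed$values[-1]
  expect_lt(max(abs(delta)), 1e-8)
})

test_that("iteration stops by tolerance or by round budget and records it", {
  s <- load_fixture("china_coal_1990_2010")
  fit <- scgm_fit(s)

  stack <- iterate_corrections(s, fit, tol = 1e6, max_rounds = 3)
  expect_equal(length(stack$layers), 0)
  expect_equal(stack$stopping$criterion, "tol")

  stack <- iterate_corrections(s, fit, tol = 0.10, max_rounds = 1)
  expect_equal(length(stack$layers), 1)
  expect_equal(stack$stopping$criterion, "max_rounds")

  exact <- generate_grey_series(-0.05, 1000, 10)
  stack <- iterate_corrections(exact, scgm_fit(exact), tol = 0.10)
  expect_equal(length(stack$layers), 0)
  expect_equal(stack$stopping$criterion, "tol")
})

test_that("published residual coefficients applied via the k-anchor build the layer", {
  signs <- stats::setNames(rep(1, 6), 2:7)
  layer <- residual_model(a = -0.0632, b = -21827.6, signs = signs, k0 = 0)
  M1 <- (1 - exp(0.0632)) * (-21827.6) / (1 + exp(0.0632))
  expect_equal(layer$M, M1)
  expect_gt(layer$M, 0)
  # correction magnitude at 1991 (k = 2) is about 1215
  expect_equal(greymarkov:::.layer_magnitude(layer, 2), 1215, tolerance = 1e-3)
})
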