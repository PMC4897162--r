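test_that("state division covers the ratios by all three methods", {
  sp <- table3_space()
  expect_equal(nrow(sp), 4)
  expect_equal(sp$lower, c(0.60, 0.75, 0.90, 1.05))
  expect_equal(sp$upper, c(0.75, 0.90, 1.05, 1.20))
  expect_equal(sp$label, paste0("E", 1:4))

  # equal width over a range spanning exactly [0.60, 1.20] matches them
  ew <- divide_states(c(0.60, 0.8, 1.0, 1.20), m = 4, method = "equal_width")
  expect_equal(ew$lower, sp$lower)
  expect_equal(ew$upper, sp$upper)

  one <- divide_states(c(0.7, 0.9, 1.1), m = 1, method = "equal_width")
  expect_equal(nrow(one), 1)
  expect_true(one$lower <= 0.7 && one$upper >= 1.1)

  # clustering splits two well-separated groups at their midpoint
  cl <- divide_states(c(0.70, 0.72, 0.74, 1.10, 1.12), m = 2, method = "cluster")
  expect_equal(nrow(cl), 2)
  expect_equal(cl$upper[1], (0.74 + 1.10) / 2)
  expect_error(divide_states(c(0.9, 0.9, 1.0), m = 3, method = "cluster"),
               "distinct")
  expect_error(state_space_fixed(c(1, 0.9)), "increasing")
})

test_that("state assignment is half-open with closed top and clips outliers", {
  sp <- table3_space()
  expect_equal(as.integer(assign_states(0.84, sp)), 2L)   # 84% -> E2
  expect_equal(as.integer(assign_states(1.11, sp)), 4L)   # 111% -> E4
  expect_equal(as.integer(assign_states(0.90, sp)), 3L)   # boundary -> upper
  expect_equal(as.integer(assign_states(1.20, sp)), 4L)   # top closed
  expect_warning(p <- assign_states(c(0.5, 1.3), sp), "clipped")
  expect_equal(as.integer(p), c(1L, 4L))
})

test_that("transition counts match a cross-tabulation oracle and rows are stochastic", {
  tm <- transition_model(c(1, 1, 1), step = 1, m = 1)
  expect_equal(tm$probs[1, 1], 1)

  tm <- transition_model(c(1, 2, 1, 2), step = 1, m = 2)
  expect_equal(tm$probs[1, 2], 1)
  expect_equal(tm$probs[2, 1], 1)
  expect_equal(tm$visits, c(E1 = 2, E2 = 1))

  set.seed(11)
  for (i in 1:50) {
    path <- sample.int(4, sample(5:12, 1), replace = TRUE)
    r <- sample(1:3, 1)
    tm <- transition_model(path, r, m = 4)
    expect_equal(unname(tm$counts), oracle_transition_counts(path, r, 4),
                 ignore_attr = TRUE)
    defined <- tm$visits > 0
    expect_equal(rowSums(tm$probs)[defined],
                 rep(1, sum(defined)), ignore_attr = TRUE, tolerance = 1e-12)
    expect_true(all(is.na(tm$probs[!defined, ])))
    expect_equal(rowSums(tm$counts), tm$visits)
  }
  expect_error(transition_model(c(1, 2), step = 0), "positive")
  expect_error(transition_model(c(1, 2), step = 5), "transitions")
})

test_that("state prediction takes the row argmax with the documented tie-breaks", {
  # absorbing state stays put
  tm <- transition_model(c(1, 1, 1, 2), m = 2)
  # 2 has no successor: uniform fallback (warned), then nearest-state rule
  expect_warning(st <- predict_state(tm, 2), "no observed successors")
  expect_equal(st, 2)
  abs1 <- transition_model(c(2, 1, 1, 1, 1), m = 2)
  expect_equal(predict_state(abs1, 1), 1)

  # constructed step-1 tie broken by the step-2 row
  m1 <- transition_model(c(1, 1, 1, 2), m = 2); m1$probs[1, ] <- c(0.5, 0.5)
  m2 <- transition_model(c(1, 1, 1, 2), m = 2); m2$probs[1, ] <- c(0.2, 0.8)
  expect_equal(predict_state(list(m1, m2), 1), 2)
  # unresolved tie: nearest state, then lower index
  m2$probs[1, ] <- c(0.5, 0.5)
  expect_equal(predict_state(list(m1, m2), 1), 1)
  expect_warning(predict_state(transition_model(c(1, 1, 2), m = 2), 2),
                 "no observed successors")
})

test_that("the fixture's state path predicts E4 after 2003", {
  tab2 <- published_table("amended")
  ratios <- tab2$actual / tab2$amended_prediction
  path <- assign_states(ratios, table3_space())
  tm <- transition_model(path, 1)
  st2003 <- path[tab2$year == 2003]
  expect_equal(as.integer(st2003), 4L)
  expect_equal(predict_state(tm, st2003), 4)
  # and the same using only data up to 2003, the true forecasting situation
  tm03 <- transition_model(path[tab2$year <= 2003], 1, m = 4)
  expect_equal(predict_state(tm03, st2003), 4)
})

test_that("midpoint adjustment stays inside the band and matches the algebra", {
  sp <- table3_space()
  af <- adjust_forecast(5433, 4, sp)
  expect_equal(af$ratio, 1.125)
  expect_equal(af$value, 5433 * 1.125)
  expect_equal(af$value_rounded, 6112)

  deg <- state_space_fixed(c(1 - 1e-9, 1 + 1e-9))
  expect_equal(adjust_forecast(100, 1, deg)$value, 100, tolerance = 1e-8)

  set.seed(3)
  for (i in 1:25) {
    base <- runif(1, 10, 1e4)
    st <- sample(4, 1)
    af <- adjust_forecast(base, st, sp)
    expect_gte(af$value, base * sp$lower[st])
    expect_lte(af$value, base * sp$upper[st])
    # midpoint identity: Y + (A+B)/2 with offsets A = lo - Y, B = hi - Y
    y <- runif(1, 0.5, 1.5)
    expect_equal(y + ((sp$lower[st] - y) + (sp$upper[st] - y)) / 2, af$ratio)
  }
})

test_that("empirical two-step transitions agree with the one-step chain squared", {
  chain <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
  sp <- state_space_fixed(c(0.7, 1.0, 1.3))
  sim <- generate_state_series(0, 1000, 1e4, chain, sp, seed = 202)
  p1 <- transition_model(sim$path, 1, m = 2)$probs
  p2 <- transition_model(sim$path, 2, m = 2)$probs
  expect_lt(max(abs(p2 - p1 %*% p1)), 0.05)
  expect_lt(max(abs(p1 - chain)), 0.05)
})
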