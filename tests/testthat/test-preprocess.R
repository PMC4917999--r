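test_that("pipeline applies median, mean, monotonic, blank and calibration in order", {
  m <- calibration_model(c = 0.8324057, blank = 0.04)
  raw <- c(0.10, 0.11, 0.35, 0.12, 0.18, 0.30, 0.55, 0.90, 1.10, 1.12)
  t <- seq_along(raw) / 3
  pc <- preprocess_curve(raw, t, m, monotonic = TRUE)
  med <- ref_median3(raw)
  sm <- ref_mean3(med)
  mono <- ref_monotonic(sm)
  expect_equal(pc$smoothed, sm)
  expect_equal(pc$filtered, mono)
  expect_equal(pc$monotonic_correction_total, sum(abs(mono - sm)))
  x <- pmax(mono - 0.04, 0)
  expect_equal(pc$calibrated, x + 0.8324057 * x^3)
  # monotonic off: filtered stays the smoothed series, correction still measured
  pc2 <- preprocess_curve(raw, t, m, monotonic = FALSE)
  expect_equal(pc2$filtered, sm)
  expect_equal(pc2$monotonic_correction_total, pc$monotonic_correction_total)
})

test_that("a single-point spike is erased; a wide spike is not", {
  m <- calibration_model()
  times <- seq(0, 24, by = 1 / 3)
  clean <- 0.05 * 2^(pmin(times, 12) / 2)
  ref <- preprocess_curve(clean, times, m)
  # spike on the stationary plateau: median restores the exact value
  flat <- clean; flat[60] <- flat[60] * 3
  expect_equal(preprocess_curve(flat, times, m)$calibrated, ref$calibrated)
  # spike mid-exponential: the median substitutes a neighbouring reading,
  # so the result deviates by at most one local increment, not the spike
  steep <- clean; steep[30] <- steep[30] * 3
  dev <- max(abs(preprocess_curve(steep, times, m)$filtered - ref$filtered))
  expect_lt(dev, clean[31] - clean[30])
  # a 3-point wide spike survives the window-3 median
  wide <- clean; wide[30:32] <- wide[30:32] * 3
  expect_false(isTRUE(all.equal(preprocess_curve(wide, times, m)$calibrated,
                                ref$calibrated)))
})

test_that("pipeline is idempotent on smooth monotone data", {
  m <- calibration_model(c = 0, blank = 0)
  times <- seq(0, 10, by = 0.25)
  v <- 0.1 + 0.05 * times          # locally linear, non-decreasing
  p1 <- preprocess_curve(v, times, m)
  p2 <- preprocess_curve(p1$calibrated, times, m)
  inner <- 3:(length(v) - 2)
  expect_lt(max(abs(p2$calibrated - p1$calibrated)[inner]), 1e-12)
  # endpoint-clone padding bends the two boundary values by a fraction
  # of one local increment on each pass (reaching one point inward);
  # bounded, not zero
  expect_lt(max(abs(p2$calibrated - p1$calibrated)), 0.05 * 0.25)
  expect_equal(p1$monotonic_correction_total, 0)
})

test_that("degenerate inputs are rejected with classed errors", {
  m <- calibration_model()
  expect_error(preprocess_curve(c(1, 2), c(0, 1), m),
               class = "odgrowth_series_too_short")
  expect_error(preprocess_curve(c(1, 2, 3), c(0, 1, 1), m),
               class = "odgrowth_nonmonotone_time")
})
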