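test_that("qualifying windows are the growth-phase windows of the raw series", {
  t <- seq(0, 20, by = 0.5)
  expect_equal(nrow(qualifying_windows(rep(0.2, 41), t)), 0)   # flat: none
  lin <- 0.1 + 0.2 * t
  qw <- qualifying_windows(lin, t)
  expect_equal(nrow(qw), 37)                                   # every window
  expect_equal(qw$r2, rep(1, 37))
  slow <- 0.1 + 0.05 * t                                       # below 0.07 OD/h
  expect_equal(nrow(qualifying_windows(slow, t)), 0)
})

test_that("qi1-qi3 follow their r-squared definitions on constructed windows", {
  t <- seq(0, 20, by = 0.5)
  lin <- 0.1 + 0.2 * t
  pc <- preprocess_curve(lin, t, calibration_model())
  q <- quality_indices(pc)
  expect_equal(q$qi1, 0)
  expect_equal(q$qi2, 0)
  expect_equal(q$qi3, 0L)
  # a tripled point mid-growth degrades overlapping windows
  spiked <- lin; spiked[20] <- spiked[20] * 3
  qs <- quality_indices(preprocess_curve(spiked, t, calibration_model()))
  expect_gt(qs$qi2, qs$qi1)
  expect_gte(qs$qi3, 1L)
  # no-growth curve: qi1/qi2 undefined, surfaced as NA
  qf <- quality_indices(preprocess_curve(rep(0.2, 41), t, calibration_model()))
  expect_true(is.na(qf$qi1) && is.na(qf$qi2))
  expect_equal(qf$qi3, 0L)
})

test_that("qi2 >= qi1 and qi3 is bounded by the qualifying windows", {
  set.seed(21)
  for (i in 1:40) {
    t <- seq(0, 36, by = 1 / 3)
    v <- 0.1 + 0.15 * t + rnorm(length(t), sd = runif(1, 0, 0.2))
    pc <- preprocess_curve(pmax(v, 0.01), t, calibration_model())
    q <- quality_indices(pc)
    if (!is.na(q$qi1)) {
      expect_gte(q$qi2, q$qi1 - 1e-12)
      expect_lte(q$qi3, q$n_windows)
    }
  }
})

test_that("qi4 equals the monotonic correction and is 0 iff the smoothed curve is monotone", {
  t <- seq_len(5)
  pc <- as_processed(t, c(2, 2, 0.5, 0.5, 0.5))
  expect_equal(quality_indices(pc)$qi4, 4.5)
  pc2 <- as_processed(seq_len(4), c(1, 2, 1, 3))
  expect_equal(quality_indices(pc2)$qi4, 1.0)
  # through the pipeline, qi4 is measured on the smoothed series
  tt <- seq(0, 24, by = 1 / 3)
  raw <- pmin(0.05 * 2^(tt / 2), 1.2)
  raw[50:length(raw)] <- raw[50:length(raw)] * 0.4      # collapse
  pc3 <- preprocess_curve(raw, tt, calibration_model())
  expect_equal(quality_indices(pc3)$qi4,
               enforce_monotonic(pc3$smoothed)$correction_total)
  expect_gt(quality_indices(pc3)$qi4, 0)
  clean <- preprocess_curve(pmin(0.05 * 2^(tt / 2), 1.2), tt, calibration_model())
  expect_equal(quality_indices(clean)$qi4, 0)
})

test_that("thresholds are interpolated quantiles and flagging is strict exceedance", {
  qis <- lapply(1:100, function(i)
    structure(list(qi1 = 0.01 * i, qi2 = 0.01 * i, qi3 = i, qi4 = 0),
              class = "quality_indices"))
  names(qis) <- 1:100
  thr <- compute_thresholds(qis, 0.05)
  expect_equal(unname(thr$cutoffs["qi1"]), quantile(0.01 * (1:100), 0.95,
                                                    names = FALSE))
  fl <- flag_curves(qis, thr)
  expect_equal(sum(vapply(fl, function(f) "qi1" %in% f, logical(1))), 5)
  # identical batch: cutoff equals the common value, nothing flagged
  same <- lapply(1:30, function(i)
    structure(list(qi1 = 0.2, qi2 = 0.3, qi3 = 1, qi4 = 0.1),
              class = "quality_indices"))
  thr2 <- compute_thresholds(same, 0.05)
  expect_true(all(lengths(flag_curves(same, thr2)) == 0))
  # larger flag fraction flags a superset
  thr15 <- compute_thresholds(qis, 0.15)
  fl15 <- flag_curves(qis, thr15)
  for (i in seq_along(fl)) expect_true(all(fl[[i]] %in% fl15[[i]]))
  expect_error(compute_thresholds(qis, 1.2), class = "odgrowth_bad_values")
  expect_warning(compute_thresholds(same[1:5], 0.05),
                 class = "odgrowth_small_batch")
})

test_that("different corruption types load on different indices", {
  m <- calibration_model()
  base <- curve_spec(lag_h = 4, doubling_time_h = 3, efficiency = 1, seed = 9)
  mk <- function(corr) {
    sp <- base; sp$corruption <- corr
    g <- generate_curve(sp, m)
    quality_indices(preprocess_curve(g$od, g$times, m))
  }
  clean <- mk(list())
  spiky <- mk(list(spike(8, 0.4), spike(10, 0.35)))
  fallen <- mk(list(collapse(40, 0.7)))
  expect_gte(spiky$qi3, 1L)
  expect_equal(spiky$qi4, clean$qi4)        # isolated spikes: no collapse signal
  expect_gt(fallen$qi4, 1)
  expect_equal(fallen$qi3, clean$qi3)       # late collapse: no spike signal
  expect_lt(fallen$qi1, 0.05)               # and barely any overall noise
})
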