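test_that("generated curves are deterministic under a fixed seed", {
  m <- calibration_model()
  sp <- curve_spec(noise_sd = 0.01, seed = 123,
                   corruption = list(spike(10, 0.3)))
  g1 <- generate_curve(sp, m)
  g2 <- generate_curve(sp, m)
  expect_identical(g1$od, g2$od)
  b1 <- generate_benchmark(10, 10, seed = 5)
  b2 <- generate_benchmark(10, 10, seed = 5)
  expect_identical(b1$run$series, b2$run$series)
  b3 <- generate_benchmark(10, 10, seed = 6)
  expect_false(identical(b1$run$series, b3$run$series))
})

test_that("the noiseless generator round-trips through pipeline and extractors", {
  m <- calibration_model()
  sp <- curve_spec(lag_h = 5, doubling_time_h = 2, efficiency = 1.2)
  g <- generate_curve(sp, m)
  tr <- extract_traits(preprocess_curve(g$od, g$times, m))
  expect_lt(abs(tr$lag_h - 5), 1 / 3)
  expect_lt(abs(tr$doubling_time_h - 2) / 2, 0.02)
  expect_lt(abs(tr$efficiency - 1.2) / 1.2, 0.01)
  # sharp limit approaches the ideal piecewise curve
  sharp <- curve_spec(lag_h = 5, doubling_time_h = 2, efficiency = 1.2,
                      lag_sharpness = Inf, sat_sharpness = Inf)
  y <- 10^odgrowth:::true_log10_curve(sharp, c(0, 5, 7, 60))
  expect_equal(y[1], 0.05)
  expect_equal(y[2], 0.05)
  expect_equal(y[3], 0.05 * 2, tolerance = 1e-12)
  expect_equal(y[4], 1.25)
})

test_that("injected corruptions express in the processed curve and indices", {
  m <- calibration_model()
  sp <- curve_spec(lag_h = 4, doubling_time_h = 2, efficiency = 1,
                   duration_h = 48, corruption = list(collapse(40, 0.8)))
  g <- generate_curve(sp, m)
  pc <- preprocess_curve(g$od, g$times, m)
  expect_gt(quality_indices(pc)$qi4, 0)
  # multimodal growth adds its gain to the realised plateau
  sp2 <- curve_spec(lag_h = 2, doubling_time_h = 2, efficiency = 0.8,
                    corruption = list(multimodal(25, 6, 0.3)))
  g2 <- generate_curve(sp2, m)
  expect_equal(g2$truth$efficiency, 1.1)
  eff <- extract_efficiency(preprocess_curve(g2$od, g2$times, m))
  expect_lt(abs(eff$efficiency - 1.1) / 1.1, 0.01)
})

test_that("benchmark runs have the advertised composition and survive TSV round-trip", {
  bench <- generate_benchmark(20, 15, seed = 3)
  expect_length(bench$run$series, 35)
  expect_equal(nrow(bench$truth), 35)
  expect_equal(sum(bench$truth$class == "clean"), 20)
  expect_true(all(bench$truth$corruption[bench$truth$class == "corrupt"] != ""))
  f <- tempfile(fileext = ".tsv")
  write_export(bench$run, "raw", file = f)
  run2 <- parse_growth_file(f)
  fit <- growth_fit(run2)
  truth <- bench$truth
  clean_uni <- truth$class == "clean" & !truth$multimodal
  # under instrument-level noise the max-slope-style rate estimators carry
  # an upward rate bias on slow growers; bounds reflect that dispersion
  expect_lt(max(abs(fit$table$lag_h - truth$lag_h)[clean_uni]), 1.5)
  expect_lt(max((abs(fit$table$doubling_time_h - truth$doubling_time_h) /
                   truth$doubling_time_h)[clean_uni]), 0.25)
  expect_lt(max((abs(fit$table$efficiency - truth$efficiency) /
                   truth$efficiency)[clean_uni]), 0.03)
})
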