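# Brute-force reference implementations and small fixture builders used
# across the test files.  The references are deliberately naive loops so
# they stay independent of the vectorised package code they check.

ref_median3 <- function(x) {
  xp <- c(x[1], x, x[length(x)])
  vapply(seq_along(x), function(i) sort(xp[i:(i + 2)])[2], numeric(1))
}

ref_mean3 <- function(x) {
  xp <- c(x[1], x, x[length(x)])
  vapply(seq_along(x), function(i) mean(xp[i:(i + 2)]), numeric(1))
}

ref_monotonic <- function(x) {
  out <- x
  for (i in seq_along(x)[-1]) if (out[i] < out[i - 1]) out[i] <- out[i - 1]
  out
}

# least squares slope/r2 by lm(), the independent route for window fits
ref_window_fit <- function(t, y) {
  fit <- stats::lm(y ~ t)
  list(k = unname(coef(fit)[2]),
       r2 = if (var(y) == 0) 1 else summary(fit)$r.squared)
}

# a processed_curve whose calibrated values are exactly `values`,
# bypassing the filters entirely: the oracle fixture for extractor tests
as_processed <- function(times, values) {
  mono <- enforce_monotonic(values)
  structure(list(times = times, raw = values, smoothed = values,
                 filtered = values, calibrated = values,
                 monotonic_applied = FALSE,
                 monotonic_correction_total = mono$correction_total),
            class = "processed_curve")
}

# identity-calibration pipeline run (filters applied, no OD transform)
exact_curve <- function(times, values) {
  preprocess_curve(values, times, calibration_model(c = 0, blank = 0))
}

# ideal exponential population curve, already processed
exponential_curve <- function(dt_h = 2, baseline = 0.05, duration = 24,
                              interval = 1 / 3) {
  times <- seq(0, duration, by = interval)
  as_processed(times, baseline * 2^(times / dt_h))
}

# tab-delimited growth file written to a temp path
write_growth_tsv <- function(times_text, series, path = tempfile(fileext = ".tsv")) {
  header <- paste(c("Time", names(series)), collapse = "\t")
  rows <- vapply(seq_along(times_text), function(i)
    paste(c(times_text[i], vapply(series, function(s) as.character(s[i]),
                                  character(1))), collapse = "\t"),
    character(1))
  writeLines(c(header, rows), path)
  path
}
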