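#' Sliding-window linear regressions along a curve
#'
#' Ordinary least-squares fit of `values` on `times` in every contiguous
#' window of `w` points.  Regressions use the actual time values, not
#' indices, so irregular sampling is handled correctly.  The window slope
#' `k`, coefficient of determination `r2`, window midpoint time `t_mid`
#' and fitted value at the midpoint `y_mid` drive lag, rate and
#' quality-index computations.
#'
#' A window whose values have zero variance is a perfect fit of a flat
#' line: `k = 0`, `r2 = 1` by convention (avoids 0/0).
#'
#' @param times Strictly increasing numeric vector (hours).
#' @param values Numeric vector, same length.
#' @param w Window width in points (>= 2).
#' @return A data frame with one row per window: `start` (index of the
#'   window's first point), `end`, `t_mid`, `y_mid`, `k`, `r2`.
#' @export
window_slopes <- function(times, values, w) {
  n <- length(times)
  if (length(values) != n)
    og_stop("odgrowth_bad_values", "times and values lengths differ")
  if (w < 2L) og_stop("odgrowth_bad_values", "window width must be >= 2")
  if (n < w)
    og_stop("odgrowth_series_too_short",
            sprintf("need at least %d points for window width %d", w, w))
  if (any(diff(times) <= 0))
    og_stop("odgrowth_nonmonotone_time", "times must be strictly increasing")
  m <- n - w + 1L
  idx <- outer(seq_len(w) - 1L, seq_len(m), "+")       # w x m window indices
  X <- matrix(times[idx], nrow = w)
  Y <- matrix(values[idx], nrow = w)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm); Yc <- sweep(Y, 2L, ym)
  sxx <- colSums(Xc * Xc)
  syy <- colSums(Yc * Yc)
  sxy <- colSums(Xc * Yc)
  k <- sxy / sxx
  r2 <- ifelse(syy > 0, pmin(pmax(sxy^2 / (sxx * syy), 0), 1), 1)
  data.frame(start = seq_len(m), end = seq_len(m) + w - 1L,
             t_mid = xm, y_mid = ym, k = k, r2 = r2)
}

# log10 with non-positive values replaced by the smallest positive value
# in the series; NULL when no positive value exists (no usable signal).
log10_safe <- function(v) {
  pos <- v[v > 0]
  if (length(pos) == 0L) return(NULL)
  log10(pmax(v, min(pos)))
}

#' Extract the growth lag from a processed curve
#'
#' On the log10 population-size curve, the lag is the time at which the
#' line extrapolated from maximal growth crosses the initial population
#' size.  The initial level is the mean of the first five log10 values;
#' slopes come from a sliding window of eight points; for every window
#' the intercept time \eqn{t^* = t_{mid} - (y_{mid} - y_0)/k} is formed
#' and the lag is the mean of the two largest intercepts, clamped at 0.
#'
#' Windows with near-zero slope would extrapolate to unbounded intercept
#' times, so intercepts are restricted to windows with
#' `k >= max(0.5 * max(k), slope_floor)`; on an ideal log-linear curve
#' this leaves the estimate unchanged since exponential-phase windows
#' dominate the largest intercepts.
#'
#' @param curve A [processed_curve].
#' @param window Window width in points (default 8).
#' @param slope_floor Absolute lower bound on qualifying slopes, in log10
#'   units per hour (default 0.01).
#' @param intercept_rule `"largest_intercepts"` (default; the two largest
#'   intercept times) or `"steepest_slopes"` (the intercepts of the two
#'   steepest windows).
#' @return List with `lag_h` and `metadata` (data frame of the winning
#'   windows: start/end indices, slope, intercept time).
#' @export
extract_lag <- function(curve, window = 8L,
                        slope_floor = 0.01,
                        intercept_rule = c("largest_intercepts", "steepest_slopes")) {
  stopifnot(inherits(curve, "processed_curve"))
  intercept_rule <- match.arg(intercept_rule)
  y <- log10_safe(curve$calibrated)
  if (is.null(y)) og_stop("odgrowth_no_growth", "no positive population sizes")
  if (length(y) < max(window, 5L))
    og_stop("odgrowth_series_too_short", "need at least 8 points for lag extraction")
  y0 <- mean(y[1:5])
  ws <- window_slopes(curve$times, y, window)
  floor_k <- max(0.5 * max(ws$k), slope_floor)
  ws <- ws[ws$k >= floor_k, , drop = FALSE]
  if (nrow(ws) == 0L)
    og_stop("odgrowth_no_growth", "no window exceeds the slope floor; lag undefined")
  ws$t_star <- ws$t_mid - (ws$y_mid - y0) / ws$k
  ord <- if (intercept_rule == "largest_intercepts") order(-ws$t_star) else order(-ws$k)
  win <- ws[ord[seq_len(min(2L, nrow(ws)))], , drop = FALSE]
  list(lag_h = max(mean(win$t_star), 0),
       metadata = win[, c("start", "end", "k", "t_star")])
}

# shared helper: log10 values and window table after the early-curve
# exclusion used by both rate methods
rate_windows <- function(curve, window, exclusion_h, min_windows) {
  y <- log10_safe(curve$calibrated)
  if (is.null(y)) og_stop("odgrowth_no_growth", "no positive population sizes")
  sel <- curve$times >= exclusion_h
  if (sum(sel) < window + min_windows - 1L)
    og_stop("odgrowth_series_too_short",
            sprintf("need at least %d points at t >= %g h",
                    window + min_windows - 1L, exclusion_h))
  offset <- which(sel)[1L] - 1L
  ws <- window_slopes(curve$times[sel], y[sel], window)
  ws$start <- ws$start + offset
  ws$end <- ws$end + offset
  ws
}

#' Extract doubling time: trimmed-maximum short-slope method
#'
#' The default rate estimator.  The first `exclusion_h` hours are
#' excluded (slopes there can reflect cell-size growth on exit from
#' starvation rather than division).  Slopes of log10 population size are
#' taken in a moving window of three points, ranked, the two highest
#' discarded as potential residual artefacts, and the mean of the next
#' five converted to doubling time `log10(2) / slope` hours.
#'
#' @param curve A [processed_curve].
#' @param window Slope window width (default 3).
#' @param exclusion_h Hours excluded at the start of the curve
#'   (default 3).
#' @return List with `doubling_time_h`, `slope` (the trimmed mean slope
#'   in log10 units per hour) and `metadata` (the five contributing
#'   windows).
#' @export
extract_rate_default <- function(curve, window = 3L, exclusion_h = 3) {
  stopifnot(inherits(curve, "processed_curve"))
  ws <- rate_windows(curve, window, exclusion_h, min_windows = 7L)
  ord <- order(-ws$k)
  use <- ws[ord[3:7], , drop = FALSE]
  xbar <- mean(use$k)
  if (xbar <= 0)
    og_stop("odgrowth_nonpositive_rate", "trimmed mean slope is not positive")
  list(doubling_time_h = log10(2) / xbar, slope = xbar,
       metadata = use[, c("start", "end", "k", "r2")])
}

#' Extract doubling time: five-point regression method
#'
#' Alternative rate estimator, less prone to overestimating growth rate
#' on noisy curves and more robust on sparse sampling: linear regressions
#' in a sliding window of five points, the single highest slope converted
#' to doubling time.  The same early-curve exclusion is applied as in
#' [extract_rate_default()].
#'
#' @inheritParams extract_rate_default
#' @param window Regression window width (default 5).
#' @return List with `doubling_time_h`, `slope` and `metadata` (the
#'   winning window).
#' @export
extract_rate_regression <- function(curve, window = 5L, exclusion_h = 3) {
  stopifnot(inherits(curve, "processed_curve"))
  ws <- rate_windows(curve, window, exclusion_h, min_windows = 1L)
  best <- ws[which.max(ws$k), , drop = FALSE]
  if (best$k <= 0)
    og_stop("odgrowth_nonpositive_rate", "maximum window slope is not positive")
  list(doubling_time_h = log10(2) / best$k, slope = best$k,
       metadata = best[, c("start", "end", "k", "r2")])
}

#' Extract growth efficiency (yield)
#'
#' Total gain in population size from baseline to stationary plateau:
#' the mean of the six highest calibrated values minus the mean of the
#' two smallest.  If the coefficient of variation of the six highest
#' values exceeds `cv_max` the curve has not plausibly reached
#' stationary phase and no efficiency estimate is given (`x_base` and
#' `x_top` are still reported).
#'
#' @param curve A [processed_curve].
#' @param cv_max Maximum sd(top six)/mean(top six) for an estimate to be
#'   given (default 0.02).
#' @return List with `efficiency` (or `NA` when undefined), `x_base`,
#'   `x_top`, `defined`, and `metadata` (indices of the points used).
#' @export
extract_efficiency <- function(curve, cv_max = 0.02) {
  stopifnot(inherits(curve, "processed_curve"))
  v <- curve$calibrated
  if (length(v) < 6L)
    og_stop("odgrowth_series_too_short", "need at least 6 points for efficiency")
  ord <- order(v)
  base_idx <- ord[1:2]
  top_idx <- ord[(length(v) - 5L):length(v)]
  x_base <- mean(v[base_idx])
  x_top <- mean(v[top_idx])
  sd_top <- stats::sd(v[top_idx])
  cv <- if (sd_top == 0) 0 else sd_top / x_top
  defined <- cv <= cv_max
  list(efficiency = if (defined) x_top - x_base else NA_real_,
       x_base = x_base, x_top = x_top, defined = defined,
       metadata = list(base = base_idx, top = sort(top_idx)))
}

#' First derivative of the log10 population-size curve
#'
#' Per-time-point slope from a centred three-point least-squares fit;
#' the end points take the slope of their nearest interior window.  For
#' clean sigmoids the derivative maximum coincides with the windows the
#' rate extractor selects.
#'
#' @param curve A [processed_curve].
#' @return Numeric vector of slopes (log10 units per hour), same length
#'   as the curve.
#' @export
first_derivative <- function(curve) {
  stopifnot(inherits(curve, "processed_curve"))
  y <- log10_safe(curve$calibrated)
  if (is.null(y)) return(rep(0, length(curve$calibrated)))
  if (length(y) < 3L)
    og_stop("odgrowth_series_too_short", "need at least 3 points for a derivative")
  ws <- window_slopes(curve$times, y, 3L)
  c(ws$k[1L], ws$k, ws$k[nrow(ws)])
}

#' Extract all fitness components from one processed curve
#'
#' Convenience wrapper running lag, rate (chosen method) and efficiency
#' extraction, converting per-trait failures (no growth, non-positive
#' rate, short series, unstationary plateau) into `NA` values with a
#' recorded reason instead of errors.
#'
#' @param curve A [processed_curve].
#' @param rate_method `"default"` (trimmed short slopes) or
#'   `"regression"` (five-point regression maximum).
#' @param lag_window,rate_exclusion_h,efficiency_cv_max,lag_intercept_rule
#'   Passed to the individual extractors.
#' @return An object of class `fitness_components`: list with `lag_h`,
#'   `doubling_time_h`, `efficiency`, `x_base`, `x_top`, `rate_method`,
#'   `metadata` (per-trait point indices) and `reasons` (per-trait
#'   failure notes, empty string when estimated).
#' @export
extract_traits <- function(curve, rate_method = c("default", "regression"),
                           lag_window = 8L, rate_exclusion_h = 3,
                           efficiency_cv_max = 0.02,
                           lag_intercept_rule = "largest_intercepts") {
  stopifnot(inherits(curve, "processed_curve"))
  rate_method <- match.arg(rate_method)
  reasons <- c(lag = "", rate = "", efficiency = "")
  meta <- list()

  lag <- tryCatch(
    extract_lag(curve, window = lag_window, intercept_rule = lag_intercept_rule),
    odgrowth_error = function(e) e)
  if (inherits(lag, "condition")) {
    lag_h <- NA_real_; reasons["lag"] <- conditionMessage(lag)
  } else {
    lag_h <- lag$lag_h; meta$lag <- lag$metadata
  }

  rate_fun <- if (rate_method == "default") extract_rate_default else extract_rate_regression
  rate <- tryCatch(rate_fun(curve, exclusion_h = rate_exclusion_h),
                   odgrowth_error = function(e) e)
  if (inherits(rate, "condition")) {
    dt_h <- NA_real_; reasons["rate"] <- conditionMessage(rate)
  } else {
    dt_h <- rate$doubling_time_h; meta$rate <- rate$metadata
  }

  eff <- tryCatch(extract_efficiency(curve, cv_max = efficiency_cv_max),
                  odgrowth_error = function(e) e)
  if (inherits(eff, "condition")) {
    efficiency <- NA_real_; x_base <- NA_real_; x_top <- NA_real_
    reasons["efficiency"] <- conditionMessage(eff)
  } else {
    efficiency <- eff$efficiency; x_base <- eff$x_base; x_top <- eff$x_top
    meta$efficiency <- eff$metadata
    if (!eff$defined) reasons["efficiency"] <- "stationary phase not reached (top-six CV above limit)"
  }

  structure(list(lag_h = lag_h, doubling_time_h = dt_h,
                 efficiency = efficiency, x_base = x_base, x_top = x_top,
                 rate_method = rate_method, metadata = meta,
                 reasons = reasons),
            class = "fitness_components")
}

#' @export
print.fitness_components <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4g", v)
  cat(sprintf("fitness components (rate method: %s)\n", x$rate_method))
  cat(sprintf("  lag: %s h   doubling time: %s h   efficiency: %s\n",
              fmt(x$lag_h), fmt(x$doubling_time_h), fmt(x$efficiency)))
  bad <- x$reasons[x$reasons != ""]
  for (nm in names(bad)) cat(sprintf("  [%s] %s\n", nm, bad[nm]))
  invisible(x)
}
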