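#' Pre-process one raw OD series into a calibrated growth curve
#'
#' Runs the full per-curve processing chain, in this order: three-point
#' median filter (removes single-point spikes), three-point mean filter
#' (damps residual high-frequency noise), optional monotonicity filter
#' (removes collapses; true batch growth is non-decreasing), then blank
#' subtraction and cubic OD calibration.  All intermediates are retained
#' so that quality indices and exports can refer to any stage.
#'
#' The monotonic correction total is always computed on the smoothed
#' series (it is quality index 4) even when `monotonic = FALSE` and the
#' correction is not applied.
#'
#' @param raw Numeric vector of raw OD readings (length >= 3).
#' @param times Numeric vector of time points in hours, strictly
#'   increasing, same length as `raw`.
#' @param model A [calibration_model] providing blank and cubic constant.
#' @param monotonic Apply the monotonicity filter? Default `TRUE`.
#' @return An object of class `processed_curve`: list with `times`,
#'   `raw`, `smoothed` (after median+mean), `filtered` (after the
#'   optional monotonic step), `calibrated` (population sizes),
#'   `monotonic_applied`, and `monotonic_correction_total`.
#' @seealso [growth_fit()] for whole-run processing.
#' @examples
#' m <- calibration_preset("S. cerevisiae")
#' pc <- preprocess_curve(c(0.1, 0.1, 0.4, 0.12, 0.2, 0.5, 1.0),
#'                        times = 0:6 / 3, model = m)
#' pc$calibrated
#' @export
preprocess_curve <- function(raw, times, model = calibration_model(),
                             monotonic = TRUE) {
  if (length(raw) < 3L)
    og_stop("odgrowth_series_too_short", "need at least 3 points to pre-process")
  if (length(times) != length(raw))
    og_stop("odgrowth_bad_values", "times and raw lengths differ")
  if (any(diff(times) <= 0))
    og_stop("odgrowth_nonmonotone_time", "times must be strictly increasing")
  smoothed <- mean_filter3(median_filter3(raw))
  mono <- enforce_monotonic(smoothed)
  filtered <- if (monotonic) mono$values else smoothed
  structure(list(
    times = times,
    raw = raw,
    smoothed = smoothed,
    filtered = filtered,
    calibrated = calibrate_od(filtered, model),
    monotonic_applied = monotonic,
    monotonic_correction_total = mono$correction_total,
    model = model
  ), class = "processed_curve")
}

#' @export
print.processed_curve <- function(x, ...) {
  cat(sprintf("processed_curve: %d points over %.2f h; monotonic %s (correction %.4g)\n",
              length(x$times), diff(range(x$times)),
              if (x$monotonic_applied) "applied" else "skipped",
              x$monotonic_correction_total))
  invisible(x)
}
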