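#' Fit growth curves: process a run and extract fitness components
#'
#' The package's central function.  For every well in a [growth_run] it
#' runs the pre-processing chain (median, mean and optional monotonicity
#' filters, blank subtraction, cubic OD calibration), extracts the three
#' fitness components (lag, doubling time, efficiency), computes the
#' four quality indices on the raw series, and — when thresholds are
#' available — flags curves for inspection.
#'
#' Per-curve extraction failures (no detectable growth, non-positive
#' rate, plateau not reached) become `NA` trait values with a recorded
#' reason; they never abort the run.
#'
#' @param run A [growth_run], or a file path passed to
#'   [parse_growth_file()].
#' @param calibration A [calibration_model] or a species preset name
#'   (see [calibration_preset()]).  Default: the S. cerevisiae constant.
#' @param blank Blank OD subtracted before calibration; overrides the
#'   model's blank when not `NULL`.
#' @param monotonic Apply the monotonicity filter (default `TRUE`).
#' @param rate_method `"default"` (trimmed short slopes) or
#'   `"regression"` (five-point regression maximum).
#' @param flag_fraction Fraction each quality index flags when
#'   thresholds are computed from this run's own curves (default 0.05).
#' @param thresholds Optional precomputed [compute_thresholds()] result
#'   (e.g. from a large reference batch); when `NULL`, thresholds are
#'   computed from this run if it has at least 20 wells, otherwise
#'   flagging is skipped.
#' @param slope_threshold Minimum raw-OD slope (OD/h) for a window to
#'   enter the quality indices (default 0.07).
#' @param lag_intercept_rule,rate_exclusion_h,efficiency_cv_max Passed
#'   to the trait extractors.
#' @return Object of class `growth_fit`: list with `run`, `curves`
#'   (processed curves per well), `traits` (per-well
#'   `fitness_components`), `qi` (per-well [quality_indices]), `flags`,
#'   `thresholds`, `table` (a per-well summary data frame) and `call`.
#' @examples
#' bench <- generate_benchmark(n_clean = 30, n_corrupt = 0, seed = 42)
#' fit <- growth_fit(bench$run)
#' fit
#' head(coef(fit))
#' @export
growth_fit <- function(run,
                       calibration = calibration_preset("S. cerevisiae"),
                       blank = NULL,
                       monotonic = TRUE,
                       rate_method = c("default", "regression"),
                       flag_fraction = 0.05,
                       thresholds = NULL,
                       slope_threshold = 0.07,
                       lag_intercept_rule = "largest_intercepts",
                       rate_exclusion_h = 3,
                       efficiency_cv_max = 0.02) {
  rate_method <- match.arg(rate_method)
  if (is.character(run)) run <- parse_growth_file(run)
  stopifnot(inherits(run, "growth_run"))
  model <- if (is.character(calibration)) calibration_preset(calibration)
           else calibration
  stopifnot(inherits(model, "calibration_model"))
  if (!is.null(blank)) model <- calibration_model(model$c, blank, model$label)

  wells <- names(run$series)
  curves <- lapply(run$series, preprocess_curve, times = run$times,
                   model = model, monotonic = monotonic)
  traits <- lapply(curves, extract_traits, rate_method = rate_method,
                   rate_exclusion_h = rate_exclusion_h,
                   efficiency_cv_max = efficiency_cv_max,
                   lag_intercept_rule = lag_intercept_rule)
  qi <- lapply(curves, quality_indices, slope_threshold = slope_threshold)
  names(curves) <- names(traits) <- names(qi) <- wells

  if (is.null(thresholds) && length(wells) >= 20L)
    thresholds <- compute_thresholds(qi, flag_fraction)
  flags <- if (!is.null(thresholds)) flag_curves(qi, thresholds) else NULL

  tab <- data.frame(
    well = as.integer(wells),
    lag_h = vapply(traits, `[[`, numeric(1), "lag_h"),
    doubling_time_h = vapply(traits, `[[`, numeric(1), "doubling_time_h"),
    efficiency = vapply(traits, `[[`, numeric(1), "efficiency"),
    qi1 = vapply(qi, `[[`, numeric(1), "qi1"),
    qi2 = vapply(qi, `[[`, numeric(1), "qi2"),
    qi3 = vapply(qi, function(q) as.numeric(q$qi3), numeric(1)),
    qi4 = vapply(qi, `[[`, numeric(1), "qi4"),
    flags = if (is.null(flags)) "" else
      vapply(flags, paste, character(1), collapse = ";"),
    row.names = NULL
  )

  structure(list(run = run, model = model, curves = curves, traits = traits,
                 qi = qi, thresholds = thresholds, flags = flags,
                 table = tab, rate_method = rate_method,
                 monotonic = monotonic, call = match.call()),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("growth_fit of '%s': %d wells, rate method '%s', calibration c = %.7g (%s)\n",
              x$run$source_name, length(x$curves), x$rate_method,
              x$model$c, x$model$label))
  n_flag <- if (is.null(x$flags)) NA_integer_
            else sum(vapply(x$flags, function(f)
              any(f %in% c("qi1", "qi2", "qi3", "qi4")), logical(1)))
  if (!is.na(n_flag))
    cat(sprintf("  %d well(s) flagged for inspection\n", n_flag))
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  structure(list(table = object$table, rate_method = object$rate_method,
                 model = object$model, thresholds = object$thresholds,
                 source = object$run$source_name),
            class = "summary.growth_fit")
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  cat(sprintf("Growth-curve fit of '%s' (rate method: %s)\n\n", x$source, x$rate_method))
  tr <- x$table[, c("lag_h", "doubling_time_h", "efficiency")]
  est <- colSums(!is.na(tr))
  cat(sprintf("Estimated: lag %d/%d, doubling time %d/%d, efficiency %d/%d wells\n",
              est[1], nrow(tr), est[2], nrow(tr), est[3], nrow(tr)))
  cat("\nTrait summaries:\n")
  print(summary(tr))
  if (!is.null(x$thresholds)) {
    cat("\n")
    print(x$thresholds)
    flagged <- x$table$flags != ""
    cat(sprintf("%d of %d wells flagged\n", sum(flagged), nrow(x$table)))
  }
  invisible(x)
}

#' Fitness-component matrix of a growth fit
#'
#' @param object A [growth_fit].
#' @param ... Unused.
#' @return Numeric matrix (wells x 3) of lag, doubling time and
#'   efficiency; `NA` where undefined.
#' @export
coef.growth_fit <- function(object, ...) {
  m <- as.matrix(object$table[, c("lag_h", "doubling_time_h", "efficiency")])
  rownames(m) <- object$table$well
  m
}

#' Plot growth curves from a fit
#'
#' Raw OD (grey) and calibrated population size (black) on a log10 axis
#' per well, with the lag, rate and efficiency metadata points marked.
#'
#' @param x A [growth_fit].
#' @param wells Well ids to plot (default: first well).
#' @param log Use a log10 y axis (default `TRUE`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.growth_fit <- function(x, wells = names(x$curves)[1L], log = TRUE, ...) {
  wells <- as.character(wells)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(wells)))
  on.exit(graphics::par(old))
  for (w in wells) {
    cv <- x$curves[[w]]
    tr <- x$traits[[w]]
    ylim <- range(c(cv$raw, cv$calibrated)[c(cv$raw, cv$calibrated) > 0])
    graphics::plot(cv$times, pmax(cv$raw, ylim[1]), col = "grey60", pch = 16,
                   cex = 0.4, log = if (log) "y" else "", ylim = ylim,
                   xlab = "time (h)", ylab = "OD / population size",
                   main = paste("well", w), ...)
    graphics::lines(cv$times, pmax(cv$calibrated, ylim[1]), lwd = 1.5)
    if (!is.null(tr$metadata$rate)) {
      idx <- unique(unlist(Map(seq, tr$metadata$rate$start, tr$metadata$rate$end)))
      graphics::points(cv$times[idx], cv$calibrated[idx], col = "red3", pch = 1)
    }
    if (!is.na(tr$lag_h))
      graphics::abline(v = tr$lag_h, col = "blue3", lty = 2)
  }
  invisible(x)
}
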