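## Synthetic growth curves with known ground truth, standing in for the
## plate reader when benchmarking the pipeline.

softplus <- function(u, s) {
  if (is.infinite(s)) return(pmax(u, 0))
  ifelse(s * u > 35, u, log1p(exp(pmin(s * u, 35))) / s)
}

softmin2 <- function(a, b, q) {
  if (is.infinite(q)) return(pmin(a, b))
  m <- pmin(a, b)
  d <- abs(a - b)
  m - log1p(exp(-q * d)) / q
}

#' Specification of one synthetic growth curve
#'
#' Describes the true curve on the log10 population-size scale: flat at
#' `baseline` through the lag, then log-linear growth at slope
#' `log10(2) / doubling_time_h`, saturating at `baseline + efficiency`.
#' The two joins are smoothed (softplus at the lag corner, soft-minimum
#' at saturation) with configurable sharpness, so the ideal piecewise
#' limit is reachable by setting the sharpness to `Inf`.  Instrument
#' noise and artefacts are added on the measured OD scale.
#'
#' @param lag_h True lag (hours, >= 0).
#' @param doubling_time_h True minimal doubling time (hours, > 0).
#' @param efficiency True population-size gain at stationary phase.
#' @param baseline Initial population size (calibrated units).
#' @param duration_h,interval_h Sampling span and interval (hours).
#' @param noise_sd Gaussian noise s.d. on the OD scale (0 = noiseless).
#' @param corruption List of artefacts built with [spike()],
#'   [wide_spike()], [collapse()], [multimodal()].
#' @param lag_sharpness Sharpness of the lag join (per hour; `Inf` for
#'   the exact piecewise corner).  Default 10.
#' @param sat_sharpness Sharpness of the saturation join (per log10
#'   unit; `Inf` for exact).  Default 60.
#' @param seed Optional per-curve RNG seed.
#' @return Object of class `curve_spec`.
#' @export
curve_spec <- function(lag_h = 4, doubling_time_h = 3, efficiency = 1,
                       baseline = 0.05, duration_h = 72, interval_h = 1 / 3,
                       noise_sd = 0, corruption = list(),
                       lag_sharpness = 10, sat_sharpness = 60, seed = NULL) {
  if (lag_h < 0 || doubling_time_h <= 0 || efficiency <= 0 ||
      baseline <= 0 || interval_h <= 0 || noise_sd < 0)
    og_stop("odgrowth_invalid_spec", "curve_spec parameter out of range")
  if (duration_h < lag_h + 3 * doubling_time_h)
    og_stop("odgrowth_invalid_spec",
            "duration must cover the lag plus several doublings")
  structure(list(lag_h = lag_h, doubling_time_h = doubling_time_h,
                 efficiency = efficiency, baseline = baseline,
                 duration_h = duration_h, interval_h = interval_h,
                 noise_sd = noise_sd, corruption = corruption,
                 lag_sharpness = lag_sharpness, sat_sharpness = sat_sharpness,
                 seed = seed),
            class = "curve_spec")
}

#' Curve artefacts for the synthetic generator
#'
#' Constructors for the noise taxonomy injected on the measured OD
#' scale: `spike` adds `amplitude` at the single sampling point nearest
#' `t`; `wide_spike` adds it over `[t, t + width]` (several consecutive
#' points, which a three-point median filter cannot remove); `collapse`
#' scales the above-blank signal down by `depth` for all later times (a
#' sudden sustained drop, as from bubbles or wall adhesion).
#' `multimodal` is not an artefact but a second growth phase on the
#' population scale, starting near `t2` with doubling time `dt2` and
#' additional population gain `gain2` (diauxic-like growth).
#'
#' @param t,t2 Time of the artefact / phase onset (hours).
#' @param amplitude Added OD.
#' @param width Duration of the wide spike (hours).
#' @param depth Fraction of the above-blank signal lost (0-1).
#' @param dt2 Doubling time of the second phase (hours).
#' @param gain2 Population-size gain of the second phase.
#' @return A tagged list understood by [generate_curve()].
#' @name curve_artefacts
NULL

#' @rdname curve_artefacts
#' @export
spike <- function(t, amplitude) list(type = "spike", t = t, amplitude = amplitude)

#' @rdname curve_artefacts
#' @export
wide_spike <- function(t, width, amplitude)
  list(type = "wide_spike", t = t, width = width, amplitude = amplitude)

#' @rdname curve_artefacts
#' @export
collapse <- function(t, depth) list(type = "collapse", t = t, depth = depth)

#' @rdname curve_artefacts
#' @export
multimodal <- function(t2, dt2, gain2)
  list(type = "multimodal", t2 = t2, dt2 = dt2, gain2 = gain2)

# true log10 population-size curve for a spec (vectorised over t)
true_log10_curve <- function(spec, t) {
  y0 <- log10(spec$baseline)
  A <- log10((spec$baseline + spec$efficiency) / spec$baseline)
  r <- log10(2) / spec$doubling_time_h
  g <- r * softplus(t - spec$lag_h, spec$lag_sharpness)
  y <- y0 + softmin2(g, A, spec$sat_sharpness)
  plateau <- spec$baseline + spec$efficiency
  for (co in spec$corruption) {
    if (co$type == "multimodal") {
      A2 <- log10((plateau + co$gain2) / plateau)
      r2 <- log10(2) / co$dt2
      g2 <- r2 * softplus(t - co$t2, spec$lag_sharpness)
      y <- y + softmin2(g2, A2, spec$sat_sharpness)
      plateau <- plateau + co$gain2
    }
  }
  y
}

#' Generate one synthetic raw OD series
#'
#' Builds the true population-size curve for `spec`, maps it to the OD
#' the instrument would record by inverting the calibration function and
#' adding the blank, then adds Gaussian noise and the requested
#' artefacts on the OD scale.  Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [curve_spec()].
#' @param model [calibration_model] describing instrument and blank.
#' @return List with `times` (hours), `od` (raw readings) and `truth`
#'   (the spec's true lag, doubling time and total efficiency, including
#'   multimodal gains).
#' @export
generate_curve <- function(spec, model = calibration_model()) {
  stopifnot(inherits(spec, "curve_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  times <- seq(0, spec$duration_h, by = spec$interval_h)
  n_pop <- 10^true_log10_curve(spec, times)
  od <- invert_calibration(n_pop, model) + model$blank
  if (spec$noise_sd > 0)
    od <- od + stats::rnorm(length(od), sd = spec$noise_sd)
  for (co in spec$corruption) {
    od <- switch(co$type,
      spike = { i <- which.min(abs(times - co$t)); od[i] <- od[i] + co$amplitude; od },
      wide_spike = { i <- times >= co$t & times <= co$t + co$width
                     od[i] <- od[i] + co$amplitude; od },
      collapse = { i <- times >= co$t
                   od[i] <- model$blank + (od[i] - model$blank) * (1 - co$depth); od },
      multimodal = od)
  }
  gains <- sum(vapply(spec$corruption,
                      function(co) if (co$type == "multimodal") co$gain2 else 0,
                      numeric(1)))
  dts <- c(spec$doubling_time_h,
           unlist(lapply(spec$corruption,
                         function(co) if (co$type == "multimodal") co$dt2 else NULL)))
  list(times = times, od = pmax(od, 0),
       truth = list(lag_h = spec$lag_h,
                    doubling_time_h = min(dts),
                    efficiency = spec$efficiency + gains))
}

# trait grids spanning the benchmark's clean curves
.clean_grid <- expand.grid(lag_h = c(2, 5, 10),
                           doubling_time_h = c(1.5, 3, 6),
                           efficiency = c(0.5, 1.0, 1.5))

clean_spec_draw <- function(i, interval_h, duration_h, noise_sd) {
  g <- .clean_grid[((i - 1L) %% nrow(.clean_grid)) + 1L, ]
  # jitter within the grid cell so replicate curves are not identical
  lag <- g$lag_h * stats::runif(1, 0.9, 1.1)
  dt <- g$doubling_time_h * stats::runif(1, 0.95, 1.05)
  eff <- g$efficiency * stats::runif(1, 0.95, 1.05)
  corr <- list()
  if (i %% 7L == 0L) {
    # diauxic-like second phase, markedly slower than the first
    r <- log10(2) / dt
    growth_end <- lag + log10((0.05 + eff) / 0.05) / r
    corr <- list(multimodal(t2 = growth_end + 3, dt2 = 3 * dt, gain2 = 0.3))
  }
  curve_spec(lag_h = lag, doubling_time_h = dt, efficiency = eff,
             duration_h = duration_h, interval_h = interval_h,
             noise_sd = noise_sd, corruption = corr)
}

corrupt_spec_draw <- function(i, interval_h, duration_h) {
  base <- clean_spec_draw(i, interval_h, duration_h, noise_sd = 0.002)
  r <- log10(2) / base$doubling_time_h
  growth_end <- base$lag_h +
    log10((base$baseline + base$efficiency) / base$baseline) / r
  draw_one <- function(type) {
    switch(type,
      spike = spike(t = stats::runif(1, base$lag_h + 0.5, growth_end),
                    amplitude = stats::runif(1, 0.15, 0.6)),
      wide_spike = wide_spike(t = stats::runif(1, base$lag_h + 0.5, growth_end),
                              width = stats::runif(1, 0.7, 2),
                              amplitude = stats::runif(1, 0.2, 0.6)),
      collapse = collapse(t = stats::runif(1, growth_end,
                                           min(duration_h - 5, growth_end + 15)),
                          depth = stats::runif(1, 0.4, 0.9)),
      noise = NULL)
  }
  types <- c("spike", "wide_spike", "collapse", "noise")
  k <- if (stats::runif(1) < 0.5) 1L else 2L
  chosen <- sample(types, k)
  base$noise_sd <- if ("noise" %in% chosen) stats::runif(1, 0.03, 0.08) else 0.002
  base$corruption <- c(base$corruption,
                       Filter(Negate(is.null), lapply(chosen, draw_one)))
  attr(base, "corruption_types") <- chosen
  base
}

#' Generate a benchmark of clean and corrupted synthetic curves
#'
#' Emulates paired benchmarking sets: `n_clean` technically sound curves
#' spanning a grid of lag, doubling-time and efficiency combinations
#' (every seventh curve with a slower diauxic-like second growth phase)
#' and `n_corrupt` curves carrying one or two artefact types drawn
#' uniformly from spikes, wide spikes, collapses and high-frequency
#' noise, at amplitudes typical of seriously compromised curves.  Clean
#' curves carry instrument-level noise (s.d. 0.002 OD).
#'
#' @param n_clean,n_corrupt Number of curves of each class.
#' @param seed RNG seed; output is deterministic given it.
#' @param model [calibration_model] used to map population sizes to OD.
#' @param duration_h,interval_h Sampling span and interval (hours).
#' @return List with `run` (a [growth_run]; wells 1..n_clean are clean,
#'   the rest corrupted) and `truth` (data frame: well, class, true
#'   traits, corruption types).
#' @export
generate_benchmark <- function(n_clean = 100, n_corrupt = 100, seed = 1,
                               model = calibration_model(),
                               duration_h = 72, interval_h = 1 / 3) {
  stopifnot(n_clean >= 1, n_corrupt >= 0)
  set.seed(seed)
  specs <- c(lapply(seq_len(n_clean), clean_spec_draw,
                    interval_h = interval_h, duration_h = duration_h,
                    noise_sd = 0.002),
             lapply(seq_len(n_corrupt), corrupt_spec_draw,
                    interval_h = interval_h, duration_h = duration_h))
  curves <- lapply(specs, generate_curve, model = model)
  series <- lapply(curves, `[[`, "od")
  names(series) <- seq_along(series)
  truth <- data.frame(
    well = seq_along(specs),
    class = rep(c("clean", "corrupt"), c(n_clean, n_corrupt)),
    lag_h = vapply(curves, function(cv) cv$truth$lag_h, numeric(1)),
    doubling_time_h = vapply(curves, function(cv) cv$truth$doubling_time_h, numeric(1)),
    efficiency = vapply(curves, function(cv) cv$truth$efficiency, numeric(1)),
    multimodal = vapply(specs, function(s)
      any(vapply(s$corruption, function(co) co$type == "multimodal", logical(1))),
      logical(1)),
    corruption = vapply(specs, function(s) {
      ct <- attr(s, "corruption_types")
      if (is.null(ct)) "" else paste(ct, collapse = ";")
    }, character(1))
  )
  list(run = growth_run(curves[[1L]]$times, series, source_name = "synthetic-benchmark"),
       truth = truth)
}
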