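#' Growth-phase windows qualifying for quality scoring
#'
#' Quality indices consider only windows in the growth phase of the raw
#' data series: five-point sliding regressions whose slope exceeds
#' `slope_threshold` (raw OD units per hour, default 0.07).  Working on
#' the raw series means the indices see the noise the filters would
#' remove.
#'
#' @param raw Numeric vector of raw OD readings.
#' @param times Numeric vector of hours, strictly increasing.
#' @param slope_threshold Minimum slope for a window to qualify
#'   (default 0.07 OD/h).
#' @param window Window width (default 5).
#' @return Data frame of qualifying windows as in [window_slopes()];
#'   zero rows when no window qualifies (no detectable growth).
#' @export
qualifying_windows <- function(raw, times, slope_threshold = 0.07, window = 5L) {
  ws <- window_slopes(times, raw, window)
  ws[ws$k > slope_threshold, , drop = FALSE]
}

#' Quality indices for one raw growth curve
#'
#' Computes the four per-curve quality scores:
#' \describe{
#'   \item{qi1 "overall noisiness"}{1 minus the mean r-squared over all
#'     qualifying growth-phase windows; `NA` when no window qualifies
#'     (no detectable growth).}
#'   \item{qi2 "local noisiness"}{1 minus the mean of the three worst
#'     r-squared values (all of them when fewer than three windows
#'     qualify); flags very noisy local regions.}
#'   \item{qi3 "number of spikes"}{count of qualifying windows with
#'     r-squared below 0.5 -- sharp bends in the curve.}
#'   \item{qi4 "curve collapses"}{total correction the monotonicity
#'     filter applies to the smoothed series: sum over time points of
#'     the absolute differences before vs after that filter.  Captures
#'     sudden sustained drops that the other indices miss.}
#' }
#' High values suggest technical problems; flagged curves should be
#' visually inspected rather than auto-rejected.
#'
#' @param curve A [processed_curve] (qi1-qi3 use its raw series, qi4 its
#'   smoothed series).
#' @param slope_threshold,window Passed to [qualifying_windows()].
#' @return Object of class `quality_indices`: list with `qi1`, `qi2`,
#'   `qi3`, `qi4` and `n_windows` (number of qualifying windows).
#' @export
quality_indices <- function(curve, slope_threshold = 0.07, window = 5L) {
  stopifnot(inherits(curve, "processed_curve"))
  qw <- if (length(curve$raw) >= window)
    qualifying_windows(curve$raw, curve$times, slope_threshold, window)
  else
    data.frame(r2 = numeric(0))
  if (nrow(qw) == 0L) {
    qi1 <- NA_real_; qi2 <- NA_real_; qi3 <- 0L
  } else {
    qi1 <- 1 - mean(qw$r2)
    worst <- sort(qw$r2)[seq_len(min(3L, nrow(qw)))]
    qi2 <- 1 - mean(worst)
    qi3 <- sum(qw$r2 < 0.5)
  }
  structure(list(qi1 = qi1, qi2 = qi2, qi3 = qi3,
                 qi4 = curve$monotonic_correction_total,
                 n_windows = nrow(qw)),
            class = "quality_indices")
}

#' @export
print.quality_indices <- function(x, ...) {
  cat(sprintf("QI1 %.4g  QI2 %.4g  QI3 %d  QI4 %.4g  (%d growth windows)\n",
              x$qi1, x$qi2, x$qi3, x$qi4, x$n_windows))
  invisible(x)
}

qi_batch_matrix <- function(batch) {
  stopifnot(length(batch) > 0L)
  m <- t(vapply(batch, function(q) c(q$qi1, q$qi2, as.numeric(q$qi3), q$qi4),
                numeric(4)))
  colnames(m) <- c("qi1", "qi2", "qi3", "qi4")
  m
}

#' Flagging thresholds from a reference batch of quality indices
#'
#' Per-index cutoffs are empirical quantiles of the index distribution
#' over a reference batch: with `flag_fraction = f`, the cutoff is the
#' `1 - f` quantile (linear interpolation between order statistics,
#' pinned so flag counts are reproducible) and curves strictly above it
#' are flagged.  In routine use the reference batch is large and
#' predominantly of good quality, so each index flags roughly its worst
#' `f` fraction; 5 % is the level at which false positives and false
#' negatives balance best.  Undefined index values (no-growth curves)
#' are excluded from the distribution.
#'
#' @param batch A list of [quality_indices] objects, or a numeric matrix
#'   / data frame with columns qi1..qi4.
#' @param flag_fraction Fraction of curves each index should flag
#'   (default 0.05).
#' @return Object of class `threshold_set`: named cutoff vector plus the
#'   flag fraction.
#' @export
compute_thresholds <- function(batch, flag_fraction = 0.05) {
  if (!is.numeric(flag_fraction) || flag_fraction <= 0 || flag_fraction >= 1)
    og_stop("odgrowth_bad_values", "flag_fraction must be in (0, 1)")
  m <- if (is.list(batch) && !is.data.frame(batch)) qi_batch_matrix(batch)
       else as.matrix(batch[, c("qi1", "qi2", "qi3", "qi4")])
  if (nrow(m) == 0L) og_stop("odgrowth_empty_batch", "empty reference batch")
  if (nrow(m) < 20L)
    og_warn("odgrowth_small_batch",
            "fewer than 20 reference curves; quantile cutoffs will be unstable")
  cutoffs <- apply(m, 2L, function(col)
    stats::quantile(col[!is.na(col)], probs = 1 - flag_fraction,
                    type = 7, names = FALSE))
  structure(list(cutoffs = cutoffs, flag_fraction = flag_fraction),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("QI flagging thresholds (worst %.3g%% per index):\n",
              100 * x$flag_fraction))
  print(signif(x$cutoffs, 5))
  invisible(x)
}

#' Flag curves whose quality indices exceed the thresholds
#'
#' An index flags a curve when its value strictly exceeds the cutoff;
#' curves carry 0 to 4 flags.  Curves with undefined qi1/qi2 (no
#' detectable growth) get a `"no-growth"` advisory rather than a quality
#' flag.
#'
#' @param indices A named list of [quality_indices] (names are well
#'   ids), or a matrix / data frame with columns qi1..qi4.
#' @param thresholds A [compute_thresholds()] result.
#' @return Named list of character vectors of flag names per curve
#'   (subset of `"qi1".."qi4"`, possibly with the `"no-growth"`
#'   advisory).
#' @export
flag_curves <- function(indices, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  m <- if (is.list(indices) && !is.data.frame(indices)) qi_batch_matrix(indices)
       else as.matrix(indices[, c("qi1", "qi2", "qi3", "qi4")])
  cut <- thresholds$cutoffs
  out <- lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    flags <- names(cut)[!is.na(v) & v > cut]
    if (is.na(v["qi1"])) flags <- c(flags, "no-growth")
    flags
  })
  names(out) <- if (!is.null(names(indices)) && is.list(indices)) names(indices)
                else rownames(m)
  out
}
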