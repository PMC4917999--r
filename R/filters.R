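#' Three-point sliding median filter
#'
#' Replaces each value by the median of the three-point window centred on
#' it.  The series is padded by cloning its endpoints, so the output has
#' the same length as the input and no edge cropping occurs.  A window of
#' three removes isolated single-point spikes while leaving monotone
#' stretches untouched; wider artefacts ("wide spikes") pass through.
#'
#' @param x Numeric vector of optical-density readings (length >= 1).
#' @return Numeric vector of the same length as `x`.
#' @seealso [mean_filter3()], [enforce_monotonic()], [preprocess_curve()]
#' @examples
#' median_filter3(c(1, 9, 1))        # spike removed -> 1 1 1
#' median_filter3(c(0.1, 0.2, 0.3))  # monotone -> unchanged
#' @export
median_filter3 <- function(x) {
  if (length(x) == 0L) og_stop("odgrowth_empty_series", "empty series")
  if (!is_finite_numeric(x)) og_stop("odgrowth_bad_values", "series must be finite numeric")
  if (length(x) == 1L) return(x)
  xp <- c(x[1L], x, x[length(x)])
  n <- length(x)
  a <- xp[1:n]; b <- xp[2:(n + 1L)]; c_ <- xp[3:(n + 2L)]
  # median of three = sum minus min minus max, vectorised
  pmin(pmax(pmin(a, b), c_), pmax(a, b))
}

#' Three-point sliding mean filter
#'
#' Replaces each value by the mean of the three-point window centred on it,
#' with endpoint-cloned padding (same convention as [median_filter3()]).
#' Smooths residual high-frequency noise after the median pass.
#'
#' @inheritParams median_filter3
#' @return Numeric vector of the same length as `x`, bounded by
#'   `range(x)`.
#' @export
mean_filter3 <- function(x) {
  if (length(x) == 0L) og_stop("odgrowth_empty_series", "empty series")
  if (!is_finite_numeric(x)) og_stop("odgrowth_bad_values", "series must be finite numeric")
  if (length(x) == 1L) return(x)
  xp <- c(x[1L], x, x[length(x)])
  n <- length(x)
  (xp[1:n] + xp[2:(n + 1L)] + xp[3:(n + 2L)]) / 3
}

#' Monotonicity filter
#'
#' Sweeps the series left to right and replaces any value lower than its
#' predecessor with the predecessor, producing the pointwise-smallest
#' non-decreasing majorant (a running maximum).  True batch growth curves
#' are non-decreasing; sustained drops are instrument artefacts (bubbles,
#' aggregation, wall adhesion), so the total correction applied is a
#' direct measure of "curve collapse" and feeds quality index 4.
#'
#' @inheritParams median_filter3
#' @return A list with `values` (non-decreasing numeric vector) and
#'   `correction_total` (sum of absolute corrections; 0 iff the input was
#'   already non-decreasing).
#' @export
enforce_monotonic <- function(x) {
  if (length(x) == 0L) og_stop("odgrowth_empty_series", "empty series")
  if (!is_finite_numeric(x)) og_stop("odgrowth_bad_values", "series must be finite numeric")
  out <- cummax(x)
  list(values = out, correction_total = sum(abs(out - x)))
}
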