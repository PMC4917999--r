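#' Calibration model for converting optical density to population size
#'
#' Recorded optical densities respond sublinearly to cell density above
#' roughly OD 0.3 because cells shield each other from the light beam.
#' The cubic response model \eqn{y = x + c x^3} corrects for this: `x` is
#' the blank-corrected OD, `y` the calibrated population-size estimate,
#' and `c` an empirical, species- and instrument-specific constant fitted
#' from a dilution series.  At low OD the mapping is near-identity.
#'
#' @param c Non-negative cubic coefficient (dimensionless).
#' @param blank Background OD of medium without cells, subtracted from
#'   every reading before calibration.  Assumed constant across wells.
#' @param label Free-text label (species / instrument).
#' @return An object of class `calibration_model`.
#' @seealso [calibration_preset()], [calibrate_od()], [fit_calibration()]
#' @export
calibration_model <- function(c = 0.8324057, blank = 0, label = "custom") {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0)
    og_stop("odgrowth_bad_model", "calibration coefficient must be a single finite value >= 0")
  if (!is.numeric(blank) || length(blank) != 1L || !is.finite(blank) || blank < 0)
    og_stop("odgrowth_bad_model", "blank must be a single finite value >= 0")
  structure(list(c = c, blank = blank, label = label),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("OD calibration model: y = x + c*x^3\n")
  cat(sprintf("  c = %.10g  blank = %.4g  (%s)\n", x$c, x$blank, x$label))
  invisible(x)
}

# Empirical cubic coefficients per species (Bioscreen C).  The
# S. cerevisiae value is the long-established one retained for
# back-compatibility with existing phenomics pipelines.
.calibration_constants <- c(
  "S. cerevisiae" = 0.8324057,
  "C. albicans"   = 0.5790256635480614,
  "P. pastoris"   = 0.5653284345804932,
  "S. pombe"      = 0.64672463774234579,
  "E. coli"       = 0.75389848795692815
)

#' Species presets for the calibration constant
#'
#' Returns a [calibration_model] with the empirical cubic coefficient for
#' one of the five shipped species presets, or the named vector of all
#' constants when called without arguments.
#'
#' @param species One of `"S. cerevisiae"` (default), `"C. albicans"`,
#'   `"P. pastoris"`, `"S. pombe"`, `"E. coli"`; partial matching allowed.
#' @param blank Blank OD to attach to the model.
#' @return A `calibration_model`, or a named numeric vector if `species`
#'   is `NULL`.
#' @export
calibration_preset <- function(species = "S. cerevisiae", blank = 0) {
  if (is.null(species)) return(.calibration_constants)
  idx <- pmatch(species, names(.calibration_constants))
  if (is.na(idx))
    og_stop("odgrowth_bad_model",
            paste0("unknown species preset: ", species, " (available: ",
                   paste(names(.calibration_constants), collapse = ", "), ")"))
  calibration_model(c = unname(.calibration_constants[idx]), blank = blank,
                    label = names(.calibration_constants)[idx])
}

#' Calibrate optical densities into population-size estimates
#'
#' Subtracts the blank, clamps negative blank-corrected values at zero
#' (the cubic term would otherwise yield negative "population sizes"),
#' and applies \eqn{y = x + c x^3}.  Strictly increasing in `x`, so the
#' ordering of population sizes is preserved.
#'
#' @param od Numeric vector of raw OD readings.
#' @param model A [calibration_model].
#' @return Numeric vector of calibrated population-size estimates.
#' @export
calibrate_od <- function(od, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (!is_finite_numeric(od)) og_stop("odgrowth_bad_values", "OD values must be finite numeric")
  x <- pmax(od - model$blank, 0)
  x + model$c * x^3
}

#' Invert the calibration function
#'
#' Solves \eqn{x + c x^3 = y} for the unique non-negative root, i.e. maps
#' a target population size back to the blank-corrected OD the instrument
#' would record.  Used by the synthetic-curve generator to emit raw OD.
#'
#' @param y Numeric vector of population sizes (>= 0).
#' @param model A [calibration_model].
#' @return Numeric vector `x >= 0` with `x + c*x^3 == y` to relative
#'   tolerance 1e-10.
#' @export
invert_calibration <- function(y, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (!is_finite_numeric(y) || any(y < 0))
    og_stop("odgrowth_negative_input", "population sizes must be finite and >= 0")
  cc <- model$c
  if (cc == 0) return(y)
  # depressed cubic c*x^3 + x - y = 0 has one real root for c > 0;
  # Cardano is exact and vectorises, then one Newton step polishes it.
  p <- 1 / cc
  q <- -y / cc
  disc <- sqrt(q^2 / 4 + p^3 / 27)
  x <- cbrt(-q / 2 + disc) + cbrt(-q / 2 - disc)
  f <- x + cc * x^3 - y
  x <- x - f / (1 + 3 * cc * x^2)
  pmax(x, 0)
}

cbrt <- function(v) sign(v) * abs(v)^(1 / 3)

#' Fit the calibration constant from a dilution series
#'
#' Given blank-corrected pairs of observed OD (`x`) and true density
#' (`y`, e.g. the OD of a dilution below 0.3 multiplied back by the
#' dilution factor), estimates `c` in \eqn{y = x + c x^3} by least
#' squares.  The model is linear in `c`, so the closed form
#' \eqn{\hat c = \sum x^3 (y - x) / \sum x^6} is exact; a negative
#' estimate is clamped to 0.
#'
#' @param observed_od Numeric vector of blank-corrected observed OD.
#' @param true_density Numeric vector of the same length with the true
#'   densities.
#' @param blank Blank value recorded in the returned model (the inputs
#'   are assumed already blank-corrected).
#' @param label Label for the returned model.
#' @return A [calibration_model] with the fitted `c`.
#' @export
fit_calibration <- function(observed_od, true_density, blank = 0,
                            label = "fitted") {
  if (length(observed_od) != length(true_density))
    og_stop("odgrowth_bad_values", "observed_od and true_density lengths differ")
  if (length(observed_od) < 2L)
    og_stop("odgrowth_insufficient_data", "need at least 2 dilution pairs")
  if (!is_finite_numeric(observed_od) || !is_finite_numeric(true_density) ||
      any(observed_od < 0) || any(true_density < 0))
    og_stop("odgrowth_bad_values", "dilution pairs must be finite and >= 0")
  x3 <- observed_od^3
  denom <- sum(x3^2)
  if (denom == 0)
    og_stop("odgrowth_insufficient_data", "all observed OD are zero; c not identifiable")
  chat <- sum(x3 * (true_density - observed_od)) / denom
  calibration_model(c = max(chat, 0), blank = blank, label = label)
}
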