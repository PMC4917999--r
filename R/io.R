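#' Construct a growth run
#'
#' A growth run is one parsed input file: a shared time axis in hours
#' plus one raw OD series per well, keyed by the integer well id from
#' the file's column header.
#'
#' @param times Strictly increasing numeric vector of hours.
#' @param series Named list of numeric vectors (names coercible to
#'   positive integers, unique), each the same length as `times`.
#' @param source_name Text label for the run.
#' @return Object of class `growth_run` with fields `times`, `series`,
#'   `source_name` and `sampling_interval_hint` (median of successive
#'   time differences, hours).
#' @export
growth_run <- function(times, series, source_name = "run") {
  if (length(times) == 0L) og_stop("odgrowth_empty_file", "no time points")
  if (any(diff(times) <= 0))
    og_stop("odgrowth_nonmonotone_time", "times must be strictly increasing")
  if (length(series) == 0L) og_stop("odgrowth_empty_file", "no data series")
  ids <- suppressWarnings(as.integer(names(series)))
  if (anyNA(ids) || any(ids < 1L) || anyDuplicated(ids))
    og_stop("odgrowth_bad_header", "well ids must be unique positive integers")
  lens <- lengths(series)
  if (any(lens != length(times)))
    og_stop("odgrowth_ragged_columns", "all series must match the time axis length")
  for (s in series) if (!is_finite_numeric(s))
    og_stop("odgrowth_bad_values", "all OD readings must be finite numbers")
  structure(list(times = as.numeric(times),
                 series = series,
                 source_name = source_name,
                 sampling_interval_hint = stats::median(diff(times))),
            class = "growth_run")
}

#' @export
print.growth_run <- function(x, ...) {
  cat(sprintf("growth_run '%s': %d wells x %d time points (%.2f-%.2f h, ~%.3g h interval)\n",
              x$source_name, length(x$series), length(x$times),
              min(x$times), max(x$times), x$sampling_interval_hint))
  invisible(x)
}

# "hh:mm:ss" (hours may exceed 24), "hh:mm", or decimal hours (decimal
# comma tolerated).  NA when unparseable.
parse_time_value <- function(s) {
  s <- trimws(s)
  if (s == "") return(NA_real_)
  if (grepl(":", s, fixed = TRUE)) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
    if (!(length(parts) %in% 2:3)) return(NA_real_)
    nums <- suppressWarnings(as.numeric(parts))
    if (anyNA(nums) || any(nums < 0)) return(NA_real_)
    nums[1L] + nums[2L] / 60 + (if (length(nums) == 3L) nums[3L] / 3600 else 0)
  } else {
    suppressWarnings(as.numeric(chartr(",", ".", s)))
  }
}

#' Read a Bioscreen-C export or generic tab-delimited growth file
#'
#' Parses a plate-reader time-series file into a [growth_run].  The
#' first column is time (`hh:mm:ss` with hours allowed past 24, or
#' decimal hours); the remaining columns are data series headed by
#' integer well ids.  Bioscreen CSV exports are comma-separated; generic
#' files are tab-separated; `dialect = "auto"` picks tab when any tab
#' occurs in the file.  Leading preamble lines are skipped until the
#' first row whose first field parses as a time; the line immediately
#' before it must be the header.  Decimal commas in data fields are
#' normalised (tab dialect only, where they are unambiguous).
#'
#' Rows whose time fails to parse are dropped with a warning; more than
#' 1 % of such rows is an error.
#'
#' @param file Path to the input file, or a character vector of lines
#'   via `text`.
#' @param dialect `"auto"` (default), `"bioscreen_csv"` or
#'   `"tab_generic"`.
#' @param text Optional character vector of lines, instead of `file`.
#' @return A [growth_run].
#' @export
parse_growth_file <- function(file, dialect = c("auto", "bioscreen_csv", "tab_generic"),
                              text = NULL) {
  dialect <- match.arg(dialect)
  lines <- if (!is.null(text)) text else readLines(file, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0L) og_stop("odgrowth_empty_file", "empty input file")
  sep <- switch(dialect,
                bioscreen_csv = ",",
                tab_generic = "\t",
                auto = if (any(grepl("\t", lines, fixed = TRUE))) "\t" else ",")
  fields <- strsplit(lines, sep, fixed = TRUE)
  is_data <- vapply(fields, function(f) !is.na(parse_time_value(f[1L])), logical(1))
  first_data <- which(is_data)[1L]
  if (is.na(first_data))
    og_stop("odgrowth_empty_file", "no data rows found (no first field parses as a time)")
  if (first_data == 1L)
    og_stop("odgrowth_bad_header", "no header row before the first data row")
  header <- trimws(fields[[first_data - 1L]])
  ids <- suppressWarnings(as.integer(header[-1L]))
  if (length(ids) == 0L || anyNA(ids) || any(ids < 1L) || anyDuplicated(ids))
    og_stop("odgrowth_bad_header",
            "series headers must be unique positive integers")
  data_fields <- fields[seq(first_data, length(fields))]
  times <- vapply(data_fields, function(f) parse_time_value(f[1L]), numeric(1))
  bad <- is.na(times)
  if (any(bad)) {
    if (mean(bad) > 0.01)
      og_stop("odgrowth_bad_values",
              sprintf("%d of %d rows have unparseable times", sum(bad), length(bad)))
    og_warn("odgrowth_dropped_rows",
            sprintf("dropped %d row(s) with unparseable times", sum(bad)))
    data_fields <- data_fields[!bad]
    times <- times[!bad]
  }
  ncols <- length(ids) + 1L
  if (any(lengths(data_fields) != ncols))
    og_stop("odgrowth_ragged_columns",
            "data rows do not all have one value per header column")
  vals <- vapply(data_fields, function(f) {
    v <- f[-1L]
    if (sep == "\t") v <- chartr(",", ".", v)
    suppressWarnings(as.numeric(v))
  }, numeric(length(ids)))
  vals <- matrix(vals, nrow = length(ids))          # wells x times
  if (anyNA(vals) || any(!is.finite(vals)))
    og_stop("odgrowth_bad_values", "non-numeric or non-finite OD readings")
  if (any(diff(times) <= 0))
    og_stop("odgrowth_nonmonotone_time", "parsed times are not strictly increasing")
  series <- lapply(seq_along(ids), function(i) vals[i, ])
  names(series) <- ids
  src <- if (!is.null(text)) "text" else basename(file)
  growth_run(times, series, source_name = src)
}

fmt6 <- function(v) {
  out <- trimws(formatC(v, digits = 6, format = "g"))
  out[is.na(v)] <- ""
  out
}

#' Export a run's data products as tab-delimited text
#'
#' Four products can be exported: `"raw"` (the parsed OD), `"processed"`
#' (calibrated population-size estimates), `"derivative"` (per-point
#' slopes of the log10 processed curves) and `"fitness"` (one row per
#' well with the fitness components, quality indices and flags).  Curve
#' products have time in hours in the first column; wells marked
#' excluded are omitted.  Floats are printed with 6 significant digits.
#' Undefined trait values are exported as empty cells with the reason in
#' a trailing column, never as zeros.
#'
#' @param run A [growth_run] (or a [growth_fit], from which processed
#'   curves, traits and quality results are taken automatically).
#' @param product One of `"raw"`, `"processed"`, `"derivative"`,
#'   `"fitness"`.
#' @param file Optional path; when given the text is written there.
#' @param processed Named list of [processed_curve] per well (curve
#'   products other than raw).
#' @param traits Named list of [extract_traits()] results (fitness
#'   product).
#' @param qi Named list of [quality_indices] per well (fitness product;
#'   optional).
#' @param flags Named list of character flag vectors (fitness product;
#'   optional).
#' @param excluded_wells Integer well ids to omit.
#' @return The export text as a character vector of lines, invisibly
#'   when `file` is given.
#' @export
write_export <- function(run, product = c("raw", "processed", "derivative", "fitness"),
                         file = NULL, processed = NULL, traits = NULL,
                         qi = NULL, flags = NULL, excluded_wells = integer()) {
  product <- match.arg(product)
  if (inherits(run, "growth_fit")) {
    fit <- run
    run <- fit$run
    if (is.null(processed)) processed <- fit$curves
    if (is.null(traits)) traits <- fit$traits
    if (is.null(qi)) qi <- fit$qi
    if (is.null(flags)) flags <- fit$flags
  }
  stopifnot(inherits(run, "growth_run"))
  wells <- names(run$series)
  keep <- wells[!(as.integer(wells) %in% excluded_wells)]

  lines <- if (product == "fitness") {
    if (is.null(traits) || !all(keep %in% names(traits)))
      og_stop("odgrowth_missing_product", "fitness components not available for all wells")
    header <- paste(c("well", "lag_h", "doubling_time_h", "efficiency",
                      "QI1", "QI2", "QI3", "QI4", "flags", "reason"),
                    collapse = "\t")
    rows <- vapply(keep, function(w) {
      tr <- traits[[w]]
      q <- qi[[w]]
      qv <- if (is.null(q)) rep(NA_real_, 4) else c(q$qi1, q$qi2, q$qi3, q$qi4)
      fl <- if (is.null(flags[[w]])) "" else paste(flags[[w]], collapse = ";")
      rs <- paste(tr$reasons[tr$reasons != ""], collapse = "; ")
      paste(c(w, fmt6(c(tr$lag_h, tr$doubling_time_h, tr$efficiency, qv)), fl, rs),
            collapse = "\t")
    }, character(1))
    c(header, rows)
  } else {
    mat <- switch(product,
      raw = vapply(keep, function(w) run$series[[w]], numeric(length(run$times))),
      processed = {
        if (is.null(processed) || !all(keep %in% names(processed)))
          og_stop("odgrowth_missing_product", "processed curves not available for all wells")
        vapply(keep, function(w) processed[[w]]$calibrated, numeric(length(run$times)))
      },
      derivative = {
        if (is.null(processed) || !all(keep %in% names(processed)))
          og_stop("odgrowth_missing_product", "processed curves required for derivatives")
        vapply(keep, function(w) first_derivative(processed[[w]]),
               numeric(length(run$times)))
      })
    mat <- matrix(mat, nrow = length(run$times))
    header <- paste(c("time_h", keep), collapse = "\t")
    rows <- vapply(seq_along(run$times), function(i)
      paste(c(fmt6(run$times[i]), fmt6(mat[i, ])), collapse = "\t"),
      character(1))
    c(header, rows)
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
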