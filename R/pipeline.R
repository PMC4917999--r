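#' Run the full processing pipeline over one or more input files
#'
#' Batch orchestration: parse each input file, pre-process every well,
#' extract fitness components, compute quality indices and flags, and
#' write the requested export products as tab-delimited files into the
#' output directory.  Per-curve extraction failures are reported in the
#' log and exported as empty cells with a reason; only I/O or
#' configuration errors abort the run.
#'
#' @param config Named list (or path to a YAML file) with keys:
#'   `input` (character vector of file paths), `dialect`
#'   (`"auto"`/`"bioscreen_csv"`/`"tab_generic"`), `blank` (number,
#'   default 0), `calibration` (list with `c` or `species`),
#'   `monotonic_filter` (logical, default TRUE), `rate_method`
#'   (`"default"`/`"regression"`), `qi` (list: `flag_fraction`,
#'   `slope_threshold`, optional `reference_file` — a TSV of reference
#'   quality-index distributions with columns qi1..qi4), `output_dir`,
#'   `products` (subset of raw/processed/derivative/fitness; default
#'   all), `excluded_wells` (integer vector).
#' @param quiet Suppress per-curve log lines (default FALSE).
#' @return Invisibly, a named list of [growth_fit] objects, one per
#'   input file.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config))
      og_stop("odgrowth_config_error", paste("config file not found:", config))
    if (!requireNamespace("yaml", quietly = TRUE))
      og_stop("odgrowth_config_error", "the 'yaml' package is needed to read YAML configs")
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  if (is.null(cfg$input) || length(cfg$input) == 0L)
    og_stop("odgrowth_config_error", "config must name at least one input file")
  missing_in <- cfg$input[!file.exists(cfg$input)]
  if (length(missing_in))
    og_stop("odgrowth_input_not_found",
            paste("input file(s) not found:", paste(missing_in, collapse = ", ")))
  dialect <- cfg$dialect %||% "auto"
  blank <- cfg$blank %||% 0
  monotonic <- cfg$monotonic_filter %||% TRUE
  rate_method <- cfg$rate_method %||% "default"
  flag_fraction <- cfg$qi$flag_fraction %||% 0.05
  slope_threshold <- cfg$qi$slope_threshold %||% 0.07
  if (flag_fraction <= 0 || flag_fraction >= 1)
    og_stop("odgrowth_config_error", "qi.flag_fraction must be in (0, 1)")
  products <- cfg$products %||% c("raw", "processed", "derivative", "fitness")
  out_dir <- cfg$output_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  excluded <- as.integer(cfg$excluded_wells %||% integer())

  model <- if (!is.null(cfg$calibration$c))
    calibration_model(c = cfg$calibration$c, blank = blank, label = "config")
  else
    calibration_preset(cfg$calibration$species %||% "S. cerevisiae", blank = blank)

  thresholds <- NULL
  if (!is.null(cfg$qi$reference_file)) {
    if (!file.exists(cfg$qi$reference_file))
      og_stop("odgrowth_input_not_found",
              paste("QI reference file not found:", cfg$qi$reference_file))
    ref <- utils::read.delim(cfg$qi$reference_file)
    thresholds <- compute_thresholds(ref, flag_fraction)
  }

  log_line <- function(...) if (!quiet) message(sprintf(...))
  fits <- list()
  for (path in cfg$input) {
    run <- parse_growth_file(path, dialect = dialect)
    fit <- growth_fit(run, calibration = model, monotonic = monotonic,
                      rate_method = rate_method,
                      flag_fraction = flag_fraction,
                      thresholds = thresholds,
                      slope_threshold = slope_threshold)
    stem <- sub("\\.[^.]*$", "", basename(path))
    for (p in intersect(products, c("raw", "processed", "derivative", "fitness")))
      write_export(fit, product = p,
                   file = file.path(out_dir, paste0(stem, "_", p, ".tsv")),
                   excluded_wells = excluded)
    for (i in seq_len(nrow(fit$table))) {
      row <- fit$table[i, ]
      reasons <- fit$traits[[i]]$reasons
      bad <- reasons[reasons != ""]
      log_line("%s well %d: lag=%s h DT=%s h eff=%s QI=[%s] flags=[%s]%s",
               stem, row$well,
               formatC(row$lag_h, digits = 4, format = "g"),
               formatC(row$doubling_time_h, digits = 4, format = "g"),
               formatC(row$efficiency, digits = 4, format = "g"),
               paste(formatC(c(row$qi1, row$qi2, row$qi3, row$qi4),
                             digits = 3, format = "g"), collapse = " "),
               row$flags,
               if (length(bad)) paste0(" (", paste(names(bad), bad,
                                                   sep = ": ", collapse = "; "), ")")
               else "")
    }
    log_line("%s: wrote %s to %s", stem, paste(products, collapse = ", "), out_dir)
    fits[[stem]] <- fit
  }
  invisible(fits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
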