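## Classed conditions so callers (and tests) can distinguish failure modes.

og_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "odgrowth_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

og_warn <- function(class, msg) {
  warning(structure(
    class = c(class, "odgrowth_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_finite_numeric <- function(x) is.numeric(x) && all(is.finite(x))
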