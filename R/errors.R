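# Classed conditions so callers (and tests) can distinguish failure modes.

#' @keywords internal
msl_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "msl_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' @keywords internal
msl_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}
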