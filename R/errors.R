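# Structured conditions so callers can distinguish failure modes
# (classed as cardiowave_error_<what> / cardiowave_error).

cw_abort <- function(what, message, call = sys.call(-1), ...) {
  cond <- structure(
    class = c(paste0("cardiowave_error_", what), "cardiowave_error",
              "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

cw_warn <- function(what, message, ...) {
  cond <- structure(
    class = c(paste0("cardiowave_warning_", what), "cardiowave_warning",
              "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  warning(cond)
}
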