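## Internal condition helpers: all package errors carry class
## "microseg_error" plus a specific subclass so callers can
## distinguish e.g. a missing optional backend from a bad input.

abort_microseg <- function(message, class = "microseg_error", call. = FALSE) {
  stop(structure(
    class = c(class, "microseg_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

abort_shape <- function(message) abort_microseg(message, "microseg_shape_error")

abort_dependency <- function(message) {
  abort_microseg(message, "microseg_dependency_error")
}
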