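# Classed conditions so callers can branch on failure kind rather than
# matching message text.

sssom_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "sssom_error", "error")))
}

sssom_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "sssom_warning", "warning")))
}
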