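# Structured condition helpers. Every validation failure carries a specific
# class plus the offending field, so callers can dispatch on failure category
# instead of matching message text.

usnp_stop <- function(message, class, field = NULL, call = sys.call(-1)) {
  stop(errorCondition(
    message,
    field = field,
    class = c(class, "usnp_validation_error", "usnp_error")
  ))
}

usnp_warn <- function(message, class, field = NULL) {
  warning(warningCondition(message, field = field, class = c(class, "usnp_warning")))
}
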