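# Classed conditions so callers can distinguish failure modes programmatically.
# Every error thrown by this package carries the "lipotyper_error" class plus a
# specific subclass (e.g. "unknown_class_error").

lt_stop <- function(subclass, msg, call = sys.call(-1), ...) {
  stop(errorCondition(msg, ..., class = c(subclass, "lipotyper_error"),
                      call = call))
}

lt_warn <- function(subclass, msg, ...) {
  warning(warningCondition(msg, ..., class = c(subclass, "lipotyper_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
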