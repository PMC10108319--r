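# Classed conditions so callers can distinguish failure modes programmatically.
# Every error inherits from "lnrrmiss_error"; the specific class encodes the
# contract that was violated (missing SD, non-ratio-scale mean, ...).

lnrr_error <- function(class, message, call = sys.call(-1), ...) {
  stop(errorCondition(
    message,
    ...,
    class = c(paste0("lnrrmiss_", class), "lnrrmiss_error", "error", "condition"),
    call = call
  ))
}

lnrr_warning <- function(class, message, ...) {
  warning(warningCondition(
    message,
    ...,
    class = c(paste0("lnrrmiss_", class), "lnrrmiss_warning", "warning", "condition")
  ))
}
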