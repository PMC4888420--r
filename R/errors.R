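# Classed conditions so callers can distinguish failure modes programmatically.
# Every error raised by this package carries class c("odmsem_<kind>", "odmsem_error").

odm_error <- function(kind, msg, ...) {
  stop(errorCondition(msg,
    class = c(paste0("odmsem_", kind), "odmsem_error", "error", "condition"),
    ...
  ))
}
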