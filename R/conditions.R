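# Classed conditions used by the kinetics stage so that per-pixel failures
# can be converted into invalid records (with a reason code) instead of
# aborting a whole-map computation.

stop_kinetics <- function(reason, message) {
  cond <- structure(
    class = c("cbf_kinetics_error", "error", "condition"),
    list(message = message, call = sys.call(-1), reason = reason)
  )
  stop(cond)
}

kinetics_reason <- function(e) {
  if (inherits(e, "cbf_kinetics_error")) e$reason else "error"
}
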