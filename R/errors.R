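# Typed condition helpers. Every user-facing failure mode has its own
# condition class ("lightdose_error_<kind>") so callers and the batch layer
# can react without matching on message text.

ld_stop <- function(kind, msg, ...) {
  stop(structure(
    class = c(paste0("lightdose_error_", kind), "lightdose_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

ld_assert <- function(cond, kind, msg, ...) {
  if (!isTRUE(cond)) ld_stop(kind, msg, ...)
  invisible(TRUE)
}
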