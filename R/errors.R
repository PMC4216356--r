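# Classed conditions so callers (and the CLI) can map failure modes to
# distinct exit codes without parsing message text.

escore_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("edemascore_", class, "_error"), "edemascore_error",
              "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_validation <- function(msg) escore_error(msg, "validation")
abort_input      <- function(msg) escore_error(msg, "input")
abort_io         <- function(msg) escore_error(msg, "io")
abort_pairing    <- function(msg) escore_error(msg, "pairing")
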