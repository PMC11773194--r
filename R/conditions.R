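# Structured error conditions. Every error raised by the package carries a
# stable machine-readable code (e.g. "E_DUP_NODE") as its first condition
# class, so callers and the command-line front end can dispatch on it.

im_stop <- function(code, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(code, "im_error", "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
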