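# Internal error helper: user-facing validation errors carry the class
# "mnsd_error" so the command-line wrapper can map them to exit code 1.
mnsd_stop <- function(..., call. = FALSE) {
  stop(structure(class = c("mnsd_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Format a numeric so that read-back with as.numeric() is bit-exact.
fmt_num <- function(x) sprintf("%.17g", x)
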