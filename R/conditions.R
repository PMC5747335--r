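# Classed conditions so callers (and the command-line layer) can map
# failure categories to exit codes without string matching.

ts_abort <- function(class, msg, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(paste0("toolscribe_", class), "toolscribe_error",
              "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), extra)
  )
  stop(cond)
}

ts_warn <- function(class, msg) {
  cond <- structure(
    class = c(paste0("toolscribe_", class), "toolscribe_warning",
              "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  warning(cond)
}

# Logging goes to stderr; data outputs never do.
ts_log <- function(..., verbose = getOption("toolscribe.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[toolscribe] ", ...)
  invisible(NULL)
}
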