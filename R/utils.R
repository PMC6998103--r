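# Classed conditions used across the pipeline: validation errors (bad
# inputs or config), I/O errors (missing/unwritable paths) and compute
# errors (a stage failed on valid-looking data). Downstream drivers
# signal these so callers can branch on condition class.

abort_validation <- function(message, ...) {
  rlang::abort(message, class = "rccpanel_validation_error", ...)
}

abort_io <- function(message, ...) {
  rlang::abort(message, class = "rccpanel_io_error", ...)
}

abort_compute <- function(message, ...) {
  rlang::abort(message, class = "rccpanel_compute_error", ...)
}

`%||%` <- rlang::`%||%`

# Collapse a character vector to "a, b, c" for messages, capped.
oxford <- function(x, max = 5L) {
  x <- as.character(x)
  if (length(x) > max) {
    x <- c(head(x, max), sprintf("... (%d more)", length(x) - max))
  }
  paste(x, collapse = ", ")
}
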