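# Classed conditions so callers (and tests) can dispatch on failure kind
# rather than on message text.

gg_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("geogain_error_", class), "geogain_error")))
}

gg_warn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(paste0("geogain_warning_", class), "geogain_warning")))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    gg_stop("config", "'%s' must be a single finite number", name)
  if (positive && x <= 0)
    gg_stop("config", "'%s' must be > 0 (got %g)", name, x)
  invisible(x)
}
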