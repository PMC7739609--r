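# Classed error conditions: every contract violation raised by the package
# carries class "exerstep_<Code>" so callers (and tests) can match on the
# code rather than on message text.

stop_exerstep <- function(code, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("exerstep_", code), "exerstep_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

#' @noRd
is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is_scalar_number(x)) {
    stop_exerstep("ConfigError", sprintf("`%s` must be a single finite number", name))
  }
  ok <- if (strict) x > min else x >= min
  if (!ok) {
    stop_exerstep("ConfigError", sprintf(
      "`%s` must be %s %s", name, if (strict) ">" else ">=", format(min)
    ))
  }
  invisible(x)
}

match_level <- function(x, choices, name) {
  if (!is.character(x) || length(x) != 1L || !x %in% choices) {
    stop_exerstep("ConfigError", sprintf(
      "`%s` must be one of: %s", name, paste(choices, collapse = ", ")
    ))
  }
  x
}
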