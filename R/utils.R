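#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

#' Validate that a value is a single finite number
#' @noRd
check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop_domain(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    stop_domain(sprintf("'%s' must be > 0 (got %g)", name, x))
  if (nonneg && x < 0)
    stop_domain(sprintf("'%s' must be >= 0 (got %g)", name, x))
  invisible(x)
}

# Structured per-stage log line; suppressible via options(dietquality.quiet = TRUE)
dq_log <- function(fmt, ...) {
  if (!isTRUE(getOption("dietquality.quiet", FALSE)))
    message(sprintf(fmt, ...))
  invisible(NULL)
}
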