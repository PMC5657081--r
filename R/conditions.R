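# Typed conditions. Every error raised by the package carries class
# "torsionrig_error" plus a stage-specific subclass, so pipeline callers can
# distinguish configuration problems from estimation failures.

tr_abort <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "torsionrig_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

tr_config_error     <- function(message, ...) tr_abort(message, "torsionrig_config_error", ...)
tr_data_error       <- function(message, ...) tr_abort(message, "torsionrig_data_error", ...)
tr_io_error         <- function(message, ...) tr_abort(message, "torsionrig_io_error", ...)
tr_estimation_error <- function(message, ...) tr_abort(message, "torsionrig_estimation_error", ...)
tr_degenerate_error <- function(message, ...) tr_abort(message, "torsionrig_degenerate_error", ...)

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    tr_config_error(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    tr_config_error(sprintf("`%s` must be strictly positive (got %g)", name, x))
  if (nonneg && x < 0)
    tr_config_error(sprintf("`%s` must be non-negative (got %g)", name, x))
  invisible(x)
}
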