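#' A sampled torsion trace
#'
#' One machine record of a cyclic torsion test: time (uniform grid), applied
#' torque and recorded actuator angle, with the loading protocol as optional
#' metadata. Canonical units: s, Nm, degree.
#'
#' @param time Strictly increasing sample times on a uniform grid, s.
#' @param torque Torque, Nm.
#' @param angle Actuator angle, degrees.
#' @param protocol Optional [load_protocol()] metadata (required for
#'   phase-based cycle segmentation).
#' @return An object of class `torsion_trace`.
#' @export
torsion_trace <- function(time, torque, angle, protocol = NULL) {
  n <- length(time)
  if (length(torque) != n || length(angle) != n)
    tr_data_error("time, torque and angle must have equal lengths")
  if (n < 2L) tr_data_error("a trace needs at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0)) tr_data_error("trace time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9)
    tr_data_error("trace time grid must be uniform to within 1e-9 s")
  if (!is.null(protocol) && !inherits(protocol, "load_protocol"))
    tr_config_error("`protocol` must be a load_protocol or NULL")
  structure(
    list(time = as.numeric(time), torque = as.numeric(torque),
         angle = as.numeric(angle), protocol = protocol),
    class = "torsion_trace"
  )
}

#' @export
print.torsion_trace <- function(x, ...) {
  cat(sprintf("<torsion_trace> %d samples, %.4g s, rate %.4g Hz\n",
              length(x$time), max(x$time) - min(x$time),
              1 / (x$time[2] - x$time[1])))
  if (!is.null(x$protocol))
    cat(sprintf("  protocol: +/-%g Nm at %g Hz, %d cycles\n",
                x$protocol$torque_amplitude, x$protocol$frequency,
                x$protocol$n_cycles))
  invisible(x)
}

#' Segment a trace into loading cycles
#'
#' Cycles are located by protocol phase, not peak detection: cycle k spans
#' `t` in `[(k-1)/f, k/f)`. Windows are half-open sample-index ranges
#' `[start, end)` that tile the trace without overlap.
#'
#' @param trace A [torsion_trace()] with protocol metadata.
#' @return A tibble with columns `cycle_index`, `start`, `end` (1-based,
#'   `end` exclusive).
#' @export
segment_cycles <- function(trace) {
  if (!inherits(trace, "torsion_trace")) tr_config_error("`trace` must be a torsion_trace")
  if (is.null(trace$protocol))
    tr_config_error("trace has no protocol metadata; cannot segment by phase")
  rate <- 1 / (trace$time[2] - trace$time[1])
  spc <- rate / trace$protocol$frequency
  if (abs(spc - round(spc)) > 1e-6)
    tr_config_error("sample rate is not an integer multiple of the loading frequency")
  spc <- as.integer(round(spc))
  n_win <- length(trace$time) %/% spc
  if (n_win < 1L)
    tr_data_error("trace is shorter than one full loading cycle")
  tibble::tibble(
    cycle_index = seq_len(n_win),
    start = (seq_len(n_win) - 1L) * spc + 1L,
    end = seq_len(n_win) * spc + 1L
  )
}

window_indices <- function(trace, window) {
  start <- window$start[1]; end <- window$end[1]
  if (is.null(start) || is.null(end) || end <= start)
    tr_config_error("window must have start < end")
  if (start < 1L || end - 1L > length(trace$time))
    tr_data_error("window lies outside the trace")
  seq.int(start, end - 1L)
}

#' Gross angular displacement of one cycle
#'
#' Full-cycle peak-to-peak rotation: the maximum minus the minimum recorded
#' angle over the window. For a sign-symmetric cycle this equals the maximum
#' plus the magnitude of the minimum.
#'
#' @param trace A [torsion_trace()].
#' @param window One row of [segment_cycles()] output (or any list with
#'   `start`/`end`).
#' @return Displacement in degrees, >= 0.
#' @export
gross_cycle_displacement <- function(trace, window) {
  idx <- window_indices(trace, window)
  if (length(idx) < 2L)
    tr_data_error("window must contain at least 2 samples")
  a <- trace$angle[idx]
  max(a) - min(a)
}

#' Decimate a trace to an analysis sample rate
#'
#' Reduces the machine stream (1000 Hz by default) to an analysis rate at
#' which a 10-point regression window spans a mechanically meaningful arc.
#' `method = "mean"` (default) averages each block of `rate/to` samples,
#' which also attenuates angle noise by the square root of the block length
#' (anti-aliasing); `method = "subsample"` keeps every block's last sample.
#'
#' @param trace A [torsion_trace()].
#' @param to Target rate, Hz; must divide the current rate and keep an
#'   integer number of samples per loading cycle.
#' @param method `"mean"` or `"subsample"`.
#' @return A decimated [torsion_trace()] (protocol metadata updated).
#' @export
decimate_trace <- function(trace, to = 25, method = c("mean", "subsample")) {
  if (!inherits(trace, "torsion_trace")) tr_config_error("`trace` must be a torsion_trace")
  method <- match.arg(method)
  rate <- 1 / (trace$time[2] - trace$time[1])
  fac <- rate / to
  if (abs(fac - round(fac)) > 1e-6 || fac < 1)
    tr_config_error(sprintf("target rate %g Hz must divide the trace rate %g Hz", to, rate))
  fac <- as.integer(round(fac))
  if (fac == 1L) return(trace)
  n <- (length(trace$time) %/% fac) * fac
  blk <- function(v) {
    m <- matrix(v[seq_len(n)], nrow = fac)
    if (method == "mean") colMeans(m) else m[fac, ]
  }
  proto <- trace$protocol
  if (!is.null(proto)) proto$sample_rate <- to
  torsion_trace(blk(trace$time), blk(trace$torque), blk(trace$angle),
                protocol = proto)
}
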