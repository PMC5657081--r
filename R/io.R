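detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!length(hdr)) tr_io_error(sprintf("'%s' is empty", path))
  if (grepl("\t", hdr)) "\t" else ","
}

read_delim_checked <- function(path, required, what) {
  if (!file.exists(path)) tr_io_error(sprintf("file '%s' does not exist", path))
  sep <- detect_sep(path)
  df <- tryCatch(read.csv(path, sep = sep, stringsAsFactors = FALSE),
                 error = function(e) tr_io_error(sprintf(
                   "cannot parse %s file '%s': %s", what, path, conditionMessage(e))))
  miss <- setdiff(required, names(df))
  if (length(miss))
    tr_io_error(sprintf("%s file '%s' is missing column(s): %s",
                        what, path, paste(miss, collapse = ", ")))
  if (!nrow(df)) tr_io_error(sprintf("%s file '%s' has no data rows", what, path))
  df
}

check_numeric_cols <- function(df, cols, path) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v))
    if (length(bad))
      tr_io_error(sprintf("'%s': unparseable value in column '%s' at data line %d",
                          path, cl, bad[1]))
    df[[cl]] <- v
  }
  df
}

#' Read a torsion trace from delimited text
#'
#' Expects header columns `time_s`, `torque_Nm`, `angle_deg` (comma- or
#' tab-separated, decimal point). Units are converted to the canonical
#' s / Nm / degree at this boundary; radian input is flagged via
#' `angle_unit = "rad"`.
#'
#' @param path File path.
#' @param protocol Optional [load_protocol()] to attach as metadata.
#' @param angle_unit `"deg"` (default) or `"rad"`.
#' @return A [torsion_trace()].
#' @export
read_trace <- function(path, protocol = NULL, angle_unit = c("deg", "rad")) {
  angle_unit <- match.arg(angle_unit)
  df <- read_delim_checked(path, c("time_s", "torque_Nm", "angle_deg"), "trace")
  df <- check_numeric_cols(df, c("time_s", "torque_Nm", "angle_deg"), path)
  if (any(diff(df$time_s) <= 0))
    tr_io_error(sprintf("'%s': time_s is not strictly increasing (first violation after data line %d)",
                        path, which(diff(df$time_s) <= 0)[1]))
  ang <- df$angle_deg
  if (angle_unit == "rad") ang <- ang * 180 / pi
  torsion_trace(df$time_s, df$torque_Nm, ang, protocol = protocol)
}

#' Write a torsion trace as CSV
#'
#' @param trace A [torsion_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "torsion_trace")) tr_config_error("`trace` must be a torsion_trace")
  df <- data.frame(time_s = format(trace$time, digits = 17),
                   torque_Nm = format(trace$torque, digits = 17),
                   angle_deg = format(trace$angle, digits = 17))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read marker trajectories from delimited text
#'
#' Expects columns `time_s`, `marker_id`, `label`, `segment`, `x_mm`,
#' `y_mm`, `z_mm`; one trajectory is built per `marker_id`. Labels and
#' segments are validated against the cranial/caudal/lateral/medial and
#' epiphysis/diaphysis/reference vocabularies; duplicate (time, marker) rows
#' and non-increasing times are rejected.
#'
#' @param path File path.
#' @return A `marker_set`.
#' @export
read_markers <- function(path) {
  df <- read_delim_checked(
    path, c("time_s", "marker_id", "label", "segment", "x_mm", "y_mm", "z_mm"),
    "marker")
  df <- check_numeric_cols(df, c("time_s", "x_mm", "y_mm", "z_mm"), path)
  key <- paste(df$marker_id, df$time_s)
  if (anyDuplicated(key))
    tr_io_error(sprintf("'%s': duplicate (time, marker) row at data line %d",
                        path, which(duplicated(key))[1]))
  out <- list()
  for (id in unique(df$marker_id)) {
    sub <- df[df$marker_id == id, ]
    if (length(unique(sub$label)) != 1L || length(unique(sub$segment)) != 1L)
      tr_io_error(sprintf("'%s': marker '%s' has inconsistent label/segment", path, id))
    traj <- tryCatch(
      marker_trajectory(id, sub$label[1], sub$segment[1], sub$time_s,
                        cbind(sub$x_mm, sub$y_mm, sub$z_mm)),
      torsionrig_error = function(e) tr_io_error(sprintf("'%s': %s", path,
                                                         conditionMessage(e))))
    out[[id]] <- traj
  }
  structure(out, class = "marker_set")
}

#' Write marker trajectories as CSV
#'
#' @param markers A `marker_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  rows <- lapply(markers, function(m) {
    data.frame(time_s = format(m$time, digits = 17), marker_id = m$marker_id,
               label = m$label, segment = m$segment,
               x_mm = format(m$position[, 1], digits = 17),
               y_mm = format(m$position[, 2], digits = 17),
               z_mm = format(m$position[, 3], digits = 17))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
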