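#' Torsion axis
#'
#' The axis about which rotation angles are measured: a point on the axis and
#' a unit direction (the machine vertical in the rig frame).
#'
#' @param point Numeric length-3, a point on the axis (mm).
#' @param direction Numeric length-3; normalised internally, must be nonzero.
#' @return An object of class `torsion_axis`.
#' @export
torsion_axis <- function(point = c(0, 0, 0), direction = c(0, 0, 1)) {
  point <- as.numeric(point); direction <- as.numeric(direction)
  if (length(point) != 3L || length(direction) != 3L)
    tr_config_error("`point` and `direction` must have length 3")
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0)
    tr_config_error("`direction` must be a nonzero vector")
  structure(list(point = point, direction = direction / nrm),
            class = "torsion_axis")
}

#' Estimate the torsion axis from static markers
#'
#' The rig's torsion axis is the machine vertical; only its in-plane position
#' needs estimating. Returns the +z axis through the time-averaged centroid
#' of the static (diaphyseal and pot reference) markers.
#'
#' @param markers A `marker_set` (or list of [marker_trajectory()] objects);
#'   at least 3 static markers (segment `"diaphysis"` or `"reference"`) are
#'   required.
#' @return A [torsion_axis()].
#' @export
estimate_axis <- function(markers) {
  static <- Filter(function(m) m$segment %in% c("diaphysis", "reference"), markers)
  if (length(static) < 3L)
    tr_data_error("axis estimation needs at least 3 static (diaphyseal or reference) markers")
  cent <- colMeans(do.call(rbind, lapply(static, function(m) colMeans(m$position))))
  torsion_axis(point = cent, direction = c(0, 0, 1))
}

project_radial <- function(p, axis) {
  v <- p - axis$point
  v - sum(v * axis$direction) * axis$direction
}

#' Rotation angle between two marker positions about an axis
#'
#' Projects both positions onto the plane perpendicular to the axis through
#' its point, then combines the Euclidean chord between the projections with
#' the Law of Cosines on the two projected radii:
#' \deqn{\phi = \arccos\!\big((r_1^2 + r_2^2 - d^2) / (2 r_1 r_2)\big).}
#' Axial translation is removed by the projection and cannot register as
#' rotation. The angle is unsigned (the Law of Cosines carries no sign).
#'
#' @param p_a,p_b Length-3 positions, mm.
#' @param axis A [torsion_axis()].
#' @param min_radius Smallest admissible projected radius, mm; below this the
#'   angle is numerically meaningless and a degenerate-geometry error is
#'   raised.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(p_a, p_b, axis, min_radius = 1) {
  if (!inherits(axis, "torsion_axis")) tr_config_error("`axis` must be a torsion_axis")
  u <- project_radial(as.numeric(p_a), axis)
  v <- project_radial(as.numeric(p_b), axis)
  r1 <- sqrt(sum(u^2)); r2 <- sqrt(sum(v^2))
  if (r1 < min_radius || r2 < min_radius)
    tr_degenerate_error(sprintf(
      "projected radius below %g mm (got %.3g and %.3g): marker too close to the axis",
      min_radius, r1, r2))
  d2 <- sum((u - v)^2)
  arg <- (r1^2 + r2^2 - d2) / (2 * r1 * r2)
  arg <- min(1, max(-1, arg))
  acos(arg) * 180 / pi
}

axis_basis <- function(axis) {
  d <- axis$direction
  seed <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

#' Full-cycle rotational displacement of one marker
#'
#' Finds, within the time span, the two samples at which the marker's own
#' angular coordinate about the axis is extremal (its within-cycle rotation
#' peaks -- using the marker's own phase tolerates slippage-induced lag
#' against the actuator), and returns the [rotation_angle()] between the
#' positions at those two samples.
#'
#' @param traj A [marker_trajectory()].
#' @param t_start,t_end Time span, s (half-open `[t_start, t_end)`).
#' @param axis A [torsion_axis()].
#' @param min_radius Passed to [rotation_angle()].
#' @param smooth Odd moving-average window (samples) used only to *locate*
#'   the angular extremes; the rotation is computed from the raw positions at
#'   the located samples, so exact rigid rotations are still recovered to
#'   machine precision. Without smoothing, coordinate noise systematically
#'   inflates the peak-to-peak estimate (the extremes of a noisy series
#'   overshoot the signal extremes). Default `NULL`: one tenth of the span
#'   (safe for near-sinusoidal motion, whose extremes are flat); 1 disables
#'   smoothing.
#' @return Peak-to-peak rotation in degrees.
#' @export
marker_cycle_displacement <- function(traj, t_start, t_end, axis, min_radius = 1,
                                      smooth = NULL) {
  if (!inherits(traj, "marker_trajectory"))
    tr_config_error("`traj` must be a marker_trajectory")
  sel <- which(traj$time >= t_start & traj$time < t_end)
  if (length(sel) < 4L)
    tr_data_error(sprintf("marker '%s': fewer than 4 samples in [%g, %g)",
                          traj$marker_id, t_start, t_end))
  if (is.null(smooth)) {
    smooth <- max(1L, as.integer(length(sel) / 10))
    if (smooth %% 2L == 0L) smooth <- smooth + 1L
  }
  if (smooth < 1 || smooth %% 2 != 1)
    tr_config_error("`smooth` must be an odd integer >= 1")
  basis <- axis_basis(axis)
  rel <- sweep(traj$position[sel, , drop = FALSE], 2, axis$point)
  pu <- rel %*% basis$u
  pv <- rel %*% basis$v
  theta <- atan2(pv, pu)
  # unwrap so extremes are found on a continuous angular coordinate
  theta <- theta[1] + c(0, cumsum(((diff(theta) + pi) %% (2 * pi)) - pi))
  k <- min(smooth, length(theta) - (1 - length(theta) %% 2))
  if (k > 1L) {
    half <- (k - 1L) %/% 2L
    padded <- c(rep(theta[1], half), theta, rep(theta[length(theta)], half))
    theta <- as.numeric(stats::filter(padded, rep(1 / k, k), sides = 2))
    theta <- theta[(half + 1L):(half + length(sel))]
  }
  i_min <- sel[which.min(theta)]
  i_max <- sel[which.max(theta)]
  rotation_angle(traj$position[i_min, ], traj$position[i_max, ], axis,
                 min_radius = min_radius)
}

#' Epiphysis-relative-to-diaphysis displacement
#'
#' Isolates peri-fragmental motion by subtracting the (near-static)
#' diaphyseal rotation from the epiphyseal rotation measured in the same
#' cycle about the same axis.
#'
#' @param epi_angle,dia_angle Rotation angles, degrees.
#' @return `epi_angle - dia_angle`, degrees.
#' @export
relative_displacement <- function(epi_angle, dia_angle) epi_angle - dia_angle

#' Per-marker, per-cycle rotational displacement of a marker set
#'
#' Computes the full-cycle rotation of every epiphyseal marker for the
#' selected loading cycles, plus the mean diaphyseal rotation in the same
#' cycle and the epiphysis-relative displacement.
#'
#' @param markers A `marker_set` from [generate_markers()] or
#'   [read_markers()].
#' @param frequency Loading frequency, Hz (defines the cycle time spans).
#' @param cycles Cycle indices to analyse.
#' @param axis Optional [torsion_axis()]; estimated from the static markers
#'   when `NULL`.
#' @return A tibble with columns `marker_id`, `label`, `cycle`,
#'   `displacement`, `dia_displacement`, `relative`.
#' @export
analyze_markers <- function(markers, frequency = 0.5, cycles = c(60, 120, 180),
                            axis = NULL) {
  if (is.null(axis)) axis <- estimate_axis(markers)
  epi <- Filter(function(m) m$segment == "epiphysis", markers)
  dia <- Filter(function(m) m$segment == "diaphysis", markers)
  if (!length(epi)) tr_data_error("marker set contains no epiphyseal markers")
  rows <- list()
  for (k in cycles) {
    t0 <- (k - 1) / frequency; t1 <- k / frequency
    dia_disp <- if (length(dia)) {
      mean(vapply(dia, marker_cycle_displacement, numeric(1),
                  t_start = t0, t_end = t1, axis = axis))
    } else 0
    for (m in epi) {
      disp <- marker_cycle_displacement(m, t0, t1, axis)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        marker_id = m$marker_id, label = m$label, cycle = k,
        displacement = disp, dia_displacement = dia_disp,
        relative = relative_displacement(disp, dia_disp))
    }
  }
  do.call(rbind, rows)
}
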