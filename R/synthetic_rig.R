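#' Cyclic torsion loading protocol
#'
#' Describes the machine loading programme: a sinusoidal torque of amplitude
#' `torque_amplitude` at `frequency` for `n_cycles` cycles, sampled at
#' `sample_rate`. The defaults are the reference experiment's protocol:
#' +/-2 Nm at 0.5 Hz for 250 cycles, actuator angle logged every millisecond,
#' under a constant 20 N axial preload (metadata only; the preload engages the
#' physeal topography but does not enter the torque signal).
#'
#' @param torque_amplitude Peak torque, Nm.
#' @param frequency Loading frequency, Hz.
#' @param n_cycles Number of full loading cycles.
#' @param sample_rate Machine sampling rate, Hz. Must give an integer number
#'   of samples per cycle.
#' @param axial_preload Constant axial compression, N (metadata).
#' @return An object of class `load_protocol`.
#' @export
#' @examples
#' load_protocol()
load_protocol <- function(torque_amplitude = 2, frequency = 0.5, n_cycles = 250,
                          sample_rate = 1000, axial_preload = 20) {
  stopifnot_scalar_num(torque_amplitude, "torque_amplitude", positive = TRUE)
  stopifnot_scalar_num(frequency, "frequency", positive = TRUE)
  stopifnot_scalar_num(n_cycles, "n_cycles", positive = TRUE)
  stopifnot_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  stopifnot_scalar_num(axial_preload, "axial_preload", positive = TRUE)
  if (n_cycles != round(n_cycles))
    tr_config_error("`n_cycles` must be an integer")
  structure(
    list(torque_amplitude = torque_amplitude, frequency = frequency,
         n_cycles = as.integer(n_cycles), sample_rate = sample_rate,
         axial_preload = axial_preload),
    class = "load_protocol"
  )
}

#' True mechanical parameters of one fixation construct
#'
#' Parameterises the sigmoidal torque-angle backbone of a pinned physeal
#' fracture construct: terminal torsional stiffness, total interfragmentary
#' toggle (the near-zero-stiffness band around zero load), and the torque
#' scale over which the construct transitions from toggling to the stiff
#' terminal limbs.
#'
#' @param stiffness_true Terminal stiffness, Nm/degree.
#' @param toggle_true Total toggle, degrees (x-axis gap between the two
#'   terminal lines).
#' @param transition_torque Sigmoid sharpness, Nm; small values give an
#'   abrupt toggle-to-stiff transition.
#' @param angle_noise_sd SD of additive Gaussian noise on the recorded
#'   actuator angle, degrees.
#' @param pin_group `"one"`, `"two"` or `"three"` pins.
#' @return An object of class `construct_params`.
#' @export
construct_params <- function(stiffness_true, toggle_true,
                             transition_torque = 0.2, angle_noise_sd = 0.02,
                             pin_group = c("three", "two", "one")) {
  stopifnot_scalar_num(stiffness_true, "stiffness_true", positive = TRUE)
  stopifnot_scalar_num(toggle_true, "toggle_true", nonneg = TRUE)
  stopifnot_scalar_num(transition_torque, "transition_torque", positive = TRUE)
  stopifnot_scalar_num(angle_noise_sd, "angle_noise_sd", nonneg = TRUE)
  pin_group <- match.arg(pin_group)
  structure(
    list(stiffness_true = stiffness_true, toggle_true = toggle_true,
         transition_torque = transition_torque,
         angle_noise_sd = angle_noise_sd, pin_group = pin_group),
    class = "construct_params"
  )
}

#' Marker rig geometry
#'
#' Geometry of the retro-reflective marker set: four epiphyseal markers
#' (cranial, lateral, caudal, medial) on the mobile fragment, four diaphyseal
#' markers on the shaft, and eight reference markers on the two moulding pots.
#' Epiphyseal marker m rotates about the +z torsion axis by
#' `rotation_share[m] * bone_angle`, where the bone's interfragmentary angle
#' is the actuator angle divided by `slippage_factor` (>= 1; slip at the
#' friction-held mould-epiphysis interface makes the machine read more
#' rotation than the bone performs).
#'
#' @param marker_radius Distance of each marker from the torsion axis, mm.
#' @param marker_height Named heights (mm, along +z) for the `epiphysis`,
#'   `diaphysis`, `pot_top` and `pot_bottom` marker rings.
#' @param rotation_share Named vector (cranial, lateral, caudal, medial) of
#'   per-marker rotation fractions; see [default_marker_shares()].
#' @param slippage_factor Actuator angle divided by bone angle, >= 1.
#' @param position_noise_sd SD of Gaussian noise per marker coordinate, mm.
#' @param marker_rate Motion-capture sampling rate, Hz (independent of the
#'   machine stream).
#' @return An object of class `rig_geometry`.
#' @export
rig_geometry <- function(marker_radius = 30,
                         marker_height = c(epiphysis = 200, diaphysis = 120,
                                           pot_top = 250, pot_bottom = 20),
                         rotation_share = default_marker_shares(),
                         slippage_factor = 2.6,
                         position_noise_sd = 0.1,
                         marker_rate = 100) {
  stopifnot_scalar_num(marker_radius, "marker_radius", positive = TRUE)
  stopifnot_scalar_num(slippage_factor, "slippage_factor")
  if (slippage_factor < 1)
    tr_config_error("`slippage_factor` must be >= 1")
  stopifnot_scalar_num(position_noise_sd, "position_noise_sd", nonneg = TRUE)
  stopifnot_scalar_num(marker_rate, "marker_rate", positive = TRUE)
  labs <- c("cranial", "lateral", "caudal", "medial")
  if (!all(labs %in% names(rotation_share)))
    tr_config_error("`rotation_share` must be named with cranial, lateral, caudal, medial")
  if (any(rotation_share < 0))
    tr_config_error("`rotation_share` values must be >= 0")
  needed <- c("epiphysis", "diaphysis", "pot_top", "pot_bottom")
  if (!all(needed %in% names(marker_height)))
    tr_config_error("`marker_height` must name epiphysis, diaphysis, pot_top, pot_bottom")
  structure(
    list(marker_radius = marker_radius, marker_height = marker_height[needed],
         rotation_share = rotation_share[labs], slippage_factor = slippage_factor,
         position_noise_sd = position_noise_sd, marker_rate = marker_rate),
    class = "rig_geometry"
  )
}

#' Repeated-measures study design
#'
#' Each specimen is tested in the fixed order three -> two -> one pins (pins
#' are removed, never re-inserted), so the same bones appear in all groups.
#' Specimen- and marker-level random intercepts (degrees, on the toggle /
#' displacement scale) are drawn once per specimen and reused across its
#' three runs, giving the repeated-measures correlation structure the
#' mixed-effects analysis assumes.
#'
#' @param n_specimens Number of bones (>= 2); default 12.
#' @param groups Group order; fixed as three, two, one.
#' @param specimen_effect_sd SD of the per-specimen toggle intercept, degrees.
#' @param marker_effect_sd SD of per-marker displacement intercepts, degrees.
#' @param seed Integer seed for the whole study.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_specimens = 12,
                         groups = c("three", "two", "one"),
                         specimen_effect_sd = 1.2,
                         marker_effect_sd = 0.5,
                         seed = 1L) {
  stopifnot_scalar_num(n_specimens, "n_specimens", positive = TRUE)
  if (n_specimens < 2 || n_specimens != round(n_specimens))
    tr_config_error("`n_specimens` must be an integer >= 2")
  if (!identical(as.character(groups), c("three", "two", "one")))
    tr_config_error("group order is fixed as three, two, one (pins are removed in sequence)")
  stopifnot_scalar_num(specimen_effect_sd, "specimen_effect_sd", nonneg = TRUE)
  stopifnot_scalar_num(marker_effect_sd, "marker_effect_sd", nonneg = TRUE)
  stopifnot_scalar_num(seed, "seed")
  structure(
    list(n_specimens = as.integer(n_specimens), groups = as.character(groups),
         specimen_effect_sd = specimen_effect_sd,
         marker_effect_sd = marker_effect_sd, seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Noise-free torque-angle backbone of a construct
#'
#' The construct's quasi-static response is modelled as a smooth sigmoid:
#' \deqn{\theta(T) = T / k + (\tau/2) \tanh(T / T_0)}
#' with terminal stiffness `k`, total toggle `tau` and transition torque
#' `T_0`. The function is odd in `T`; as `|T|` grows the curve approaches the
#' terminal lines `T = k (\theta - \tau/2)` (loading) and
#' `T = k (\theta + \tau/2)` (unloading direction), whose x-axis gap is the
#' toggle. In the limit `T_0 -> 0` the curve degenerates to two parallel
#' lines separated by exactly `tau`.
#'
#' @param torque Torque, Nm (vectorised).
#' @param params A [construct_params()] object.
#' @return Angle in degrees, same length as `torque`.
#' @export
#' @examples
#' p <- construct_params(stiffness_true = 2, toggle_true = 6,
#'                       transition_torque = 0.5)
#' backbone_angle(1, p)  # 0.5 + 3 * tanh(2)
backbone_angle <- function(torque, params) {
  if (!inherits(params, "construct_params"))
    tr_config_error("`params` must be a construct_params object")
  torque / params$stiffness_true +
    (params$toggle_true / 2) * tanh(torque / params$transition_torque)
}

#' Simulate one cyclic torsion trace
#'
#' Generates the machine record of one test run: sinusoidal torque
#' `A sin(2 pi f t)` sampled at the protocol rate for `n_cycles / f` seconds,
#' with recorded angle equal to the backbone response plus seeded Gaussian
#' noise. The protocol is carried as trace metadata.
#'
#' @param protocol A [load_protocol()].
#' @param params A [construct_params()].
#' @param seed Integer seed; identical seeds give identical traces.
#' @return A [torsion_trace()] object.
#' @export
generate_trace <- function(protocol, params, seed = 1L) {
  if (!inherits(protocol, "load_protocol"))
    tr_config_error("`protocol` must be a load_protocol object")
  if (!inherits(params, "construct_params"))
    tr_config_error("`params` must be a construct_params object")
  spc <- protocol$sample_rate / protocol$frequency
  if (abs(spc - round(spc)) > 1e-9)
    tr_config_error(sprintf(
      "sample_rate/frequency must give an integer sample count per cycle (got %g)", spc))
  n <- as.integer(round(spc)) * protocol$n_cycles
  time <- seq(0, by = 1 / protocol$sample_rate, length.out = n)
  torque <- protocol$torque_amplitude * sin(2 * pi * protocol$frequency * time)
  angle <- backbone_angle(torque, params)
  if (params$angle_noise_sd > 0) {
    withr_seed <- function(expr) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      expr
    }
    angle <- angle + withr_seed(rnorm(n, 0, params$angle_noise_sd))
  }
  torsion_trace(time, torque, angle, protocol = protocol)
}

#' Simulate retro-reflective marker trajectories for one run
#'
#' Resamples the trace's actuator angle onto the motion-capture time grid,
#' divides by the slippage factor to obtain the bone's interfragmentary
#' angle, and rotates each epiphyseal marker about the +z torsion axis by its
#' rotation share of the bone angle. Diaphyseal and pot reference markers are
#' static up to coordinate noise. Positions are mm in a right-handed frame
#' with +z up the torsion axis; positive torque = external rotation =
#' positive angle.
#'
#' @param trace A [torsion_trace()] with protocol metadata.
#' @param geometry A [rig_geometry()].
#' @param params The [construct_params()] used for the trace (noise metadata).
#' @param seed Integer seed for marker coordinate noise.
#' @return A `marker_set`: named list of `marker_trajectory` objects (4
#'   epiphyseal, 4 diaphyseal, 8 reference).
#' @export
generate_markers <- function(trace, geometry, params, seed = 1L) {
  if (!inherits(trace, "torsion_trace")) tr_config_error("`trace` must be a torsion_trace")
  if (!inherits(geometry, "rig_geometry")) tr_config_error("`geometry` must be a rig_geometry")
  t_mk <- seq(0, max(trace$time), by = 1 / geometry$marker_rate)
  actuator <- approx(trace$time, trace$angle, xout = t_mk, rule = 2)$y
  bone_deg <- actuator / geometry$slippage_factor

  azimuth <- c(cranial = 0, lateral = 90, caudal = 180, medial = 270)
  r <- geometry$marker_radius
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  mk <- function(id, label, segment, height, phi_deg) {
    ang <- (azimuth[[label]] + phi_deg) * pi / 180
    pos <- cbind(x = r * cos(ang), y = r * sin(ang),
                 z = rep(height, length(t_mk)))
    if (geometry$position_noise_sd > 0)
      pos <- pos + matrix(rnorm(length(pos), 0, geometry$position_noise_sd),
                          ncol = 3L)
    marker_trajectory(id, label, segment, t_mk, pos)
  }

  out <- list()
  for (lab in names(azimuth)) {
    share <- geometry$rotation_share[[lab]]
    out[[paste0("epi_", lab)]] <- mk(paste0("epi_", lab), lab, "epiphysis",
                                     geometry$marker_height[["epiphysis"]],
                                     share * bone_deg)
    out[[paste0("dia_", lab)]] <- mk(paste0("dia_", lab), lab, "diaphysis",
                                     geometry$marker_height[["diaphysis"]], 0)
    out[[paste0("pot_top_", lab)]] <- mk(paste0("pot_top_", lab), lab, "reference",
                                         geometry$marker_height[["pot_top"]], 0)
    out[[paste0("pot_bottom_", lab)]] <- mk(paste0("pot_bottom_", lab), lab, "reference",
                                            geometry$marker_height[["pot_bottom"]], 0)
  }
  structure(out, class = "marker_set")
}

#' One labelled marker trajectory
#'
#' @param marker_id Unique identifier.
#' @param label Aspect: cranial, caudal, lateral or medial.
#' @param segment `"epiphysis"`, `"diaphysis"` or `"reference"`.
#' @param time Strictly increasing sample times, s.
#' @param position n x 3 matrix of (x, y, z) positions, mm.
#' @return An object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(marker_id, label, segment, time, position) {
  label <- as.character(label); segment <- as.character(segment)
  if (!label %in% c("cranial", "caudal", "lateral", "medial"))
    tr_data_error(sprintf("unknown marker label '%s'", label))
  if (!segment %in% c("epiphysis", "diaphysis", "reference"))
    tr_data_error(sprintf("unknown marker segment '%s'", segment))
  position <- as.matrix(position)
  if (ncol(position) != 3L || nrow(position) != length(time))
    tr_data_error("`position` must be an n x 3 matrix matching `time`")
  if (any(!is.finite(position)) || any(!is.finite(time)))
    tr_data_error(sprintf("non-finite coordinates in marker '%s'", marker_id))
  if (length(time) > 1L && any(diff(time) <= 0))
    tr_data_error(sprintf("marker '%s' has non-increasing time stamps", marker_id))
  colnames(position) <- c("x", "y", "z")
  structure(
    list(marker_id = as.character(marker_id), label = label, segment = segment,
         time = as.numeric(time), position = position),
    class = "marker_trajectory"
  )
}

#' Calibrate rotation shares to a target motion-analysis group mean
#'
#' Scales the per-marker rotation shares so that, for a construct at the
#' given group-mean parameters, the four-marker average full-cycle rotation
#' equals `target_motion` degrees. The construct's expected machine
#' peak-to-peak displacement is the closed-form
#' `2 A / k + tau * tanh(A / T0)`; dividing by the slippage factor gives the
#' bone rotation available to the markers.
#'
#' @param stiffness_mean,toggle_mean Group-mean construct parameters.
#' @param target_motion Target mean marker rotation, degrees.
#' @param protocol A [load_protocol()].
#' @param geometry A [rig_geometry()] whose shares are rescaled.
#' @param transition_torque Sigmoid transition torque, Nm.
#' @return `geometry` with rescaled `rotation_share`.
#' @export
calibrate_rotation_shares <- function(stiffness_mean, toggle_mean, target_motion,
                                      protocol = load_protocol(),
                                      geometry = rig_geometry(),
                                      transition_torque = 0.2) {
  A <- protocol$torque_amplitude
  gross <- 2 * A / stiffness_mean + toggle_mean * tanh(A / transition_torque)
  bone <- gross / geometry$slippage_factor
  geometry$rotation_share <- geometry$rotation_share * (target_motion / bone)
  geometry
}

#' Simulate a full repeated-measures study
#'
#' Draws, for each specimen, a toggle random intercept (and per-marker
#' intercepts) once and reuses them across the specimen's three runs
#' (three -> two -> one pins). Within each run, true stiffness is drawn from
#' the group's mean/SD and true toggle is
#' `group mean + specimen intercept + residual`, where the residual SD is
#' `sqrt(max(group_sd^2 - specimen_effect_sd^2, 0))` so the marginal SD
#' matches the group table. Negative draws are truncated at small positive
#' floors. Everything is derived from `design$seed`.
#'
#' @param design A [study_design()].
#' @param protocol A [load_protocol()].
#' @param group_params Per-group parameter table, as [default_group_params()].
#' @param geometry A [rig_geometry()], used when `include_markers = TRUE`.
#' @param include_markers Also simulate marker trajectories per run.
#' @param calibrate_markers When `TRUE`, rescale the rotation shares per group
#'   so marker group means hit the reference motion-analysis levels. The
#'   default `FALSE` keeps the share pattern at mean 1, so the four-marker
#'   average equals the bone rotation and the machine/motion displacement
#'   ratio round-trips to the slippage factor.
#' @param angle_noise_sd Machine angle noise SD passed to every run's
#'   [construct_params()], degrees.
#' @return A list of class `torsion_study` with elements `runs` (list of
#'   bundles: `specimen`, `pin_group`, `params`, `trace`, optionally
#'   `markers`), `true_params` (tibble of drawn parameters), `design`,
#'   `protocol`.
#' @export
generate_study <- function(design = study_design(), protocol = load_protocol(),
                           group_params = default_group_params(),
                           geometry = rig_geometry(),
                           include_markers = FALSE,
                           calibrate_markers = FALSE,
                           angle_noise_sd = 0.02) {
  if (!inherits(design, "study_design")) tr_config_error("`design` must be a study_design")
  req <- c("pin_group", "stiffness_mean", "stiffness_sd", "toggle_mean", "toggle_sd")
  if (!all(req %in% names(group_params)))
    tr_config_error("`group_params` must have columns pin_group, stiffness_mean/sd, toggle_mean/sd")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(design$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  ns <- design$n_specimens
  spec_int <- rnorm(ns, 0, design$specimen_effect_sd)
  labs <- c("cranial", "lateral", "caudal", "medial")
  marker_int <- matrix(rnorm(ns * 4L, 0, design$marker_effect_sd), ns, 4L,
                       dimnames = list(NULL, labs))

  ref_motion <- reference_group_summary()
  ref_motion <- ref_motion[ref_motion$parameter == "gross_motion", ]

  runs <- list()
  tp <- list()
  for (s in seq_len(ns)) {
    for (g in design$groups) {
      row <- group_params[group_params$pin_group == g, ]
      if (nrow(row) != 1L)
        tr_config_error(sprintf("`group_params` must have exactly one row for group '%s'", g))
      res_sd <- sqrt(max(row$toggle_sd^2 - design$specimen_effect_sd^2, 0))
      k <- max(rnorm(1, row$stiffness_mean, row$stiffness_sd), 0.05)
      tau <- max(row$toggle_mean + spec_int[s] + rnorm(1, 0, res_sd), 0)
      par <- construct_params(k, tau, angle_noise_sd = angle_noise_sd,
                              pin_group = g)
      run_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      trace <- generate_trace(protocol, par, seed = run_seed)
      bundle <- list(specimen = s, pin_group = g, params = par, trace = trace)
      if (include_markers) {
        geo <- geometry
        if (calibrate_markers)
          geo <- calibrate_rotation_shares(
            row$stiffness_mean, row$toggle_mean,
            target_motion = ref_motion$mean[ref_motion$pin_group == g],
            protocol = protocol, geometry = geometry)
        A <- protocol$torque_amplitude
        bone_run <- (2 * A / k + tau * tanh(A / par$transition_torque)) /
          geo$slippage_factor
        geo$rotation_share <- pmax(
          geo$rotation_share + marker_int[s, ] / max(bone_run, 0.5), 0)
        bundle$markers <- generate_markers(trace, geo, par,
                                           seed = sample.int(.Machine$integer.max - 1L, 1L))
      }
      runs[[length(runs) + 1L]] <- bundle
      tp[[length(tp) + 1L]] <- tibble::tibble(
        specimen = s, pin_group = g, stiffness_true = k, toggle_true = tau)
    }
  }
  structure(
    list(runs = runs, true_params = do.call(rbind, tp),
         design = design, protocol = protocol),
    class = "torsion_study"
  )
}
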