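#' Reference group summaries from the porcine K-wire fixation experiment
#'
#' Published per-group mean +/- SD values (all cycles, 0-250) for the cadaveric
#' porcine Salter-Harris I proximal-humeral fixation experiment that the
#' simulator emulates: torsional stiffness, interfragmentary toggle, and gross
#' angular displacement measured both by the materials testing system (MTS)
#' and by motion-analysis marker tracking. These are the levels the synthetic
#' study generator reproduces and the inputs to the derived-arithmetic
#' helpers ([ratio_and_percent()], [compare_systems()]).
#'
#' @return A tibble with columns `parameter` (one of `"stiffness"`,
#'   `"toggle"`, `"gross_mts"`, `"gross_motion"`), `pin_group` (`"three"`,
#'   `"two"`, `"one"`), `mean` and `sd`. Units are Nm/degree for stiffness and
#'   degrees otherwise.
#' @seealso [reference_marker_means()], [default_group_params()]
#' @export
#' @examples
#' reference_group_summary()
reference_group_summary <- function() {
  tibble::tibble(
    parameter = rep(c("stiffness", "toggle", "gross_mts", "gross_motion"), each = 3L),
    pin_group = rep(c("three", "two", "one"), times = 4L),
    mean = c(1.18, 1.10, 1.16,
             4.25, 5.08, 6.41,
             6.64, 7.81, 9.74,
             2.34, 2.75, 4.22),
    sd   = c(0.21, 0.23, 0.35,
             1.05, 1.63, 2.05,
             1.03, 1.73, 2.36,
             1.06, 1.26, 1.79)
  )
}

#' Reference per-marker rotational displacement means
#'
#' Published mean +/- SD rotational displacement of the four epiphyseal
#' markers (all pin groups pooled). The cranial aspect, directly stabilised by
#' the pins entering the greater tubercle, moves least; the caudal aspect
#' (humeral head, no direct fixation) moves most.
#'
#' @return A tibble with columns `label`, `mean`, `sd` (degrees).
#' @export
reference_marker_means <- function() {
  tibble::tibble(
    label = c("cranial", "lateral", "caudal", "medial"),
    mean  = c(2.08, 3.12, 3.84, 3.36),
    sd    = c(1.42, 1.38, 1.63, 1.51)
  )
}

#' Default per-group construct parameters for the synthetic study
#'
#' Group-level means and SDs of true construct stiffness and toggle used by
#' [generate_study()], taken from the reference experiment's group summaries
#' ([reference_group_summary()]).
#'
#' @return A tibble with columns `pin_group`, `stiffness_mean`, `stiffness_sd`,
#'   `toggle_mean`, `toggle_sd`.
#' @export
default_group_params <- function() {
  ref <- reference_group_summary()
  k <- ref[ref$parameter == "stiffness", ]
  tau <- ref[ref$parameter == "toggle", ]
  tibble::tibble(
    pin_group = k$pin_group,
    stiffness_mean = k$mean, stiffness_sd = k$sd,
    toggle_mean = tau$mean, toggle_sd = tau$sd
  )
}

#' Default relative rotation shares of the epiphyseal markers
#'
#' The four epiphyseal markers do not rotate equally: pin placement is
#' eccentric (cranial, in the greater tubercle), so the cranial aspect is the
#' most constrained and the caudal aspect the least. The default shares are
#' the reference per-marker displacement means normalised to mean 1, so a
#' marker's rotation is `share * bone_rotation` and the four-marker average
#' equals the bone's interfragmentary rotation.
#'
#' @return Named numeric vector (cranial, lateral, caudal, medial), mean 1.
#' @export
default_marker_shares <- function() {
  ref <- reference_marker_means()
  setNames(ref$mean / mean(ref$mean), ref$label)
}
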