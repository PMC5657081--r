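r_squared <- function(x, y) {
  # squared Pearson correlation; 0 when either variable is constant
  if (length(x) < 3L) return(NA_real_)
  sx <- sd(x); sy <- sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  cor(x, y)^2
}

#' Terminal-slope fit of one load-displacement branch
#'
#' Implements the iterative R-squared-thresholded terminal regression used to
#' estimate torsional stiffness. Within the cycle window, the sample of
#' maximum (external branch) or minimum (internal branch) torque is located;
#' the initial point set is that sample plus the `n_init - 1` immediately
#' preceding samples along the loading limb. If the ordinary least-squares
#' regression of torque on angle over the initial set reaches
#' `R^2 >= r2_min`, adjacent preceding samples are added one at a time while
#' the fit keeps passing (the last passing set is kept); if the initial set
#' fails, the earliest sample is dropped repeatedly until the fit passes or
#' fewer than 3 points would remain, in which case estimation fails. The
#' regression slope is the branch stiffness (Nm/degree) and the x-intercept
#' feeds the toggle statistic.
#'
#' @param trace A [torsion_trace()] (typically after [decimate_trace()]).
#' @param window One row of [segment_cycles()] output.
#' @param branch `"external"` (positive torque extremum) or `"internal"`
#'   (negative).
#' @param r2_min Acceptance threshold on R-squared; default 0.995.
#' @param n_init Initial point count; default 10.
#' @return An object of class `terminal_fit`: `branch`, `cycle_index`,
#'   `n_points`, `slope` (Nm/degree), `intercept` (Nm), `r_squared`,
#'   `x_intercept` (degree), `indices` (trace sample indices used).
#' @export
fit_terminal_segment <- function(trace, window, branch = c("external", "internal"),
                                 r2_min = 0.995, n_init = 10) {
  branch <- match.arg(branch)
  if (r2_min <= 0 || r2_min > 1) tr_config_error("`r2_min` must be in (0, 1]")
  if (n_init < 3) tr_config_error("`n_init` must be >= 3")
  idx <- window_indices(trace, window)
  cyc <- if (!is.null(window$cycle_index)) window$cycle_index[1] else NA_integer_
  tq <- trace$torque[idx]

  anchor_rel <- if (branch == "external") which.max(tq) else which.min(tq)
  if ((branch == "external" && tq[anchor_rel] <= 0) ||
      (branch == "internal" && tq[anchor_rel] >= 0))
    tr_data_error(sprintf(
      "cycle %s: window contains no %s-branch torque extremum", cyc, branch))
  anchor <- idx[anchor_rel]
  lo <- idx[1]
  navail <- anchor - lo + 1L
  if (navail < 3L)
    tr_estimation_error(sprintf(
      "cycle %s, %s branch: fewer than 3 samples precede the extremum", cyc, branch),
      cycle = cyc, branch = branch)

  pts <- function(n) seq.int(anchor - n + 1L, anchor)
  r2_of <- function(n) r_squared(trace$angle[pts(n)], trace$torque[pts(n)])

  n <- min(as.integer(n_init), navail)
  if (sd(trace$angle[pts(n)]) == 0)
    tr_degenerate_error(sprintf(
      "cycle %s, %s branch: zero angle variance in the initial point set", cyc, branch),
      cycle = cyc, branch = branch)
  cur <- r2_of(n)
  if (!is.na(cur) && cur >= r2_min) {
    while (n < navail) {
      nxt <- r2_of(n + 1L)
      if (is.na(nxt) || nxt < r2_min) break
      n <- n + 1L
    }
  } else {
    ok <- FALSE
    while (n > 3L) {
      n <- n - 1L
      cur <- r2_of(n)
      if (!is.na(cur) && cur >= r2_min) { ok <- TRUE; break }
    }
    if (!ok)
      tr_estimation_error(sprintf(
        "cycle %s, %s branch: no contiguous point set of >= 3 samples reaches R^2 >= %g",
        cyc, branch, r2_min),
        cycle = cyc, branch = branch)
  }

  sel <- pts(n)
  x <- trace$angle[sel]; y <- trace$torque[sel]
  if (sd(x) == 0)
    tr_degenerate_error(sprintf(
      "cycle %s, %s branch: zero angle variance in the accepted point set", cyc, branch),
      cycle = cyc, branch = branch)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  structure(
    list(branch = branch, cycle_index = cyc, n_points = n,
         slope = slope, intercept = intercept,
         r_squared = r_squared(x, y),
         x_intercept = if (slope != 0) -intercept / slope else NA_real_,
         indices = sel),
    class = "terminal_fit"
  )
}

#' @export
print.terminal_fit <- function(x, ...) {
  cat(sprintf(
    "<terminal_fit> %s branch, cycle %s: slope %.4g Nm/deg, x-intercept %.4g deg, R^2 %.5f (%d points)\n",
    x$branch, x$cycle_index, x$slope, x$x_intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Toggle from a pair of terminal fits
#'
#' Extends the external and internal terminal regression lines to the x-axis:
#' the positive toggle is the external-branch x-intercept, the negative
#' toggle the internal-branch x-intercept, and the total toggle their
#' difference -- the width of the near-zero-stiffness interfragmentary band.
#'
#' @param external,internal [fit_terminal_segment()] results for the two
#'   branches.
#' @return An object of class `toggle_result` with `positive_toggle`,
#'   `negative_toggle`, `total_toggle` (degrees).
#' @export
toggle_from_fits <- function(external, internal) {
  if (!inherits(external, "terminal_fit") || !inherits(internal, "terminal_fit"))
    tr_config_error("both arguments must be terminal_fit objects")
  if (external$branch != "external" || internal$branch != "internal")
    tr_config_error("fits must be the external and internal branch, in that order")
  if (!is.finite(external$slope) || !is.finite(internal$slope) ||
      external$slope == 0 || internal$slope == 0)
    tr_degenerate_error("terminal fit with zero slope: x-intercept undefined")
  pos <- external$x_intercept
  neg <- internal$x_intercept
  structure(
    list(positive_toggle = pos, negative_toggle = neg,
         total_toggle = pos - neg),
    class = "toggle_result"
  )
}

#' Torsional stiffness of a terminal fit
#'
#' The branch stiffness is the terminal regression slope, Nm/degree.
#'
#' @param fit A [fit_terminal_segment()] result.
#' @return Stiffness in Nm/degree.
#' @export
stiffness_of <- function(fit) {
  if (!inherits(fit, "terminal_fit")) tr_config_error("`fit` must be a terminal_fit")
  fit$slope
}

#' Per-cycle stiffness, toggle and gross displacement of one trace
#'
#' Runs the full machine-data analysis for the selected cycles: gross
#' peak-to-peak displacement on the raw stream, and terminal fits (both
#' branches) plus toggle on the stream decimated to `analysis_rate`.
#'
#' @param trace A raw [torsion_trace()] with protocol metadata.
#' @param cycles Cycle indices to analyse; default 60, 120, 180.
#' @param analysis_rate Decimation target for the terminal fits, Hz.
#' @param decimation_method Passed to [decimate_trace()].
#' @param r2_min,n_init Passed to [fit_terminal_segment()].
#' @return A tibble with one row per cycle: `cycle`, `gross_mts`,
#'   `stiffness_external`, `stiffness_internal`, `stiffness` (branch mean),
#'   `toggle_positive`, `toggle_negative`, `toggle_total`,
#'   `n_points_external`, `n_points_internal`.
#' @export
analyze_trace <- function(trace, cycles = c(60, 120, 180), analysis_rate = 25,
                          decimation_method = "mean",
                          r2_min = 0.995, n_init = 10) {
  win_raw <- segment_cycles(trace)
  missing <- setdiff(cycles, win_raw$cycle_index)
  if (length(missing))
    tr_config_error(sprintf("trace has no cycle(s) %s", paste(missing, collapse = ", ")))
  dec <- decimate_trace(trace, to = analysis_rate, method = decimation_method)
  win_dec <- segment_cycles(dec)

  rows <- lapply(cycles, function(k) {
    wr <- win_raw[win_raw$cycle_index == k, ]
    wd <- win_dec[win_dec$cycle_index == k, ]
    gross <- gross_cycle_displacement(trace, wr)
    ext <- fit_terminal_segment(dec, wd, "external", r2_min = r2_min, n_init = n_init)
    int <- fit_terminal_segment(dec, wd, "internal", r2_min = r2_min, n_init = n_init)
    tg <- toggle_from_fits(ext, int)
    tibble::tibble(
      cycle = k, gross_mts = gross,
      stiffness_external = ext$slope, stiffness_internal = int$slope,
      stiffness = (ext$slope + int$slope) / 2,
      toggle_positive = tg$positive_toggle, toggle_negative = tg$negative_toggle,
      toggle_total = tg$total_toggle,
      n_points_external = ext$n_points, n_points_internal = int$n_points
    )
  })
  do.call(rbind, rows)
}
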