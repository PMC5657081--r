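#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with the reference
#' experiment's values as defaults: +/-2 Nm at 0.5 Hz for 250 cycles sampled
#' at 1000 Hz, analysis cycles 60/120/180, terminal-fit threshold R^2 >=
#' 0.995 starting from 10 points, and block-mean decimation to 25 Hz for the
#' terminal fits. The resolved configuration is serialised into every report
#' for provenance.
#'
#' @param protocol A [load_protocol()].
#' @param design A [study_design()] (synthetic mode).
#' @param geometry A [rig_geometry()] (synthetic mode with markers).
#' @param cycles Analysis cycle indices.
#' @param r2_min,n_init Terminal-fit parameters.
#' @param analysis_rate Decimation target, Hz.
#' @param decimation_method `"mean"` or `"subsample"`.
#' @param include_markers Simulate and analyse marker streams.
#' @param seed Integer seed for synthetic mode.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(protocol = load_protocol(),
                            design = study_design(),
                            geometry = rig_geometry(),
                            cycles = c(60, 120, 180),
                            r2_min = 0.995, n_init = 10,
                            analysis_rate = 25,
                            decimation_method = "mean",
                            include_markers = TRUE,
                            seed = 1L) {
  if (!inherits(protocol, "load_protocol")) tr_config_error("`protocol` must be a load_protocol")
  if (!inherits(design, "study_design")) tr_config_error("`design` must be a study_design")
  if (!inherits(geometry, "rig_geometry")) tr_config_error("`geometry` must be a rig_geometry")
  if (!is.numeric(cycles) || !length(cycles) || any(cycles < 1) ||
      any(cycles != round(cycles)))
    tr_config_error("`cycles` must be positive integer cycle indices")
  if (any(cycles > protocol$n_cycles))
    tr_config_error("`cycles` exceed the protocol's cycle count")
  if (!is.numeric(r2_min) || r2_min <= 0 || r2_min > 1)
    tr_config_error("`r2_min` must be in (0, 1]")
  if (n_init < 3) tr_config_error("`n_init` must be >= 3")
  stopifnot_scalar_num(analysis_rate, "analysis_rate", positive = TRUE)
  decimation_method <- match.arg(decimation_method, c("mean", "subsample"))
  design$seed <- as.integer(seed)
  structure(
    list(protocol = protocol, design = design, geometry = geometry,
         cycles = as.integer(cycles), r2_min = r2_min,
         n_init = as.integer(n_init), analysis_rate = analysis_rate,
         decimation_method = decimation_method,
         include_markers = isTRUE(include_markers), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_as_list <- function(config) {
  list(
    schema_version = "1.0",
    protocol = unclass(config$protocol),
    design = unclass(config$design),
    geometry = lapply(unclass(config$geometry), function(x)
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
    cycles = config$cycles, r2_min = config$r2_min, n_init = config$n_init,
    analysis_rate = config$analysis_rate,
    decimation_method = config$decimation_method,
    include_markers = config$include_markers, seed = config$seed
  )
}

analyze_bundle <- function(bundle, config) {
  per_cycle <- withCallingHandlers(
    analyze_trace(bundle$trace, cycles = config$cycles,
                  analysis_rate = config$analysis_rate,
                  decimation_method = config$decimation_method,
                  r2_min = config$r2_min, n_init = config$n_init),
    torsionrig_error = function(e) {
      tr_estimation_error(sprintf(
        "stage trace_analysis, specimen %s, %s-pin run: %s",
        bundle$specimen, bundle$pin_group, conditionMessage(e)))
    })
  per_cycle$specimen <- bundle$specimen
  per_cycle$pin_group <- bundle$pin_group
  motion <- NULL
  if (!is.null(bundle$markers)) {
    motion <- analyze_markers(bundle$markers,
                              frequency = config$protocol$frequency,
                              cycles = config$cycles)
    motion$specimen <- bundle$specimen
    motion$pin_group <- bundle$pin_group
  }
  list(per_cycle = per_cycle, motion = motion)
}

#' Run the full analysis pipeline
#'
#' Synthetic mode (default, `runs = NULL`): simulates the repeated-measures
#' study specified by the config (specimen by specimen, so memory stays flat)
#' and analyses every run. File mode: `runs` is a data frame manifest with
#' columns `specimen`, `pin_group`, `trace_path` and optionally
#' `marker_path`.
#'
#' The report contains per-cycle metrics for every run, group mean +/- SD
#' for stiffness, toggle and gross displacement (machine and, when markers
#' are present, motion analysis), mixed-model likelihood-ratio p-values,
#' pairwise paired comparisons, the machine-vs-motion system comparison, and
#' the fully resolved configuration. Identical (config, seed, inputs)
#' reproduce the report exactly.
#'
#' @param config A [pipeline_config()].
#' @param runs Optional manifest data frame (file mode).
#' @return A list of class `torsion_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), runs = NULL) {
  if (!inherits(config, "pipeline_config"))
    tr_config_error("`config` must be a pipeline_config")

  per_cycle <- list(); motion <- list()
  if (is.null(runs)) {
    study <- generate_study(config$design, config$protocol,
                            geometry = config$geometry,
                            include_markers = config$include_markers)
    for (b in study$runs) {
      res <- analyze_bundle(b, config)
      per_cycle[[length(per_cycle) + 1L]] <- res$per_cycle
      if (!is.null(res$motion)) motion[[length(motion) + 1L]] <- res$motion
    }
  } else {
    need <- c("specimen", "pin_group", "trace_path")
    if (!all(need %in% names(runs)))
      tr_config_error("`runs` manifest needs columns specimen, pin_group, trace_path")
    for (i in seq_len(nrow(runs))) {
      b <- list(specimen = runs$specimen[i], pin_group = runs$pin_group[i],
                trace = read_trace(runs$trace_path[i], protocol = config$protocol))
      if ("marker_path" %in% names(runs) && !is.na(runs$marker_path[i]) &&
          nzchar(runs$marker_path[i]))
        b$markers <- read_markers(runs$marker_path[i])
      res <- analyze_bundle(b, config)
      per_cycle[[length(per_cycle) + 1L]] <- res$per_cycle
      if (!is.null(res$motion)) motion[[length(motion) + 1L]] <- res$motion
    }
  }
  per_cycle <- do.call(rbind, per_cycle)
  motion <- if (length(motion)) do.call(rbind, motion) else NULL

  mk_table <- function(resp, kind) {
    measurement_table(data.frame(
      specimen = per_cycle$specimen, pin_group = per_cycle$pin_group,
      cycle = per_cycle$cycle, response = per_cycle[[resp]],
      response_kind = kind))
  }
  tabs <- list(
    stiffness = mk_table("stiffness", "stiffness"),
    toggle = mk_table("toggle_total", "toggle"),
    gross_mts = mk_table("gross_mts", "gross_displacement_mts")
  )
  if (!is.null(motion)) {
    tabs$gross_motion <- measurement_table(data.frame(
      specimen = motion$specimen, pin_group = motion$pin_group,
      cycle = motion$cycle, marker = motion$marker_id,
      response = motion$displacement,
      response_kind = "gross_displacement_motion"))
  }

  summaries <- lapply(tabs, summarize_groups)
  models <- lapply(tabs, fit_mixed_model)
  pairwise <- lapply(tabs, function(tb)
    tryCatch(pairwise_group_tests(tb, force = TRUE),
             torsionrig_error = function(e) NULL))
  systems <- if (!is.null(motion)) {
    compare_systems(tabs$gross_mts$response,
                    tabs$gross_motion$response)
  } else NULL

  structure(
    list(per_cycle = per_cycle, motion = motion,
         group_summaries = summaries,
         model_p_values = lapply(models, function(m) as.list(m$p_fixed)),
         random_effect_variances = lapply(models, function(m)
           as.list(m$ranef_variances)),
         pairwise = pairwise, system_comparison = systems,
         config = config_as_list(config)),
    class = "torsion_report"
  )
}

#' @export
print.torsion_report <- function(x, ...) {
  cat("<torsion_report>\n")
  for (nm in names(x$group_summaries)) {
    s <- x$group_summaries[[nm]]
    cat(sprintf("  %-12s %s\n", nm, paste(
      sprintf("%s: %.2f +/- %.2f", s$pin_group, s$mean, s$sd), collapse = "  ")))
  }
  if (!is.null(x$system_comparison))
    cat(sprintf("  MTS / motion displacement ratio: %.2f (p = %.3g)\n",
                x$system_comparison$ratio, x$system_comparison$p_value))
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Structured text with a stable `schema_version` field inside the embedded
#' configuration; byte-identical for identical (config, seed, inputs).
#'
#' @param report A [run_pipeline()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "torsion_report")) tr_config_error("`report` must be a torsion_report")
  out <- report
  class(out) <- NULL
  out$per_cycle <- as.data.frame(out$per_cycle)
  if (!is.null(out$motion)) out$motion <- as.data.frame(out$motion)
  out$group_summaries <- lapply(out$group_summaries, as.data.frame)
  out$pairwise <- lapply(out$pairwise, function(p)
    if (is.null(p)) NULL else as.data.frame(p))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
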