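#' Validate a measurement table
#'
#' The long-format table the statistical layer consumes: one response value
#' per specimen x pin group x cycle (x marker, for motion-analysis
#' responses).
#'
#' @param data A data frame with columns `specimen`, `pin_group` (one of
#'   "one", "two", "three"), `cycle`, `response` (numeric, no missing
#'   values), optionally `marker`, and optionally `response_kind` (one of
#'   `"gross_displacement_mts"`, `"gross_displacement_motion"`,
#'   `"stiffness"`, `"toggle"`).
#' @return The validated tibble (class `measurement_table` prepended).
#' @export
measurement_table <- function(data) {
  need <- c("specimen", "pin_group", "cycle", "response")
  miss <- setdiff(need, names(data))
  if (length(miss))
    tr_data_error(sprintf("measurement table is missing column(s): %s",
                          paste(miss, collapse = ", ")))
  if (!all(data$pin_group %in% c("one", "two", "three")))
    tr_data_error("`pin_group` must be one of 'one', 'two', 'three'")
  if (!is.numeric(data$response) || anyNA(data$response))
    tr_data_error("`response` must be numeric with no missing values")
  if ("response_kind" %in% names(data)) {
    kinds <- c("gross_displacement_mts", "gross_displacement_motion",
               "stiffness", "toggle")
    if (!all(data$response_kind %in% kinds))
      tr_data_error(sprintf("`response_kind` must be one of: %s",
                            paste(kinds, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  class(out) <- c("measurement_table", class(out))
  out
}

#' Per-group mean and SD
#'
#' Group summaries in the reporting convention mean +/- sample SD (n - 1
#' denominator). With `by_specimen = TRUE`, observations are first averaged
#' within specimen (over cycles and markers) so n is the number of bones.
#'
#' @param table A [measurement_table()].
#' @param by_specimen Aggregate to specimen-level means first.
#' @return A tibble with columns `pin_group`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(table, by_specimen = FALSE) {
  table <- measurement_table(table)
  if (by_specimen) {
    agg <- aggregate(response ~ specimen + pin_group, data = table, FUN = mean)
    table <- agg
  }
  groups <- intersect(c("three", "two", "one"), unique(table$pin_group))
  rows <- lapply(groups, function(g) {
    v <- table$response[table$pin_group == g]
    if (length(v) < 2L)
      tr_data_error(sprintf("group '%s' has fewer than 2 observations", g))
    tibble::tibble(pin_group = g, n = length(v), mean = mean(v), sd = sd(v))
  })
  do.call(rbind, rows)
}

#' Fit the study's linear mixed-effects model
#'
#' Fits `response ~ pin_group + cycle + (1 | specimen)` -- plus
#' `(1 | marker)` for motion-analysis responses -- by maximum likelihood with
#' [lme4::lmer()]. Pin group and cycle enter as categorical factors. The
#' p-value for each fixed factor comes from a likelihood-ratio (Chi-square)
#' test against the ML fit without that factor; the same likelihood-ratio
#' comparison against fits without each random intercept is reported to
#' support stepwise retention of random effects. A singular random-effect
#' variance is reported as such, never silently dropped.
#'
#' @param table A [measurement_table()].
#' @param include_marker `TRUE`, `FALSE`, or `"auto"` (include the marker
#'   intercept when a `marker` column is present).
#' @return An object of class `torsion_mixed_model`: `model` (the lmerMod),
#'   `fixed` (coefficient tibble), `ranef_variances`, `p_fixed` (named:
#'   pin_group, cycle), `p_random` (named LRT p-values for dropping each
#'   random intercept), `singular`.
#' @export
fit_mixed_model <- function(table, include_marker = "auto") {
  table <- measurement_table(table)
  if (identical(include_marker, "auto"))
    include_marker <- "marker" %in% names(table) && length(unique(table$marker)) > 1L
  for (f in c("pin_group", "cycle"))
    if (length(unique(table[[f]])) < 2L)
      tr_data_error(sprintf("factor `%s` needs at least 2 levels", f))
  cyc_raw <- table$cycle
  cyc_lv <- unique(as.character(cyc_raw))
  num <- suppressWarnings(as.numeric(cyc_lv))
  if (!anyNA(num)) cyc_lv <- cyc_lv[order(num)]
  df <- data.frame(
    response = table$response,
    pin_group = factor(table$pin_group, levels = c("three", "two", "one")),
    cycle = factor(as.character(cyc_raw), levels = cyc_lv),
    specimen = factor(table$specimen)
  )
  if (include_marker) {
    if (!"marker" %in% names(table))
      tr_data_error("include_marker = TRUE but the table has no `marker` column")
    df$marker <- factor(table$marker)
  }
  re <- if (include_marker) "(1 | specimen) + (1 | marker)" else "(1 | specimen)"
  fml <- as.formula(paste("response ~ pin_group + cycle +", re))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
  fit_ml <- function(f) {
    res <- tryCatch(
      suppressMessages(lme4::lmer(f, data = df, REML = FALSE, control = ctrl)),
      error = function(e) e)
    if (inherits(res, "error"))
      tr_estimation_error(sprintf("mixed model failed to converge: %s",
                                  conditionMessage(res)))
    res
  }
  full <- fit_ml(fml)
  lrt_p <- function(reduced, df_diff) {
    stat <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced))))
    pchisq(stat, df = df_diff, lower.tail = FALSE)
  }
  no_pin <- fit_ml(as.formula(paste("response ~ cycle +", re)))
  no_cyc <- fit_ml(as.formula(paste("response ~ pin_group +", re)))
  p_fixed <- c(
    pin_group = lrt_p(no_pin, length(levels(df$pin_group)) - 1L),
    cycle = lrt_p(no_cyc, length(levels(df$cycle)) - 1L)
  )
  # random-effect retention: LRT against the fit without each intercept
  p_random <- c()
  drop_re <- function(keep) {
    rhs <- if (is.null(keep)) "response ~ pin_group + cycle"
           else paste("response ~ pin_group + cycle + (1 |", keep, ")")
    if (is.null(keep)) {
      ols <- lm(response ~ pin_group + cycle, data = df)
      as.numeric(logLik(ols))
    } else as.numeric(logLik(fit_ml(as.formula(rhs))))
  }
  ll_full <- as.numeric(logLik(full))
  if (include_marker) {
    p_random <- c(
      specimen = pchisq(max(0, 2 * (ll_full - drop_re("marker"))), 1, lower.tail = FALSE),
      marker = pchisq(max(0, 2 * (ll_full - drop_re("specimen"))), 1, lower.tail = FALSE))
  } else {
    p_random <- c(
      specimen = pchisq(max(0, 2 * (ll_full - drop_re(NULL))), 1, lower.tail = FALSE))
  }
  vc <- as.data.frame(lme4::VarCorr(full))
  fe <- coef(summary(full))
  structure(
    list(model = full,
         fixed = tibble::tibble(term = rownames(fe),
                                estimate = fe[, "Estimate"],
                                std_error = fe[, "Std. Error"]),
         ranef_variances = setNames(vc$vcov, ifelse(is.na(vc$grp), "residual", vc$grp)),
         p_fixed = p_fixed, p_random = p_random,
         singular = lme4::isSingular(full)),
    class = "torsion_mixed_model"
  )
}

#' @export
print.torsion_mixed_model <- function(x, ...) {
  cat("<torsion_mixed_model>\n  fixed-effect LRT p-values:\n")
  for (nm in names(x$p_fixed))
    cat(sprintf("    %-10s p = %.4g\n", nm, x$p_fixed[[nm]]))
  cat(sprintf("  random-intercept variances: %s\n",
              paste(sprintf("%s=%.4g", names(x$ranef_variances),
                            x$ranef_variances), collapse = ", ")))
  if (x$singular) cat("  note: singular random-effect fit\n")
  invisible(x)
}

#' Pairwise group comparisons
#'
#' Paired t-tests between pin groups on specimen-level means (the same bones
#' are tested in every group), performed only after the overall pin-group
#' factor is significant in the mixed model (gatekeeping), unless
#' `force = TRUE`. P-values are uncorrected by default; Holm adjustment is
#' available.
#'
#' @param table A [measurement_table()].
#' @param paired Use paired tests on matched specimens (default).
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @param force Skip the gatekeeping check.
#' @param alpha Gatekeeping significance level.
#' @return A tibble with columns `group_a`, `group_b`, `mean_a`, `mean_b`,
#'   `p_value`; the overall pin-group p-value is attached as attribute
#'   `overall_p`.
#' @export
pairwise_group_tests <- function(table, paired = TRUE,
                                 p_adjust = c("none", "holm"),
                                 force = FALSE, alpha = 0.05) {
  p_adjust <- match.arg(p_adjust)
  table <- measurement_table(table)
  overall_p <- NA_real_
  if (!force) {
    overall_p <- fit_mixed_model(table)$p_fixed[["pin_group"]]
    if (overall_p > alpha)
      tr_estimation_error(sprintf(
        "overall pin-group factor not significant (p = %.3g); use force = TRUE to override",
        overall_p))
  }
  agg <- aggregate(response ~ specimen + pin_group, data = table, FUN = mean)
  groups <- intersect(c("three", "two", "one"), unique(agg$pin_group))
  if (length(unique(agg$specimen)) < 2L)
    tr_data_error("paired comparisons need at least 2 specimens")
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- agg[agg$pin_group == pr[1], ]
    b <- agg[agg$pin_group == pr[2], ]
    if (paired) {
      common <- intersect(a$specimen, b$specimen)
      if (length(common) < length(unique(c(a$specimen, b$specimen))))
        tr_data_error(sprintf("groups '%s' and '%s' have unmatched specimens; paired mode needs the same bones",
                              pr[1], pr[2]))
      va <- a$response[match(common, a$specimen)]
      vb <- b$response[match(common, b$specimen)]
      p <- t.test(va, vb, paired = TRUE)$p.value
    } else {
      va <- a$response; vb <- b$response
      p <- t.test(va, vb)$p.value
    }
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   mean_a = mean(va), mean_b = mean(vb), p_value = p)
  })
  out <- do.call(rbind, rows)
  out$p_value <- p.adjust(out$p_value, method = p_adjust)
  attr(out, "overall_p") <- overall_p
  out
}

#' Compare machine and motion-analysis displacement
#'
#' Welch two-sample t-test between the materials-testing-system and
#' motion-analysis displacement samples, plus the ratio of their pooled
#' means -- the factor by which actuator-reported rotation exceeds the
#' marker-tracked bone rotation (mould-bone slippage).
#'
#' @param mts_values,motion_values Numeric displacement samples, degrees.
#' @return A list: `p_value`, `ratio` (mean(mts)/mean(motion)), `mean_mts`,
#'   `mean_motion`.
#' @export
compare_systems <- function(mts_values, motion_values) {
  if (length(mts_values) < 2L || length(motion_values) < 2L)
    tr_data_error("both samples need at least 2 values")
  if (sd(mts_values) == 0 && sd(motion_values) == 0)
    tr_degenerate_error("both samples have zero variance; t-test undefined")
  ht <- t.test(mts_values, motion_values)
  list(p_value = ht$p.value,
       ratio = mean(mts_values) / mean(motion_values),
       mean_mts = mean(mts_values), mean_motion = mean(motion_values))
}

#' Ratios and percentage changes between group means
#'
#' `mode = "ratio"` returns `mean_a / mean_b`. `mode =
#' "percent_decrease_of_larger"` returns `(larger - smaller) / larger * 100`,
#' the convention under which removing a pin "increases motion by X%": the
#' change is expressed relative to the larger of the two means, making the
#' result symmetric in argument order.
#'
#' @param mean_a,mean_b Group means.
#' @param mode `"ratio"` or `"percent_decrease_of_larger"`.
#' @return A unitless scalar.
#' @export
#' @examples
#' ratio_and_percent(4.22, 2.75, "ratio")                      # 1.53x
#' ratio_and_percent(2.75, 2.34, "percent_decrease_of_larger") # 14.91%
ratio_and_percent <- function(mean_a, mean_b,
                              mode = c("ratio", "percent_decrease_of_larger")) {
  mode <- match.arg(mode)
  stopifnot_scalar_num(mean_a, "mean_a")
  stopifnot_scalar_num(mean_b, "mean_b")
  if (mode == "ratio") {
    if (mean_b == 0) tr_config_error("zero denominator in ratio")
    mean_a / mean_b
  } else {
    hi <- max(mean_a, mean_b); lo <- min(mean_a, mean_b)
    if (hi == 0) tr_config_error("zero denominator in percent change")
    (hi - lo) / hi * 100
  }
}

#' Implant cross-sectional area as a fraction of the physis
#'
#' Combined cross-sectional area of `n_pins` circular pins and the
#' percentage of a circular physis of diameter `physis_diameter` they
#' occupy -- a proxy for the growth-plate area destroyed by transphyseal
#' pinning.
#'
#' @param n_pins Number of pins (>= 0).
#' @param pin_diameter Pin diameter, mm.
#' @param physis_diameter Physis diameter, mm.
#' @return A list: `combined_area` (mm^2), `fraction` (percent), `flagged`
#'   (TRUE when the pin diameter is not smaller than the physis diameter).
#' @export
#' @examples
#' implant_area_fraction(3, 3.0, 30)  # ~21 mm^2, ~3%
implant_area_fraction <- function(n_pins, pin_diameter, physis_diameter) {
  stopifnot_scalar_num(n_pins, "n_pins", nonneg = TRUE)
  stopifnot_scalar_num(pin_diameter, "pin_diameter", positive = TRUE)
  stopifnot_scalar_num(physis_diameter, "physis_diameter", positive = TRUE)
  flagged <- pin_diameter >= physis_diameter
  if (flagged)
    warning("pin diameter is not smaller than the physis diameter")
  area <- n_pins * pi * (pin_diameter / 2)^2
  frac <- area / (pi * (physis_diameter / 2)^2) * 100
  list(combined_area = area, fraction = frac, flagged = flagged)
}

#' Simulate a measurement table from the mixed-model structure
#'
#' Draws responses directly from the linear mixed-effects data-generating
#' process (group effects + cycle effects + specimen intercept + optional
#' marker intercept + residual), for calibration studies of the statistical
#' layer (type-I error, power, coverage) without simulating traces.
#'
#' @param n_specimens Number of specimens.
#' @param group_effects Named offsets (degrees) for groups three/two/one.
#' @param cycle_effects Named offsets for the analysis cycles.
#' @param specimen_sd,marker_sd,sigma SDs of the specimen intercept, marker
#'   intercept and residual.
#' @param n_markers 0 for machine-style tables; > 1 adds a marker column.
#' @param intercept Grand mean.
#' @param seed Integer seed.
#' @return A [measurement_table()].
#' @export
simulate_measurements <- function(n_specimens = 12,
                                  group_effects = c(three = 0, two = 0, one = 0),
                                  cycle_effects = c("60" = 0, "120" = 0, "180" = 0),
                                  specimen_sd = 1, marker_sd = 0.5, sigma = 0.5,
                                  n_markers = 0, intercept = 5, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  groups <- names(group_effects); cycles <- names(cycle_effects)
  spec_int <- rnorm(n_specimens, 0, specimen_sd)
  use_marker <- n_markers > 0
  mk <- if (use_marker) paste0("m", seq_len(n_markers)) else NA_character_
  mk_int <- if (use_marker) rnorm(n_markers, 0, marker_sd) else 0
  grid <- expand.grid(specimen = seq_len(n_specimens), pin_group = groups,
                      cycle = cycles,
                      marker = if (use_marker) mk else NA_character_,
                      stringsAsFactors = FALSE)
  mu <- intercept + group_effects[grid$pin_group] + cycle_effects[grid$cycle] +
    spec_int[grid$specimen] +
    (if (use_marker) mk_int[match(grid$marker, mk)] else 0)
  grid$response <- as.numeric(mu + rnorm(nrow(grid), 0, sigma))
  if (!use_marker) grid$marker <- NULL
  measurement_table(grid)
}
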