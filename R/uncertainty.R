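#' Perturbation scenario specification
#'
#' The default uncertainty model of the pipeline: +/- 1 mm applicator
#' translations along each cardinal axis (6 scenarios), +/- 2 degree
#' rigid-body rotations about each axis (6 scenarios) and multiplicative
#' +/- 2 percent TPS dose-calculation variability. The zero (baseline)
#' scenario is always included.
#'
#' @param translations List of length-3 translation vectors, mm.
#' @param rotations List of length-3 per-axis rotation angle vectors,
#'   degrees.
#' @param tps_factors Numeric multiplicative dose factors (> 0).
#' @param pivot One of `"os"` (rotate about the cervical os, the
#'   anatomical anchor of the applicator) or `"applicator_centroid"`.
#' @return Object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(translations = NULL, rotations = NULL,
                              tps_factors = c(0.98, 1.02),
                              pivot = c("os", "applicator_centroid")) {
  pivot <- match.arg(pivot)
  if (is.null(translations)) {
    translations <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                         c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  }
  if (is.null(rotations)) {
    rotations <- list(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0),
                      c(0, -2, 0), c(0, 0, 2), c(0, 0, -2))
  }
  stopifnot(all(vapply(translations, length, 1L) == 3),
            all(vapply(rotations, length, 1L) == 3),
            all(tps_factors > 0))
  structure(
    list(translations = translations, rotations = rotations,
         tps_factors = tps_factors, pivot = pivot),
    class = "perturbation_spec"
  )
}

# metrics tracked by the perturbation report
.report_metrics <- function(dose, structures) {
  m <- plan_metrics(dose, structures)
  c(hrctv_d90 = m$d90, stats::setNames(m$d2cc, paste0(names(m$d2cc), "_d2cc")))
}

#' Perturb the applicator and re-evaluate the plan
#'
#' Applies every scenario in the perturbation spec to the normalized
#' plan: dwells are rigidly transformed (anatomy stays fixed), dose is
#' recomputed WITHOUT renormalization - the delivered plan is fixed and
#' the positioning error moves it - and the tracked metrics (HR-CTV D90
#' and per-OAR D2cc) are extracted. TPS factors scale the baseline dose
#' multiplicatively. Percent changes are 100 x (value - baseline) /
#' baseline.
#'
#' @param plan A normalized [brachy_plan()].
#' @param structures A `structure_set`.
#' @param source A [source_model()].
#' @param spec A [perturbation_spec()].
#' @return Object of class `perturbation_report`: per-scenario metric
#'   table, baseline values, and per-metric min/max ranges in Gy and
#'   percent.
#' @export
perturb_and_evaluate <- function(plan, structures, source,
                                 spec = perturbation_spec()) {
  stopifnot(inherits(plan, "brachy_plan"), inherits(structures, "structure_set"),
            inherits(spec, "perturbation_spec"))
  pivot <- switch(spec$pivot,
                  os = plan$applicator$os_position,
                  applicator_centroid = colMeans(plan$applicator$dwell_positions))
  base_dose <- compute_dose(plan, source, structures)
  base <- .report_metrics(base_dose, structures)

  lo <- structures$grid_origin
  hi <- structures$grid_origin + structures$dim * structures$voxel_size
  scen_rows <- list()
  add_row <- function(name, type, vals) {
    scen_rows[[length(scen_rows) + 1]] <<- data.frame(
      scenario = name, type = type, t(vals), check.names = FALSE)
  }
  add_row("baseline", "baseline", base)

  eval_transform <- function(name, type, tr) {
    pl <- plan
    pl$applicator <- transform_applicator(plan$applicator, tr)
    dw <- pl$applicator$dwell_positions
    if (any(dw < matrix(lo, nrow(dw), 3, byrow = TRUE)) ||
        any(dw > matrix(hi, nrow(dw), 3, byrow = TRUE))) {
      stop("scenario '", name, "' pushes dwells outside the dose grid")
    }
    add_row(name, type, .report_metrics(compute_dose(pl, source, structures),
                                        structures))
  }
  for (tv in spec$translations) {
    nm <- sprintf("shift(%+g,%+g,%+g)mm", tv[1], tv[2], tv[3])
    eval_transform(nm, "translation", rigid_transform(translation = tv))
  }
  for (rv in spec$rotations) {
    nm <- sprintf("rot(%+g,%+g,%+g)deg", rv[1], rv[2], rv[3])
    eval_transform(nm, "rotation",
                   rigid_transform(rotation_deg = rv, pivot = pivot))
  }
  for (f in spec$tps_factors) {
    add_row(sprintf("tps(x%.3g)", f), "tps",
            .report_metrics(scale_dose(base_dose, f), structures))
  }

  tab <- do.call(rbind, scen_rows)
  metrics <- names(base)
  pct <- tab
  for (m in metrics) pct[[m]] <- 100 * (tab[[m]] - base[[m]]) / base[[m]]
  ranges <- do.call(rbind, lapply(metrics, function(m) {
    v <- tab[[m]][tab$type != "baseline"]
    p <- pct[[m]][pct$type != "baseline"]
    data.frame(metric = m, baseline_gy = base[[m]],
               min_gy = min(v), max_gy = max(v),
               pct_min = min(p), pct_max = max(p))
  }))
  structure(
    list(baseline = base, table = tab, percent = pct, ranges = ranges,
         spec = spec),
    class = "perturbation_report"
  )
}

#' TPS variability metric deltas
#'
#' Applies multiplicative dose factors (via [scale_dose()]) and reports
#' the per-metric percent change; by linearity every Dx-type metric
#' changes by exactly (factor - 1) x 100 percent.
#'
#' @param dose A `dose_grid`.
#' @param structures A `structure_set`.
#' @param factors Positive scale factors, default 0.98 and 1.02.
#' @return data.frame: factor, metric, value (Gy), percent change.
#' @export
tps_variability <- function(dose, structures, factors = c(0.98, 1.02)) {
  stopifnot(all(factors > 0))
  base <- .report_metrics(dose, structures)
  out <- lapply(factors, function(f) {
    v <- .report_metrics(scale_dose(dose, f), structures)
    data.frame(factor = f, metric = names(base), value_gy = as.numeric(v),
               pct_change = 100 * (as.numeric(v) - as.numeric(base)) /
                 as.numeric(base))
  })
  do.call(rbind, out)
}

#' Cohort summary statistics
#'
#' Mean, sample SD (n - 1), standard error, normal-approximation 95
#' percent confidence interval (mean +/- 1.96 SE), min and max.
#' `n_override` supports per-fraction observation counting (e.g. 30
#' patients x 4 fractions = 120 observations) when the values supplied
#' are per-patient means.
#'
#' @param values Numeric vector (length >= 2).
#' @param n_override Optional integer to use for the SE denominator.
#' @return Object of class `cohort_summary` (one-row data.frame:
#'   mean, sd, se, ci_lb, ci_ub, min, max, n).
#' @export
summarize_cohort <- function(values, n_override = NULL) {
  if (length(values) < 2) stop("need at least 2 values to summarize")
  n <- if (is.null(n_override)) length(values) else as.integer(n_override)
  stopifnot(n >= 2)
  m <- mean(values)
  s <- stats::sd(values)
  se <- s / sqrt(n)
  out <- data.frame(mean = m, sd = s, se = se,
                    ci_lb = m - 1.96 * se, ci_ub = m + 1.96 * se,
                    min = min(values), max = max(values), n = n)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.perturbation_report <- function(x, digits = 3, ...) {
  cat("applicator position / TPS uncertainty report\n")
  cat(sprintf("  pivot: %s | %d scenarios\n", x$spec$pivot,
              nrow(x$table) - 1))
  r <- x$ranges
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-14s baseline %6.2f Gy | range %5.2f-%5.2f Gy | %% change %+.1f%% to %+.1f%%\n",
                r$metric[i], r$baseline_gy[i], r$min_gy[i], r$max_gy[i],
                r$pct_min[i], r$pct_max[i]))
  }
  invisible(x)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("mean %.3f, SD %.3f, SE %.3f, 95%% CI [%.3f, %.3f], range [%.3g, %.3g], n = %d\n",
              x$mean, x$sd, x$se, x$ci_lb, x$ci_ub, x$min, x$max, x$n))
  invisible(x)
}
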