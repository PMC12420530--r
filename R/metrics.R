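#' Cumulative dose-volume histogram
#'
#' Exact voxel-count cumulative DVH of a structure: for each dose level
#' d on a regular bin grid, the absolute volume (cm^3) receiving at
#' least d. Voxels flagged in-applicator are excluded.
#'
#' @param dose A `dose_grid`.
#' @param mask Logical array matching the grid, or the name of a
#'   structure when `structures` is given.
#' @param structures Optional `structure_set` to resolve `mask` by name.
#' @param bin_width Dose bin width in Gy (default 0.01).
#' @param name Structure label carried on the curve.
#' @return Object of class `dvh`: data.frame-backed curve with columns
#'   `dose_gy`, `volume_cm3`, `volume_pct`, plus `total_volume` cm^3.
#' @export
dvh <- function(dose, mask, structures = NULL, bin_width = 0.01,
                name = NULL) {
  stopifnot(inherits(dose, "dose_grid"), bin_width > 0)
  if (is.character(mask)) {
    stopifnot(!is.null(structures), mask %in% names(structures$masks))
    if (is.null(name)) name <- mask
    mask <- structures$masks[[mask]]
  }
  stopifnot(is.logical(mask), identical(dim(mask), dose$dim))
  sel <- mask & !dose$in_applicator
  d <- dose$dose[sel]
  if (length(d) == 0) stop("empty structure mask (after applicator exclusion)")
  voxvol <- prod(dose$voxel_size) / 1000
  total <- length(d) * voxvol
  edges <- seq(0, (floor(max(d) / bin_width) + 1) * bin_width, by = bin_width)
  # volume receiving >= each edge, by exact counting
  counts <- length(d) - findInterval(edges, sort(d), left.open = TRUE)
  curve <- data.frame(dose_gy = edges,
                      volume_cm3 = counts * voxvol,
                      volume_pct = 100 * counts / length(d))
  structure(
    list(structure = if (is.null(name)) "structure" else name,
         curve = curve,
         doses_desc = sort(d, decreasing = TRUE),
         voxel_volume = voxvol,
         total_volume = total,
         bin_width = bin_width),
    class = "dvh"
  )
}

#' Differential DVH
#'
#' @param x A [dvh()] curve.
#' @return data.frame with bin centres (`dose_gy`) and the volume in
#'   each bin (`volume_cm3`).
#' @export
differential_dvh <- function(x) {
  stopifnot(inherits(x, "dvh"))
  cv <- x$curve
  data.frame(dose_gy = cv$dose_gy[-nrow(cv)] + x$bin_width / 2,
             volume_cm3 = -diff(cv$volume_cm3))
}

# minimum dose of the hottest v cm^3, exact on the voxel-dose order
# statistics: voxel i (descending) covers cumulative volume
# ((i-1)v, iv] with its dose attributed to the interval centre; linear
# interpolation between centres. Exactly equivariant under dose scaling.
.dose_at_volume <- function(x, v_cm3) {
  d <- x$doses_desc
  n <- length(d)
  m <- v_cm3 / x$voxel_volume # volume expressed in voxels
  if (m <= 0.5) return(d[1])
  if (m >= n - 0.5) return(d[n])
  k <- floor(m + 0.5)         # centre indices straddling m
  f <- m + 0.5 - k
  d[k] + f * (d[k + 1] - d[k])
}

#' Dx: minimum dose to the hottest x percent
#'
#' D90 / D80 style metric: the minimum dose received by the hottest `x`
#' percent of the structure volume, computed exactly from the voxel-dose
#' order statistics (linear interpolation between adjacent voxels).
#'
#' @param x A [dvh()] curve.
#' @param percent Percentage of the structure volume, in (0, 100].
#' @return Dose in Gy; monotone non-increasing in `percent`.
#' @export
d_percent <- function(x, percent) {
  stopifnot(inherits(x, "dvh"), percent > 0, percent <= 100)
  .dose_at_volume(x, percent / 100 * x$total_volume)
}

#' D2cc: minimum dose to the hottest 2 cm^3
#'
#' @param x A [dvh()] curve.
#' @param volume_cm3 Absolute hot volume, default 2 cm^3.
#' @return Dose in Gy.
#' @export
d_2cc <- function(x, volume_cm3 = 2) {
  stopifnot(inherits(x, "dvh"), volume_cm3 > 0)
  if (x$total_volume < volume_cm3) {
    stop("structure volume ", signif(x$total_volume, 4), " cm^3 < ",
         volume_cm3, " cm^3; report D(V = total volume) instead")
  }
  .dose_at_volume(x, volume_cm3)
}

#' Volume receiving at least a dose
#'
#' @param x A [dvh()] curve.
#' @param dose_gy Dose threshold in Gy.
#' @return Absolute volume in cm^3, by exact voxel counting.
#' @export
volume_at_dose <- function(x, dose_gy) {
  stopifnot(inherits(x, "dvh"))
  sum(x$doses_desc >= dose_gy) * x$voxel_volume
}

#' Plan conformity / homogeneity indices
#'
#' Computes, from exact voxel counts over the whole grid (in-applicator
#' voxels excluded):
#' \itemize{
#'   \item CI (coverage index) = V100 within the CTV / CTV volume
#'   \item COIN = CI x selectivity, selectivity = (CTV cap V100) / V100
#'   \item DHI = (V100 - V150) / V100 and DNR = V150 / V100 (whole-grid
#'     treated volumes; DHI + DNR = 1 identically)
#'   \item ODI = V200 / CTV volume
#' }
#' V100/V150/V200 are the volumes receiving at least 100/150/200 percent
#' of the prescription.
#'
#' @param dose A `dose_grid`.
#' @param hrctv Logical HR-CTV mask (or a `structure_set`, in which case
#'   its `hrctv` mask is used).
#' @param rx Prescription dose per fraction, Gy; defaults to the plan
#'   prescription carried on the grid.
#' @return Named list: ci, coin, selectivity, dhi, dnr, odi, v100_cm3,
#'   v150_cm3, v200_cm3, v100_ctv_cm3, v100_ctv_pct, ctv_cm3.
#' @export
plan_indices <- function(dose, hrctv, rx = NULL) {
  stopifnot(inherits(dose, "dose_grid"))
  if (inherits(hrctv, "structure_set")) hrctv <- hrctv$masks$hrctv
  stopifnot(is.logical(hrctv), identical(dim(hrctv), dose$dim))
  if (is.null(rx)) rx <- dose$prescription_dose
  stopifnot(rx > 0)
  ok <- !dose$in_applicator
  d <- dose$dose
  voxvol <- prod(dose$voxel_size) / 1000
  ctv <- hrctv & ok
  n_ctv <- sum(ctv)
  if (n_ctv == 0) stop("empty HR-CTV")
  n100 <- sum(d >= rx & ok)
  n150 <- sum(d >= 1.5 * rx & ok)
  n200 <- sum(d >= 2 * rx & ok)
  n100_ctv <- sum(d >= rx & ctv)
  if (n100 == 0) stop("prescription isodose volume is empty; DHI/DNR undefined")
  ci <- n100_ctv / n_ctv
  sel <- n100_ctv / n100
  list(ci = ci,
       coin = ci * sel,
       selectivity = sel,
       dhi = (n100 - n150) / n100,
       dnr = n150 / n100,
       odi = n200 / n_ctv,
       v100_cm3 = n100 * voxvol,
       v150_cm3 = n150 * voxvol,
       v200_cm3 = n200 * voxvol,
       v100_ctv_cm3 = n100_ctv * voxvol,
       v100_ctv_pct = 100 * n100_ctv / n_ctv,
       ctv_cm3 = n_ctv * voxvol)
}

#' Percent of prescription, reported to one decimal
#'
#' @param value Dose in Gy.
#' @param rx Prescription dose in Gy (> 0).
#' @return 100 * value / rx, rounded half-up to one decimal.
#' @export
percent_of_rx <- function(value, rx) {
  stopifnot(rx > 0)
  floor(100 * value / rx * 10 + 0.5) / 10
}

#' Full per-plan metric set
#'
#' Extracts the standard evaluation metrics of one plan: HR-CTV D90 and
#' D80, per-OAR D2cc, V100 of the CTV, conformity/homogeneity indices
#' and percent-of-prescription values.
#'
#' @param dose A `dose_grid`.
#' @param structures A `structure_set` with `hrctv` and OAR masks.
#' @param rx Prescription per fraction, Gy (default: from the grid).
#' @param bin_width DVH bin width, Gy.
#' @return Object of class `plan_metrics` (a named list; `as.data.frame`
#'   gives a one-row summary).
#' @export
plan_metrics <- function(dose, structures, rx = NULL, bin_width = 0.01) {
  stopifnot(inherits(dose, "dose_grid"), inherits(structures, "structure_set"))
  if (is.null(rx)) rx <- dose$prescription_dose
  cv <- dvh(dose, "hrctv", structures, bin_width = bin_width)
  oars <- setdiff(names(structures$masks), "hrctv")
  d2 <- vapply(oars, function(org) {
    d_2cc(dvh(dose, org, structures, bin_width = bin_width))
  }, numeric(1))
  idx <- plan_indices(dose, structures$masks$hrctv, rx = rx)
  out <- list(
    d90 = d_percent(cv, 90),
    d80 = d_percent(cv, 80),
    d2cc = d2,
    v100_ctv_pct = idx$v100_ctv_pct,
    indices = idx,
    rx = rx,
    pct_rx = c(d90 = percent_of_rx(d_percent(cv, 90), rx),
               stats::setNames(percent_of_rx(d2, rx), names(d2)))
  )
  class(out) <- "plan_metrics"
  out
}

#' @export
print.plan_metrics <- function(x, ...) {
  cat(sprintf("HR-CTV D90 %.2f Gy (%.1f%% Rx), D80 %.2f Gy\n",
              x$d90, x$pct_rx[["d90"]], x$d80))
  for (org in names(x$d2cc)) {
    cat(sprintf("  %-8s D2cc %.2f Gy (%.1f%% Rx)\n", org, x$d2cc[[org]],
                x$pct_rx[[org]]))
  }
  i <- x$indices
  cat(sprintf("  V100(CTV) %.1f%% | CI %.2f COIN %.3f DHI %.3f DNR %.3f ODI %.3f\n",
              x$v100_ctv_pct, i$ci, i$coin, i$dhi, i$dnr, i$odi))
  invisible(x)
}

#' @export
as.data.frame.plan_metrics <- function(x, ...) {
  i <- x$indices
  cbind(data.frame(d90 = x$d90, d80 = x$d80),
        as.data.frame(as.list(stats::setNames(x$d2cc,
                                              paste0("d2cc_", names(x$d2cc))))),
        data.frame(v100_ctv_pct = x$v100_ctv_pct, ci = i$ci, coin = i$coin,
                   dhi = i$dhi, dnr = i$dnr, odi = i$odi))
}

#' @export
print.dvh <- function(x, ...) {
  cat("DVH of", x$structure, ":", signif(x$total_volume, 4),
      "cm^3, bin", x$bin_width, "Gy, max dose",
      max(x$curve$dose_gy), "Gy\n")
  invisible(x)
}

#' Plot a DVH
#'
#' @param x A [dvh()] curve.
#' @param relative Plot volume in percent (default) or cm^3.
#' @param add Add to an existing plot.
#' @param ... Passed to [graphics::lines()] / [graphics::plot()].
#' @export
plot.dvh <- function(x, relative = TRUE, add = FALSE, ...) {
  cv <- x$curve
  yv <- if (relative) cv$volume_pct else cv$volume_cm3
  if (add) {
    graphics::lines(cv$dose_gy, yv, ...)
  } else {
    graphics::plot(cv$dose_gy, yv, type = "l",
                   xlab = "dose (Gy)",
                   ylab = if (relative) "volume (%)" else expression(volume ~ (cm^3)),
                   main = paste("cumulative DVH:", x$structure), ...)
  }
  invisible(x)
}
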