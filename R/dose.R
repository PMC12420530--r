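#' HDR brachytherapy plan
#'
#' Binds an applicator to dwell times, relative loading weights and the
#' fractionation prescription. The default protocol is 7 Gy per fraction
#' in 4 fractions prescribed to Point A (after 45 Gy / 25 fx external
#' beam radiotherapy).
#'
#' @param applicator An [applicator_model()].
#' @param dwell_times Numeric, seconds per dwell (>= 0, at least one
#'   positive). Defaults to the relative loading (i.e. an un-normalized
#'   plan; see [normalize_to_point_a()]).
#' @param relative_loading Dimensionless weights per dwell. The default
#'   is a Manchester-style loading: tandem dwells weight 1, ovoid dwells
#'   weight 0.9.
#' @param prescription_dose Gy per fraction (> 0).
#' @param n_fractions Integer number of brachytherapy fractions.
#' @return Object of class `brachy_plan`.
#' @export
brachy_plan <- function(applicator,
                        dwell_times = NULL,
                        relative_loading = NULL,
                        prescription_dose = 7,
                        n_fractions = 4L) {
  stopifnot(inherits(applicator, "applicator_model"),
            prescription_dose > 0, n_fractions >= 1)
  nd <- n_dwells(applicator)
  if (is.null(relative_loading)) {
    relative_loading <- ifelse(applicator$dwell_labels == "tandem", 1, 0.9)
  }
  stopifnot(length(relative_loading) == nd, all(relative_loading >= 0))
  if (is.null(dwell_times)) dwell_times <- relative_loading
  stopifnot(length(dwell_times) == nd, all(dwell_times >= 0))
  if (!any(dwell_times > 0)) stop("at least one dwell time must be positive")
  structure(
    list(applicator = applicator,
         dwell_times = as.numeric(dwell_times),
         relative_loading = as.numeric(relative_loading),
         prescription_dose = prescription_dose,
         n_fractions = as.integer(n_fractions)),
    class = "brachy_plan"
  )
}

#' Dose at arbitrary points
#'
#' Sums the TG-43 dose-rate contribution of every dwell, weighted by its
#' dwell time, at a set of points. Units: cGy/h x s -> Gy.
#'
#' @param plan A [brachy_plan()].
#' @param source A [source_model()].
#' @param points n x 3 matrix of points, mm.
#' @return Numeric vector of doses in Gy (per fraction).
#' @export
dose_at_points <- function(plan, source, points) {
  stopifnot(inherits(plan, "brachy_plan"), inherits(source, "source_model"))
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  pos <- plan$applicator$dwell_positions
  ori <- plan$applicator$dwell_orientations
  total <- numeric(nrow(p))
  for (i in seq_len(nrow(pos))) {
    if (plan$dwell_times[i] == 0) next
    rate <- dose_rate_kernel(source, pos[i, ], ori[i, ],
                             p[, 1], p[, 2], p[, 3], clamp_rmin = TRUE)
    total <- total + rate * plan$dwell_times[i]
  }
  total / 3600 / 100 # cGy/h * s -> Gy
}

#' Compute the per-fraction dose grid
#'
#' Accumulates dose from all dwells over the voxel grid of a structure
#' set, sampling at voxel centres. Voxels closer to any dwell than the
#' source's masking radius (`r_min`, extended in line mode to cover the
#' active-length region where the line geometry factor is undefined) are
#' flagged `in_applicator` - their dose is computed with the radius
#' clamped at that bound - and excluded from DVH analysis downstream.
#' Dose is exactly linear in the dwell times.
#'
#' @param plan A [brachy_plan()].
#' @param source A [source_model()].
#' @param grid A `structure_set` (supplies origin, voxel size, dims).
#' @return Object of class `dose_grid` with fields `dose` (3-D array,
#'   Gy per fraction), `in_applicator` (logical array), grid geometry
#'   and the prescription carried over from the plan.
#' @export
compute_dose <- function(plan, source, grid) {
  stopifnot(inherits(plan, "brachy_plan"), inherits(source, "source_model"),
            inherits(grid, "structure_set"))
  pos <- plan$applicator$dwell_positions
  if (nrow(pos) == 0) stop("empty dwell set")
  ax <- grid_axes(grid)
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  # flat voxel-centre coordinates (column-major array order)
  px <- rep(ax$x, times = ny * nz)
  py <- rep(rep(ax$y, each = nx), times = nz)
  pz <- rep(ax$z, each = nx * ny)

  dose <- numeric(nx * ny * nz)
  inapp <- logical(nx * ny * nz)
  ori <- plan$applicator$dwell_orientations
  rmin_mm <- mask_radius_cm(source) * 10
  for (i in seq_len(nrow(pos))) {
    d2 <- (px - pos[i, 1])^2 + (py - pos[i, 2])^2 + (pz - pos[i, 3])^2
    inapp <- inapp | (d2 < rmin_mm^2)
    if (plan$dwell_times[i] == 0) next
    rate <- dose_rate_kernel(source, pos[i, ], ori[i, ], px, py, pz,
                             clamp_rmin = TRUE)
    dose <- dose + rate * plan$dwell_times[i]
  }
  dose <- dose / 3600 / 100

  structure(
    list(dose = array(dose, dim = grid$dim),
         in_applicator = array(inapp, dim = grid$dim),
         grid_origin = grid$grid_origin,
         voxel_size = grid$voxel_size,
         dim = grid$dim,
         prescription_dose = plan$prescription_dose,
         n_fractions = plan$n_fractions),
    class = "dose_grid"
  )
}

#' Normalize a plan to the Point A prescription
#'
#' Rescales dwell times to `k * relative_loading`, with `k` the unique
#' positive scalar that makes the mean dose at the two Manchester
#' Point A positions equal the per-fraction prescription. Idempotent:
#' the times are always recomputed from the fixed relative loading.
#'
#' @param plan A [brachy_plan()].
#' @param source A [source_model()].
#' @return The normalized `brachy_plan`.
#' @export
normalize_to_point_a <- function(plan, source) {
  stopifnot(inherits(plan, "brachy_plan"))
  pa <- manchester_points(plan$applicator)
  unit_plan <- plan
  unit_plan$dwell_times <- plan$relative_loading
  da <- mean(dose_at_points(unit_plan, source, pa))
  if (!is.finite(da) || da <= 0) {
    stop("zero dose at Point A: degenerate plan geometry")
  }
  k <- plan$prescription_dose / da
  out <- plan
  out$dwell_times <- k * plan$relative_loading
  out
}

#' Scale a dose grid
#'
#' Multiplies every voxel by a positive factor; models multiplicative
#' TPS dose-calculation variability (e.g. factors 0.98 / 1.02 for the
#' +/- 2 percent model). All Dx-type DVH metrics scale by exactly the
#' same factor.
#'
#' @param dose A `dose_grid`.
#' @param factor Positive scalar.
#' @return The scaled `dose_grid`.
#' @export
scale_dose <- function(dose, factor) {
  stopifnot(inherits(dose, "dose_grid"))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop("scale factor must be a positive scalar")
  }
  dose$dose <- dose$dose * factor
  dose
}

#' Optional dwell-time optimizer (non-negative least squares)
#'
#' Fits non-negative dwell times so that computed doses at target points
#' approximate requested doses in the least-squares sense. This is an
#' optional refinement tool; the reference pipeline uses fixed relative
#' loading plus Point A normalization, mirroring manual/graphical
#' planning.
#'
#' @param plan A [brachy_plan()].
#' @param source A [source_model()].
#' @param target_points n x 3 matrix, mm.
#' @param target_doses Length-n desired doses, Gy.
#' @return A `brachy_plan` with optimized dwell times.
#' @export
optimize_dwells <- function(plan, source, target_points, target_doses) {
  stopifnot(inherits(plan, "brachy_plan"),
            nrow(target_points) == length(target_doses))
  pos <- plan$applicator$dwell_positions
  ori <- plan$applicator$dwell_orientations
  p <- as.matrix(target_points)
  A <- vapply(seq_len(nrow(pos)), function(i) {
    dose_rate_kernel(source, pos[i, ], ori[i, ], p[, 1], p[, 2], p[, 3],
                     clamp_rmin = TRUE) / 3600 / 100
  }, numeric(nrow(p)))
  A <- matrix(A, nrow = nrow(p))
  fit <- pracma::lsqnonneg(A, as.numeric(target_doses))
  out <- plan
  out$dwell_times <- fit$x
  out
}

#' @export
print.brachy_plan <- function(x, ...) {
  cat("brachytherapy plan:", length(x$dwell_times), "dwells,",
      x$prescription_dose, "Gy/fx x", x$n_fractions, "fx\n")
  cat("  total dwell time", signif(sum(x$dwell_times), 4), "s\n")
  invisible(x)
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- x$dose[!x$in_applicator]
  cat("dose grid:", paste(x$dim, collapse = " x "), "voxels,",
      "max", signif(max(d), 4), "Gy/fx (outside applicator)\n")
  invisible(x)
}

#' Plot an axial dose slice
#'
#' @param x A `dose_grid`.
#' @param z Slice position in mm (nearest slice is shown); defaults to
#'   the grid centre.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the slice matrix.
#' @export
plot.dose_grid <- function(x, z = NULL, ...) {
  ax <- grid_axes(x)
  if (is.null(z)) z <- stats::median(ax$z)
  k <- which.min(abs(ax$z - z))
  sl <- x$dose[, , k]
  graphics::image(ax$x, ax$y, sl, xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("dose, axial z = %.1f mm", ax$z[k]), ...)
  invisible(sl)
}
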