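#' Read source tables from CSV
#'
#' @param radial_csv Path to a CSV with header `r_cm,g`.
#' @param anisotropy_csv Path to a CSV with header `r_cm,theta_deg,F`.
#' @param ... Passed to [source_model()] (Sk, Lambda, active length...).
#' @return A [source_model()].
#' @export
read_source_tables <- function(radial_csv, anisotropy_csv, ...) {
  source_model(radial_dose_table = utils::read.csv(radial_csv),
               anisotropy_table = utils::read.csv(anisotropy_csv), ...)
}

#' Write / read an applicator as JSON
#'
#' @param applicator An [applicator_model()].
#' @param path JSON file path.
#' @return `read_applicator_json` returns an `applicator_model`.
#' @export
write_applicator_json <- function(applicator, path) {
  stopifnot(inherits(applicator, "applicator_model"))
  jsonlite::write_json(
    list(os_position = applicator$os_position,
         tandem_axis = applicator$tandem_axis,
         lateral_axis = applicator$lateral_axis,
         tandem_dwell_mm = applicator$tandem_dwell_mm,
         ovoid_offset = applicator$ovoid_offset,
         dwells_per_ovoid = sum(applicator$dwell_labels == "ovoid_left"),
         step_size = applicator$step_size),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_applicator_json
#' @export
read_applicator_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  applicator_model(os_position = j$os_position,
                   tandem_axis = j$tandem_axis,
                   lateral_axis = j$lateral_axis,
                   tandem_dwell_mm = j$tandem_dwell_mm,
                   ovoid_offset = j$ovoid_offset,
                   dwells_per_ovoid = j$dwells_per_ovoid,
                   step_size = j$step_size)
}

#' Write / read a plan as JSON
#'
#' Serializes dwell times, loading and prescription together with the
#' applicator geometry.
#'
#' @param plan A [brachy_plan()].
#' @param path JSON file path.
#' @return `read_plan_json` returns a `brachy_plan`.
#' @export
write_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "brachy_plan"))
  a <- plan$applicator
  jsonlite::write_json(
    list(applicator = list(os_position = a$os_position,
                           tandem_axis = a$tandem_axis,
                           lateral_axis = a$lateral_axis,
                           tandem_dwell_mm = a$tandem_dwell_mm,
                           ovoid_offset = a$ovoid_offset,
                           dwells_per_ovoid = sum(a$dwell_labels == "ovoid_left"),
                           step_size = a$step_size),
         dwell_times = plan$dwell_times,
         relative_loading = plan$relative_loading,
         prescription_dose = plan$prescription_dose,
         n_fractions = plan$n_fractions),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- j$applicator
  app <- applicator_model(os_position = a$os_position,
                          tandem_axis = a$tandem_axis,
                          lateral_axis = a$lateral_axis,
                          tandem_dwell_mm = a$tandem_dwell_mm,
                          ovoid_offset = a$ovoid_offset,
                          dwells_per_ovoid = a$dwells_per_ovoid,
                          step_size = a$step_size)
  brachy_plan(app, dwell_times = j$dwell_times,
              relative_loading = j$relative_loading,
              prescription_dose = j$prescription_dose,
              n_fractions = j$n_fractions)
}

#' Export a dose grid as flat CSV
#'
#' One row per voxel: linear index, centre coordinates (mm) and dose
#' (Gy per fraction). Intended for small grids and interchange.
#'
#' @param dose A `dose_grid`.
#' @param path CSV file path.
#' @export
write_dose_csv <- function(dose, path) {
  stopifnot(inherits(dose, "dose_grid"))
  ax <- grid_axes(dose)
  nx <- dose$dim[1]; ny <- dose$dim[2]; nz <- dose$dim[3]
  df <- data.frame(index = seq_len(nx * ny * nz),
                   x_mm = rep(ax$x, times = ny * nz),
                   y_mm = rep(rep(ax$y, each = nx), times = nz),
                   z_mm = rep(ax$z, each = nx * ny),
                   dose_gy = as.vector(dose$dose))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a DVH curve as CSV
#'
#' @param x A [dvh()] curve.
#' @param path CSV file path.
#' @export
write_dvh_csv <- function(x, path) {
  stopifnot(inherits(x, "dvh"))
  utils::write.csv(x$curve, path, row.names = FALSE)
  invisible(path)
}

#' Export structure masks as per-slice run-length CSV
#'
#' Plain-text mask interchange: one row per contiguous x-run of TRUE
#' voxels (structure, iy, iz, ix_start, ix_end).
#'
#' @param structures A `structure_set`.
#' @param path CSV file path.
#' @export
write_masks_rle_csv <- function(structures, path) {
  stopifnot(inherits(structures, "structure_set"))
  rows <- list()
  for (nm in names(structures$masks)) {
    m <- structures$masks[[nm]]
    for (iz in seq_len(dim(m)[3])) for (iy in seq_len(dim(m)[2])) {
      col <- m[, iy, iz]
      if (!any(col)) next
      r <- rle(col)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- r$values
      if (any(keep)) {
        rows[[length(rows) + 1]] <- data.frame(
          structure = nm, iy = iy, iz = iz,
          ix_start = starts[keep], ix_end = ends[keep])
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
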