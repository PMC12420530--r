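#' Tandem-and-ovoids applicator model
#'
#' Geometric model of a Fletcher-Suit-Delclos style intracavitary
#' applicator in the patient frame (mm; x = patient-left, y = anterior,
#' z = superior). The tandem carries an ordered run of dwell positions
#' along its axis starting at the external cervical os; the two ovoids
#' sit in the vaginal fornices, mirror-symmetric about the sagittal
#' tandem plane in the unperturbed pose.
#'
#' @param os_position Length-3, external cervical os, mm.
#' @param tandem_axis Unit length-3 vector along the tandem (default +z,
#'   superior).
#' @param lateral_axis Unit length-3 vector defining patient-right in the
#'   frontal plane of the tandem (default +x); Point A is offset along
#'   +/- this axis.
#' @param tandem_dwell_mm Ordered distances of tandem dwells from the os
#'   along the tandem axis, mm.
#' @param ovoid_offset Length-3 offset (lateral, anterior, superior
#'   components in the applicator frame, mm) of the right ovoid dwell
#'   centre from the os; the left ovoid mirrors it.
#' @param dwells_per_ovoid Number of dwells per ovoid (1-3), stacked
#'   along the tandem axis at `step_size` spacing.
#' @param step_size Dwell step, mm.
#' @return Object of class `applicator_model` with dwell positions,
#'   orientations and a tandem/ovoid label per dwell.
#' @export
applicator_model <- function(os_position = c(0, 0, 0),
                             tandem_axis = c(0, 0, 1),
                             lateral_axis = c(1, 0, 0),
                             tandem_dwell_mm = seq(10, 50, by = 5),
                             ovoid_offset = c(13, 0, -5),
                             dwells_per_ovoid = 2,
                             step_size = 5) {
  stopifnot(length(os_position) == 3, length(tandem_axis) == 3,
            length(lateral_axis) == 3, dwells_per_ovoid >= 1,
            dwells_per_ovoid <= 3, step_size > 0,
            length(tandem_dwell_mm) >= 1)
  nt <- sqrt(sum(tandem_axis^2))
  if (nt < 1e-9) stop("degenerate tandem_axis")
  tandem_axis <- tandem_axis / nt
  # orthonormalize lateral axis against the tandem axis
  lat <- lateral_axis - sum(lateral_axis * tandem_axis) * tandem_axis
  nl <- sqrt(sum(lat^2))
  if (nl < 1e-9) stop("lateral_axis parallel to tandem_axis")
  lat <- lat / nl
  ant <- c(tandem_axis[2] * lat[3] - tandem_axis[3] * lat[2],
           tandem_axis[3] * lat[1] - tandem_axis[1] * lat[3],
           tandem_axis[1] * lat[2] - tandem_axis[2] * lat[1])
  # anterior = tandem x lateral completes the right-handed frame

  tandem <- t(vapply(tandem_dwell_mm,
                     function(d) os_position + d * tandem_axis,
                     numeric(3)))
  ov_steps <- (seq_len(dwells_per_ovoid) - (dwells_per_ovoid + 1) / 2) * step_size
  ov_one <- function(side) {
    t(vapply(ov_steps, function(s) {
      os_position + side * ovoid_offset[1] * lat +
        ovoid_offset[2] * ant + (ovoid_offset[3] + s) * tandem_axis
    }, numeric(3)))
  }
  ovoid_right <- ov_one(+1)
  ovoid_left <- ov_one(-1)

  positions <- rbind(tandem, ovoid_left, ovoid_right)
  labels <- c(rep("tandem", nrow(tandem)),
              rep("ovoid_left", nrow(ovoid_left)),
              rep("ovoid_right", nrow(ovoid_right)))
  orientations <- matrix(rep(tandem_axis, nrow(positions)),
                         ncol = 3, byrow = TRUE)

  structure(
    list(os_position = as.numeric(os_position),
         tandem_axis = tandem_axis,
         lateral_axis = lat,
         anterior_axis = ant,
         tandem_dwell_mm = tandem_dwell_mm,
         ovoid_offset = as.numeric(ovoid_offset),
         dwell_positions = positions,
         dwell_orientations = orientations,
         dwell_labels = labels,
         step_size = step_size),
    class = "applicator_model"
  )
}

#' Number of dwells of an applicator
#' @param applicator An [applicator_model()].
#' @return Integer dwell count.
#' @export
n_dwells <- function(applicator) nrow(applicator$dwell_positions)

#' Manchester Point A pair
#'
#' Point A lies 20 mm superior to the external cervical os along the
#' tandem axis, then 20 mm laterally (left and right) in the tandem's
#' frontal plane. The prescription (7 Gy per fraction in the default
#' protocol) is normalized to the mean dose of the two points.
#'
#' @param applicator An [applicator_model()].
#' @return 2 x 3 matrix, rows `A_left` and `A_right`, mm.
#' @export
manchester_points <- function(applicator) {
  stopifnot(inherits(applicator, "applicator_model"))
  up <- applicator$os_position + 20 * applicator$tandem_axis
  out <- rbind(A_left = up - 20 * applicator$lateral_axis,
               A_right = up + 20 * applicator$lateral_axis)
  out
}

#' Apply a rigid transform to an applicator
#'
#' Moves the whole applicator (dwells, axes, os) rigidly; used by the
#' uncertainty module to model positioning error while anatomy stays
#' fixed.
#'
#' @param applicator An [applicator_model()].
#' @param t A [rigid_transform()].
#' @return Transformed `applicator_model`.
#' @export
transform_applicator <- function(applicator, t) {
  stopifnot(inherits(applicator, "applicator_model"),
            inherits(t, "rigid_transform"))
  out <- applicator
  out$os_position <- apply_transform(t, applicator$os_position)
  out$tandem_axis <- apply_rotation(t, applicator$tandem_axis)
  out$lateral_axis <- apply_rotation(t, applicator$lateral_axis)
  out$anterior_axis <- apply_rotation(t, applicator$anterior_axis)
  out$dwell_positions <- apply_transform(t, applicator$dwell_positions)
  out$dwell_orientations <- apply_rotation(t, applicator$dwell_orientations)
  out
}

#' @export
print.applicator_model <- function(x, ...) {
  cat("tandem-and-ovoids applicator:", n_dwells(x), "dwells (",
      sum(x$dwell_labels == "tandem"), "tandem +",
      sum(x$dwell_labels != "tandem"), "ovoid )\n")
  cat("  os at (", paste(signif(x$os_position, 4), collapse = ", "),
      ") mm, tandem axis (",
      paste(signif(x$tandem_axis, 4), collapse = ", "), ")\n")
  cat("  step size", x$step_size, "mm\n")
  invisible(x)
}
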