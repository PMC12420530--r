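# shared fixtures built in code

# analytic kernel: point mode, g = F = 1 (pure inverse square)
flat_point_source <- function(sk = 1000) co60_source(air_kerma_strength = sk,
                                                     mode = "point", flat = TRUE)

# build a dose_grid directly from a dose array (bypasses the engine);
# used to feed DVH/index oracles hand-set dose fields
toy_dose_grid <- function(dose_array, voxel_size = c(1, 1, 1), rx = 7,
                          in_applicator = NULL) {
  dims <- dim(dose_array)
  if (is.null(in_applicator)) in_applicator <- array(FALSE, dim = dims)
  structure(
    list(dose = dose_array, in_applicator = in_applicator,
         grid_origin = c(0, 0, 0), voxel_size = voxel_size, dim = dims,
         prescription_dose = rx, n_fractions = 4L),
    class = "dose_grid"
  )
}

# a one-dwell "applicator" for single-source analytic checks
single_dwell_applicator <- function(position = c(0, 0, 0)) {
  a <- applicator_model(os_position = position - c(0, 0, 10),
                        tandem_dwell_mm = 10, dwells_per_ovoid = 1,
                        ovoid_offset = c(13, 0, -5))
  # keep only the tandem dwell at `position`
  keep <- a$dwell_labels == "tandem"
  a$dwell_positions <- a$dwell_positions[keep, , drop = FALSE]
  a$dwell_orientations <- a$dwell_orientations[keep, , drop = FALSE]
  a$dwell_labels <- a$dwell_labels[keep]
  a
}

# small reference phantom at coarse resolution for integration tests
coarse_phantom <- function(voxel = c(2.5, 2.5, 2.5)) {
  make_phantom(phantom_spec(), voxel_size = voxel)
}
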