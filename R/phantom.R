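#' Phantom specification
#'
#' Parameters of a synthetic pelvic phantom: an ellipsoidal HR-CTV
#' centred on the tandem plus four organs at risk (bladder anterior,
#' rectum posterior, sigmoid posterior-superior, bowel superior) placed
#' by their nominal wall-to-tandem distances. The phantom stands in for
#' a contoured planning CT; structures are geometric primitives, not
#' segmentations.
#'
#' @param hrctv_semi_axes Length-3 HR-CTV ellipsoid semi-axes, mm.
#' @param hrctv_center_offset Length-3 offset of the HR-CTV centre from
#'   the cervical os, mm.
#' @param organ_offsets Named numeric (bladder, rectum, sigmoid, bowel):
#'   nominal closest wall-to-tandem distances, mm. The construction
#'   guarantees bladder <= rectum <= sigmoid <= bowel ordering of actual
#'   minimal wall distances when the offsets are ordered.
#' @param organ_volumes Named numeric, target organ volumes in cm^3.
#' @param seed Integer; reserved for per-phantom stochastic detail
#'   (construction is fully deterministic given the spec).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(hrctv_semi_axes = c(24, 20, 30),
                         hrctv_center_offset = c(0, 0, 20),
                         organ_offsets = c(bladder = 14, rectum = 19.5,
                                           sigmoid = 22, bowel = 24.5),
                         organ_volumes = c(bladder = 70, rectum = 45,
                                           sigmoid = 35, bowel = 60),
                         seed = 1L) {
  organs <- c("bladder", "rectum", "sigmoid", "bowel")
  stopifnot(length(hrctv_semi_axes) == 3, all(hrctv_semi_axes > 0),
            length(hrctv_center_offset) == 3,
            all(organs %in% names(organ_offsets)),
            all(organs %in% names(organ_volumes)),
            all(organ_offsets > 0), all(organ_volumes > 0))
  vol <- 4 / 3 * pi * prod(hrctv_semi_axes) / 1000
  if (vol < 10 || vol > 80) {
    stop("HR-CTV volume ", signif(vol, 3), " cm^3 outside plausible [10, 80]")
  }
  structure(
    list(hrctv_semi_axes = as.numeric(hrctv_semi_axes),
         hrctv_center_offset = as.numeric(hrctv_center_offset),
         organ_offsets = organ_offsets[organs],
         organ_volumes = organ_volumes[organs],
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# fixed per-organ ellipsoid aspect ratios (x, y, z)
.organ_aspect <- list(
  bladder = c(1.2, 0.9, 1.0),
  rectum  = c(0.7, 0.7, 2.0),   # elongated along the canal
  sigmoid = c(1.4, 0.8, 1.2),
  bowel   = c(2.0, 1.3, 0.55)   # loops draping flat over the fundus
)

# semi-axes of an ellipsoid with volume V (cm^3) and aspect ratios p
.semi_axes_for_volume <- function(V_cm3, p) {
  s <- (3 * V_cm3 * 1000 / (4 * pi * prod(p)))^(1 / 3)
  s * p
}

#' Build a synthetic pelvic phantom
#'
#' Voxelizes the spec's structures on a common grid and places the
#' default tandem-and-ovoids applicator at the os (origin). Organ masks
#' are made pairwise disjoint by priority (HR-CTV first, then bladder,
#' rectum, sigmoid, bowel). Deterministic given the spec.
#'
#' @param spec A [phantom_spec()].
#' @param voxel_size Length-3 voxel dimensions in mm; `c(1, 1, 1)` by
#'   default, `c(1, 1, 2.5)` gives a CT-like grid emulating 2.5 mm
#'   slices.
#' @param grid_margin Margin around the union of structures, mm.
#' @return List with elements `structures` (a `structure_set`) and
#'   `applicator` (an [applicator_model()]).
#' @export
make_phantom <- function(spec, voxel_size = c(1, 1, 1), grid_margin = 5) {
  stopifnot(inherits(spec, "phantom_spec"), length(voxel_size) == 3,
            all(voxel_size > 0))
  applicator <- applicator_model()
  os <- applicator$os_position
  z_top <- max(spec$hrctv_center_offset[3] + spec$hrctv_semi_axes[3],
               max(applicator$tandem_dwell_mm))

  geom <- list()
  geom$hrctv <- list(center = os + spec$hrctv_center_offset,
                     semi = spec$hrctv_semi_axes)
  off <- spec$organ_offsets
  # each organ sits along an anatomical direction from an anchor on the
  # tandem; the offset is the closest wall-to-tandem distance by
  # construction (centre = anchor + (offset + ellipsoid radius along the
  # direction) * direction)
  placement <- list(
    bladder = list(anchor = c(0, 0, 25), dir = c(0, 1, 0)),
    rectum  = list(anchor = c(0, 0, 10), dir = c(0, -1, 0)),
    sigmoid = list(anchor = c(0, 0, 40), dir = c(0, -0.7, 0.714)),
    bowel   = list(anchor = c(0, 0, 42), dir = c(0, 0.6, 0.8))
  )
  for (org in names(off)) {
    semi <- .semi_axes_for_volume(spec$organ_volumes[[org]], .organ_aspect[[org]])
    pl <- placement[[org]]
    u <- pl$dir / sqrt(sum(pl$dir^2))
    r_dir <- 1 / sqrt(sum((u / semi)^2)) # ellipsoid radius along u
    center <- pl$anchor + (off[[org]] + r_dir) * u
    geom[[org]] <- list(center = os + center, semi = semi)
  }

  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (g in geom) {
    lo <- pmin(lo, g$center - g$semi)
    hi <- pmax(hi, g$center + g$semi)
  }
  lo <- pmin(lo, apply(applicator$dwell_positions, 2, min))
  hi <- pmax(hi, apply(applicator$dwell_positions, 2, max))
  lo <- floor((lo - grid_margin) / voxel_size) * voxel_size
  hi <- ceiling((hi + grid_margin) / voxel_size) * voxel_size
  dims <- as.integer(round((hi - lo) / voxel_size))

  xc <- lo[1] + (seq_len(dims[1]) - 0.5) * voxel_size[1]
  yc <- lo[2] + (seq_len(dims[2]) - 0.5) * voxel_size[2]
  zc <- lo[3] + (seq_len(dims[3]) - 0.5) * voxel_size[3]

  ellipsoid_mask <- function(g) {
    qx <- ((xc - g$center[1]) / g$semi[1])^2
    qy <- ((yc - g$center[2]) / g$semi[2])^2
    qz <- ((zc - g$center[3]) / g$semi[3])^2
    array(outer(outer(qx, qy, `+`), qz, `+`) <= 1, dim = dims)
  }

  masks <- lapply(geom, ellipsoid_mask)
  names(masks)[1] <- "hrctv"
  # enforce disjointness by priority order
  taken <- array(FALSE, dim = dims)
  for (nm in names(masks)) {
    masks[[nm]] <- masks[[nm]] & !taken
    taken <- taken | masks[[nm]]
  }
  counts <- vapply(masks, sum, numeric(1))
  if (any(counts < 20)) {
    stop("grid too coarse: structure(s) ",
         paste(names(counts)[counts < 20], collapse = ", "),
         " resolved by fewer than 20 voxels")
  }

  structures <- structure_set(grid_origin = lo, voxel_size = voxel_size,
                              masks = masks)
  list(structures = structures, applicator = applicator)
}

#' Structure set on a voxel grid
#'
#' @param grid_origin Length-3 grid corner (minimum coordinate), mm.
#' @param voxel_size Length-3 voxel size, mm.
#' @param masks Named list of logical 3-D arrays of identical dimension;
#'   must include a nonempty `hrctv`.
#' @return Object of class `structure_set`; `volumes` holds
#'   voxel_count x voxel_volume in cm^3 per structure.
#' @export
structure_set <- function(grid_origin, voxel_size, masks) {
  stopifnot(length(grid_origin) == 3, length(voxel_size) == 3,
            all(voxel_size > 0), is.list(masks), length(masks) >= 1,
            !is.null(names(masks)))
  dims <- dim(masks[[1]])
  for (m in masks) {
    stopifnot(is.logical(m), identical(dim(m), dims))
  }
  if (!"hrctv" %in% names(masks) || sum(masks$hrctv) == 0) {
    stop("structure set must contain a nonempty hrctv mask")
  }
  voxvol <- prod(voxel_size) / 1000 # cm^3
  structure(
    list(grid_origin = as.numeric(grid_origin),
         voxel_size = as.numeric(voxel_size),
         dim = dims,
         masks = masks,
         volumes = vapply(masks, function(m) sum(m) * voxvol, numeric(1))),
    class = "structure_set"
  )
}

# voxel-centre coordinate vectors of a structure_set grid
grid_axes <- function(ss) {
  list(x = ss$grid_origin[1] + (seq_len(ss$dim[1]) - 0.5) * ss$voxel_size[1],
       y = ss$grid_origin[2] + (seq_len(ss$dim[2]) - 0.5) * ss$voxel_size[2],
       z = ss$grid_origin[3] + (seq_len(ss$dim[3]) - 0.5) * ss$voxel_size[3])
}

#' @export
print.structure_set <- function(x, ...) {
  cat("structure set:", paste(x$dim, collapse = " x "), "voxels at",
      paste(x$voxel_size, collapse = " x "), "mm\n")
  v <- signif(x$volumes, 4)
  for (nm in names(v)) cat(sprintf("  %-8s %8.2f cm^3\n", nm, v[[nm]]))
  invisible(x)
}

# truncated normal sampler (rejection; sd = 0 degenerates to the mean)
rtnorm1 <- function(mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:10000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stop("invalid distribution bounds: rejection sampling failed for mean ",
       mean, ", sd ", sd, " on [", lo, ", ", hi, "]")
}

#' Default cohort population configuration
#'
#' Inter-patient variability of the phantom geometry, expressed as
#' truncated normal distributions around the nominal [phantom_spec()].
#' The spreads are calibration: they were chosen so that a planned
#' cohort reproduces the clinically observed organ dose ordering
#' (bladder > rectum > sigmoid > bowel D2cc) with realistic relative
#' variability (larger for sigmoid/bowel than bladder/rectum), not
#' measured anatomy statistics.
#'
#' @return A list with `nominal` (a `phantom_spec`), per-parameter `sd`
#'   and truncation `bounds`.
#' @export
default_population <- function() {
  list(
    nominal = phantom_spec(),
    sd = list(hrctv_semi_axes = c(1.5, 1.5, 2.0),
              organ_offsets = c(bladder = 2.0, rectum = 2.5,
                                sigmoid = 5.5, bowel = 5.5),
              organ_volumes = c(bladder = 8, rectum = 5,
                                sigmoid = 5, bowel = 8)),
    bounds = list(hrctv_semi_axes = c(14, 34),
                  organ_offsets = list(bladder = c(10, 19), rectum = c(15, 27),
                                       sigmoid = c(16, 40), bowel = c(18, 44)),
                  organ_volumes = c(15, 110)),
    # minimum wall-offset separation between successive organs, mm:
    # keeps the anatomical ordering bladder < rectum < sigmoid < bowel
    # strict for every sampled patient
    min_gap = c(3, 2, 2)
  )
}

#' Sample a synthetic phantom cohort
#'
#' Draws `n` patient phantoms from the population distribution,
#' reproducibly from a master seed, and voxelizes each.
#'
#' @param n Cohort size (the emulated study uses 30).
#' @param population A population configuration, see
#'   [default_population()].
#' @param master_seed Integer seed controlling the whole cohort.
#' @param voxel_size Grid resolution passed to [make_phantom()].
#' @return List of length `n`; each element has `spec`, `structures`,
#'   `applicator`.
#' @export
sample_cohort <- function(n, population = default_population(),
                          master_seed = 17L, voxel_size = c(1, 1, 1)) {
  stopifnot(n >= 1)
  nom <- population$nominal
  sds <- population$sd
  bnd <- population$bounds
  set.seed(as.integer(master_seed))
  organs <- names(nom$organ_offsets)
  lapply(seq_len(n), function(i) {
    # rejection on the joint volume plausibility bound [10, 80] cm^3
    repeat {
      semi <- vapply(1:3, function(k) {
        rtnorm1(nom$hrctv_semi_axes[k], sds$hrctv_semi_axes[k],
                bnd$hrctv_semi_axes[1], bnd$hrctv_semi_axes[2])
      }, numeric(1))
      v <- 4 / 3 * pi * prod(semi) / 1000
      if (v >= 10 && v <= 80) break
    }
    offs <- vapply(organs, function(org) {
      b <- bnd$organ_offsets[[org]]
      rtnorm1(nom$organ_offsets[[org]], sds$organ_offsets[[org]], b[1], b[2])
    }, numeric(1))
    # preserve the anatomical ordering bladder < rectum < sigmoid < bowel
    offs <- sort(offs)
    gap <- if (is.null(population$min_gap)) c(3, 2, 2) else population$min_gap
    for (k in 2:4) offs[k] <- max(offs[k], offs[k - 1] + gap[k - 1])
    names(offs) <- organs
    vols <- vapply(organs, function(org) {
      rtnorm1(nom$organ_volumes[[org]], sds$organ_volumes[[org]],
              bnd$organ_volumes[1], bnd$organ_volumes[2])
    }, numeric(1))
    sp <- phantom_spec(hrctv_semi_axes = semi,
                       hrctv_center_offset = nom$hrctv_center_offset,
                       organ_offsets = offs,
                       organ_volumes = vols,
                       seed = master_seed + i)
    ph <- make_phantom(sp, voxel_size = voxel_size)
    list(spec = sp, structures = ph$structures, applicator = ph$applicator)
  })
}
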