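#' Co-60 HDR source model (TG-43 parameterization)
#'
#' Constructs a sealed-source dose-rate model following the AAPM TG-43
#' formalism: dose rate = Sk * Lambda * G(r,theta)/G(r0,theta0) * g(r) *
#' F(r,theta), with the reference point at r0 = 1 cm, theta0 = 90 degrees.
#' Radial dose function and anisotropy tables are renormalized on
#' construction so that g(1 cm) = 1 exactly and F(r, 90 deg) = 1 for every
#' tabulated radius.
#'
#' @param air_kerma_strength Air-kerma strength Sk in U (uGy m^2 h^-1).
#' @param dose_rate_constant Dose-rate constant Lambda in cGy h^-1 U^-1.
#' @param active_length Active source length in mm (used in line mode).
#' @param radial_dose_table data.frame with columns `r_cm` (strictly
#'   increasing) and `g` (dimensionless radial dose function).
#' @param anisotropy_table data.frame with columns `r_cm`, `theta_deg`,
#'   `F` on a full (r, theta) grid, theta in [0, 180].
#' @param mode `"line"` for the line-source geometry factor, `"point"`
#'   for inverse square.
#' @param r_min Minimum meaningful radius in cm; dose requests below it
#'   are an error ("too close to source") and voxels that close are
#'   masked as in-applicator by the dose engine.
#'
#' @return An object of class `source_model`.
#' @seealso [co60_source()] for the packaged generic Co-60 configuration,
#'   [dose_rate_at()] for point evaluations.
#' @export
source_model <- function(air_kerma_strength,
                         dose_rate_constant,
                         active_length,
                         radial_dose_table,
                         anisotropy_table,
                         mode = c("line", "point"),
                         r_min = 0.1) {
  mode <- match.arg(mode)
  stopifnot(
    is.numeric(air_kerma_strength), air_kerma_strength > 0,
    is.numeric(dose_rate_constant), dose_rate_constant > 0,
    is.numeric(active_length), active_length > 0,
    is.numeric(r_min), r_min > 0
  )
  rd <- as.data.frame(radial_dose_table)
  if (!all(c("r_cm", "g") %in% names(rd))) {
    stop("radial_dose_table needs columns r_cm and g")
  }
  rd <- rd[order(rd$r_cm), , drop = FALSE]
  if (any(diff(rd$r_cm) <= 0)) stop("radial_dose_table radii must be strictly increasing")
  # renormalize so g(1 cm) = 1 exactly
  g1 <- stats::approx(rd$r_cm, rd$g, xout = 1, rule = 2)$y
  rd$g <- rd$g / g1

  an <- as.data.frame(anisotropy_table)
  if (!all(c("r_cm", "theta_deg", "F") %in% names(an))) {
    stop("anisotropy_table needs columns r_cm, theta_deg and F")
  }
  r_grid <- sort(unique(an$r_cm))
  th_grid <- sort(unique(an$theta_deg))
  if (min(th_grid) > 0 || max(th_grid) < 180) {
    stop("anisotropy table must span theta in [0, 180] degrees")
  }
  Fm <- matrix(NA_real_, nrow = length(r_grid), ncol = length(th_grid))
  ir <- match(an$r_cm, r_grid)
  it <- match(an$theta_deg, th_grid)
  Fm[cbind(ir, it)] <- an$F
  if (anyNA(Fm)) stop("anisotropy table must be a full (r, theta) grid")
  # renormalize each radius row by its value at theta = 90
  f90 <- apply(Fm, 1L, function(row) stats::approx(th_grid, row, xout = 90, rule = 2)$y)
  Fm <- Fm / f90

  structure(
    list(
      air_kerma_strength = air_kerma_strength,
      dose_rate_constant = dose_rate_constant,
      active_length = active_length,
      radial_dose_table = rd,
      anisotropy_r = r_grid,
      anisotropy_theta = th_grid,
      anisotropy_F = Fm,
      mode = mode,
      r_min = r_min
    ),
    class = "source_model"
  )
}

#' Packaged generic Co-60 HDR source
#'
#' Loads the generic Co-60 HDR source configuration shipped with the
#' package: dose-rate constant 1.087 cGy h^-1 U^-1, 3.5 mm active length
#' and smooth g(r) / F(r,theta) tables typical of clinical Co-60 HDR
#' sources. The tables are versioned configuration shipped as CSV, not
#' measured ground truth; substitute site-specific tables via
#' [source_model()] when available.
#'
#' @param air_kerma_strength Sk in U; default corresponds to roughly a
#'   2 Ci Co-60 source.
#' @param mode `"line"` or `"point"`. Point mode with `flat = TRUE`
#'   gives the analytic inverse-square kernel used in validation tests.
#' @param flat If TRUE, replace g and F by 1 everywhere (analytic mode).
#' @return A `source_model`.
#' @export
co60_source <- function(air_kerma_strength = 22700,
                        mode = c("line", "point"),
                        flat = FALSE) {
  mode <- match.arg(mode)
  if (flat) {
    rd <- data.frame(r_cm = c(0.1, 20), g = c(1, 1))
    an <- expand.grid(r_cm = c(0.1, 20), theta_deg = c(0, 90, 180))
    an$F <- 1
  } else {
    rd <- utils::read.csv(system.file("extdata", "co60_radial_dose.csv",
                                      package = "cobraplan"))
    an <- utils::read.csv(system.file("extdata", "co60_anisotropy.csv",
                                      package = "cobraplan"))
  }
  source_model(
    air_kerma_strength = air_kerma_strength,
    dose_rate_constant = 1.087,
    active_length = 3.5,
    radial_dose_table = rd,
    anisotropy_table = an,
    mode = mode
  )
}

# TG-43 geometry factor, vectorized over (r, theta).
# r in cm, theta in degrees, L in cm. Line mode uses the subtended-angle
# formula G_L = beta / (L * r * sin(theta)), with the on-axis limit
# 1 / (r^2 - L^2/4).
geometry_factor <- function(r, theta_deg, L_cm, mode) {
  if (mode == "point") return(1 / r^2)
  th <- theta_deg * pi / 180
  x <- r * sin(th)           # transverse distance
  z <- r * cos(th)           # along source axis
  out <- numeric(length(r))
  on_axis <- x < 1e-9
  if (any(!on_axis)) {
    xs <- x[!on_axis]; zs <- z[!on_axis]
    beta <- atan2(xs, zs - L_cm / 2) - atan2(xs, zs + L_cm / 2)
    out[!on_axis] <- beta / (L_cm * xs)
  }
  if (any(on_axis)) {
    r2 <- r[on_axis]^2 - L_cm^2 / 4
    if (any(r2 <= 0)) stop("field point inside the active source length")
    out[on_axis] <- 1 / r2
  }
  out
}

# Linear interpolation of g(r), clamped to the table edges beyond range.
radial_dose_g <- function(source, r) {
  rd <- source$radial_dose_table
  stats::approx(rd$r_cm, rd$g, xout = r, rule = 2)$y
}

# Bilinear interpolation of F(r, theta), clamped at the table edges.
# Hand-vectorized (findInterval) for speed in the voxel loop.
anisotropy_F <- function(source, r, theta_deg) {
  rg <- source$anisotropy_r
  tg <- source$anisotropy_theta
  Fm <- source$anisotropy_F
  nr <- length(rg); nt <- length(tg)
  rq <- pmin(pmax(r, rg[1]), rg[nr])
  thq <- pmin(pmax(theta_deg, tg[1]), tg[nt])
  i <- pmin(findInterval(rq, rg), nr - 1L)
  j <- pmin(findInterval(thq, tg), nt - 1L)
  wr <- (rq - rg[i]) / (rg[i + 1L] - rg[i])
  wt <- (thq - tg[j]) / (tg[j + 1L] - tg[j])
  f00 <- Fm[cbind(i, j)]
  f10 <- Fm[cbind(i + 1L, j)]
  f01 <- Fm[cbind(i, j + 1L)]
  f11 <- Fm[cbind(i + 1L, j + 1L)]
  (1 - wr) * ((1 - wt) * f00 + wt * f01) + wr * ((1 - wt) * f10 + wt * f11)
}

# radius (cm) below which voxels are treated as in-applicator: at least
# r_min, and in line mode also the on-axis singular zone of the active
# length (|z| < L/2 has no defined line-source geometry factor)
mask_radius_cm <- function(source) {
  if (source$mode == "line") {
    max(source$r_min, 0.55 * source$active_length / 10)
  } else {
    source$r_min
  }
}

# Core vectorized kernel: dose rate (cGy/h) at many field points from one
# dwell. Positions in mm; internal radii in cm.
dose_rate_kernel <- function(source, dwell_position, dwell_orientation,
                             px, py, pz, clamp_rmin = FALSE) {
  dx <- (px - dwell_position[1]) / 10
  dy <- (py - dwell_position[2]) / 10
  dz <- (pz - dwell_position[3]) / 10
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  if (clamp_rmin) r <- pmax(r, mask_radius_cm(source))
  ct <- (dx * dwell_orientation[1] + dy * dwell_orientation[2] +
           dz * dwell_orientation[3]) / r
  ct <- pmin(pmax(ct, -1), 1)
  theta <- acos(ct) * 180 / pi
  L_cm <- source$active_length / 10
  G <- geometry_factor(r, theta, L_cm, source$mode)
  G0 <- geometry_factor(1, 90, L_cm, source$mode)
  source$air_kerma_strength * source$dose_rate_constant *
    (G / G0) * radial_dose_g(source, r) * anisotropy_F(source, r, theta)
}

#' TG-43 dose rate at a field point
#'
#' Evaluates the TG-43 dose rate (cGy/h) delivered by a single dwell to a
#' field point.
#'
#' @param source A [source_model()].
#' @param dwell_position Numeric length-3, dwell position in mm.
#' @param dwell_orientation Unit length-3 vector: the source long axis.
#' @param field_point Numeric length-3, evaluation point in mm.
#' @return Dose rate in cGy/h (strictly positive scalar).
#' @examples
#' src <- co60_source(mode = "point", flat = TRUE)
#' # pure inverse square in flat point mode:
#' dose_rate_at(src, c(0, 0, 0), c(0, 0, 1), c(10, 0, 0)) /
#'   dose_rate_at(src, c(0, 0, 0), c(0, 0, 1), c(20, 0, 0)) # = 4
#' @export
dose_rate_at <- function(source, dwell_position, dwell_orientation, field_point) {
  stopifnot(inherits(source, "source_model"),
            length(dwell_position) == 3, length(field_point) == 3,
            length(dwell_orientation) == 3)
  nrm <- sqrt(sum(dwell_orientation^2))
  if (abs(nrm - 1) > 1e-6) stop("dwell_orientation must be a unit vector")
  r_cm <- sqrt(sum((field_point - dwell_position)^2)) / 10
  if (r_cm < source$r_min) {
    stop("too close to source: r = ", signif(r_cm, 3), " cm < r_min = ",
         source$r_min, " cm")
  }
  dose_rate_kernel(source, dwell_position, dwell_orientation,
                   field_point[1], field_point[2], field_point[3])
}

#' @export
print.source_model <- function(x, ...) {
  cat("TG-43 source model (", x$mode, " mode)\n", sep = "")
  cat("  Sk     =", x$air_kerma_strength, "U\n")
  cat("  Lambda =", x$dose_rate_constant, "cGy/h/U\n")
  cat("  L      =", x$active_length, "mm\n")
  cat("  g(r) table:", nrow(x$radial_dose_table), "radii,",
      "r in [", min(x$radial_dose_table$r_cm), ",",
      max(x$radial_dose_table$r_cm), "] cm\n")
  cat("  F(r,theta) grid:", length(x$anisotropy_r), "radii x",
      length(x$anisotropy_theta), "angles\n")
  invisible(x)
}
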