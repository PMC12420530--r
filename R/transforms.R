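#' Rigid-body transform
#'
#' A rigid transform in the patient frame (mm): rotation about a pivot,
#' applied in the order x then y then z, followed by a translation. Used
#' to model applicator displacement (+/- 1 mm) and rotational
#' (+/- 2 degrees per axis) positioning uncertainty.
#'
#' @param translation Length-3 translation in mm.
#' @param rotation_deg Length-3 rotation angles in degrees about the x,
#'   y and z axes (applied x, then y, then z).
#' @param pivot Length-3 rotation pivot in mm (default origin; the
#'   uncertainty module pivots at the cervical os).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0),
                            rotation_deg = c(0, 0, 0),
                            pivot = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, length(rotation_deg) == 3,
            length(pivot) == 3)
  a <- rotation_deg * pi / 180
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])),
              c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0),
              c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  structure(
    list(translation = as.numeric(translation),
         rotation_deg = as.numeric(rotation_deg),
         pivot = as.numeric(pivot),
         R = Rz %*% Ry %*% Rx),
    class = "rigid_transform"
  )
}

#' Apply a rigid transform to points
#'
#' Rotates points about the transform's pivot, then translates. With zero
#' translation the map is distance preserving.
#'
#' @param t A [rigid_transform()].
#' @param points Numeric matrix (n x 3) or length-3 vector, mm.
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(t, points) {
  stopifnot(inherits(t, "rigid_transform"))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, ncol = 3) else as.matrix(points)
  stopifnot(ncol(p) == 3)
  out <- sweep(p, 2, t$pivot) %*% t(t$R)
  out <- sweep(out, 2, t$pivot + t$translation, `+`)
  if (vec) as.numeric(out) else out
}

# Rotate direction vectors (no pivot, no translation).
apply_rotation <- function(t, vectors) {
  vec <- is.null(dim(vectors))
  v <- if (vec) matrix(vectors, ncol = 3) else as.matrix(vectors)
  out <- v %*% t(t$R)
  if (vec) as.numeric(out) else out
}

#' Homogeneous 4x4 matrix of a rigid transform
#'
#' @param t A [rigid_transform()].
#' @return 4x4 matrix mapping homogeneous points (mm).
#' @export
transform_matrix <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  M <- diag(4)
  M[1:3, 1:3] <- t$R
  M[1:3, 4] <- t$pivot - t$R %*% t$pivot + t$translation
  M
}

#' Inverse of a rigid transform
#'
#' Composition with the inverse is the identity to within 1e-9 mm.
#'
#' @param t A [rigid_transform()].
#' @return A `rigid_transform` whose rotation matrix is the transpose and
#'   whose translation undoes `t` (expressed with pivot at the origin).
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  M <- transform_matrix(t)
  Rin <- t(t$R)
  out <- rigid_transform()
  out$R <- Rin
  out$pivot <- c(0, 0, 0)
  out$translation <- as.numeric(-Rin %*% M[1:3, 4])
  out$rotation_deg <- c(NA_real_, NA_real_, NA_real_) # composite; matrix is canonical
  out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform: rotation (deg x/y/z) =",
      paste(signif(x$rotation_deg, 4), collapse = ", "),
      "| translation (mm) =",
      paste(signif(x$translation, 4), collapse = ", "),
      "| pivot (mm) =", paste(signif(x$pivot, 4), collapse = ", "), "\n")
  invisible(x)
}
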