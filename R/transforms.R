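# Rigid-transform algebra. Internally rotations are composed in the
# (x, y, z) basis as R = Rz(rz) %*% Ry(ry) %*% Rx(rx) (degrees) and then
# reordered to the package's (z, y, x) axis convention.

.rotationMatrixXYZ <- function(rotations) {
  a <- rotations * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

.anglesFromRotationXYZ <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ry <- asin(sy)
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rz, ry, rx) * 180 / pi
}

# 3x3 matrix acting on (z, y, x) coordinate vectors.
.rotationMatrixZYX <- function(rotations) {
  R <- .rotationMatrixXYZ(rotations)
  p <- c(3, 2, 1)
  R[p, p]
}

# Physical centre of a volume (z, y, x mm).
.physCenter <- function(vol) {
  origin(vol) + (dim(vol) - 1) / 2 * spacing(vol)
}

# Affine (M, b) over (z, y, x) physical coords: q = M p + b, rotation about
# centre c: q = R (p - c) + c + t.
.affineFor <- function(transform, center) {
  M <- .rotationMatrixZYX(transform@rotations)
  b <- center + transform@translations - M %*% center
  list(M = M, b = as.numeric(b))
}

#' Compose and invert rigid transforms
#'
#' `composeTransforms(a, b)` returns the transform applying `b` first and
#' then `a` (matrix-product order); `invertTransform(a)` returns the
#' transform undoing `a`. Both assume rotation about a common centre.
#' Composing a transform with its inverse yields the identity to within
#' 1e-6.
#'
#' @param a,b [RigidTransform-class] objects.
#' @return A [RigidTransform-class].
#' @examples
#' a <- rigidTransform(rotations = c(5, 0, 0), translations = c(1, 2, 3))
#' composeTransforms(a, invertTransform(a))
#' @export
composeTransforms <- function(a, b) {
  Ra <- .rotationMatrixXYZ(a@rotations)
  Rb <- .rotationMatrixXYZ(b@rotations)
  Rc <- Ra %*% Rb
  # translations live in (z,y,x); rotate via the zyx-ordered matrix
  tc <- as.numeric(.rotationMatrixZYX(a@rotations) %*% b@translations) +
    a@translations
  rigidTransform(rotations = .anglesFromRotationXYZ(Rc), translations = tc)
}

#' @rdname composeTransforms
#' @export
invertTransform <- function(a) {
  Rt <- t(.rotationMatrixXYZ(a@rotations))
  ti <- -as.numeric(t(.rotationMatrixZYX(a@rotations)) %*% a@translations)
  rigidTransform(rotations = .anglesFromRotationXYZ(Rt), translations = ti)
}

#' Read and write rigid transforms as plain text
#'
#' Transforms are serialized as a small JSON record holding the six
#' parameters with the package's conventions (degrees about the reference
#' centre, mm translations, (z, y, x) order).
#'
#' @param transform a [RigidTransform-class].
#' @param path file path.
#' @return `readTransform()` returns a [RigidTransform-class];
#'   `writeTransform()` returns `path` invisibly.
#' @export
writeTransform <- function(transform, path) {
  jsonlite::write_json(
    list(rotations_deg_zyx = transform@rotations,
         translations_mm_zyx = transform@translations,
         convention = "p_moving = R (p_fixed - center) + center + t"),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform(rotations = x$rotations_deg_zyx,
                 translations = x$translations_mm_zyx)
}
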