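# NIfTI input/output. On disk the array is stored in (x, y, z) =
# (col, row, slice) order with a diagonal sform; in memory the package uses
# (slice, row, col). Conversion is a pure axis permutation, so write/read
# round trips are exact.

#' Read and write CT volumes as NIfTI
#'
#' `readVolume()` reads a `.nii`/`.nii.gz` file into a [CTVolume-class] in
#' Hounsfield units with geometry taken from the header; `writeVolume()` is
#' its inverse. Only axis-aligned (axial) orientations are supported;
#' oblique headers raise an error.
#'
#' @param path a NIfTI file path.
#' @param vol a [CTVolume-class].
#' @param patientId identifier stored on the returned volume.
#' @return `readVolume()`: a [CTVolume-class]. `writeVolume()`: `path`,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(ctVolume(array(0, c(2, 4, 4)), spacing = c(5, 1, 1)), f)
#' spacing(readVolume(f))
#' @seealso [writeMask()], [readDicomSeries()]
#' @export
readVolume <- function(path, patientId = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path, internal = FALSE)
  arr <- as.array(img)
  if (is.null(dim(arr))) dim(arr) <- length(arr)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) < 3L)
    dim(arr) <- c(dim(arr), rep(1L, 3L - length(dim(arr))))
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D NIfTI volume, got rank ", length(dim(arr)))
  xf <- RNifti::xform(img)
  R3 <- xf[1:3, 1:3]
  sp <- sqrt(colSums(R3^2))
  if (all(sp > 0)) {
    D <- sweep(R3, 2, sp, "/")
    if (max(abs(abs(D) - diag(3))) > 1e-3)
      stop("ambiguous or oblique NIfTI orientation; only axis-aligned ",
           "axial volumes are supported")
    orig <- xf[1:3, 4]
  } else {
    sp <- abs(RNifti::pixdim(img))[1:3]
    orig <- c(0, 0, 0)
  }
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in NIfTI header")
  ctVolume(aperm(arr, c(3, 2, 1)), spacing = rev(sp), origin = rev(orig),
           patientId = patientId)
}

#' @rdname readVolume
#' @export
writeVolume <- function(vol, path) {
  arr <- aperm(voxels(vol), c(3, 2, 1))
  sp <- rev(spacing(vol))
  orig <- rev(origin(vol))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  m <- diag(4)
  m[1, 1] <- sp[1]; m[2, 2] <- sp[2]; m[3, 3] <- sp[3]
  m[1:3, 4] <- orig
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write binary masks as NIfTI
#'
#' Masks round-trip exactly: `readMask()` thresholds the stored values at
#' 0.5, so `writeMask()` followed by `readMask()` recovers the identical
#' mask with its grid metadata.
#'
#' @param mask a [BinaryMask-class].
#' @inheritParams readVolume
#' @return `readMask()`: a [BinaryMask-class]. `writeMask()`: `path`,
#'   invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  arr <- aperm(voxels(mask), c(3, 2, 1))
  sp <- rev(spacing(mask))
  orig <- rev(origin(mask))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  m <- diag(4)
  m[1, 1] <- sp[1]; m[2, 2] <- sp[2]; m[3, 3] <- sp[3]
  m[1:3, 4] <- orig
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path, patientId = "") {
  vol <- readVolume(path, patientId = patientId)
  binaryMask(1 * (voxels(vol) > 0.5), spacing = spacing(vol),
             origin = origin(vol), patientId = patientId)
}

#' Resample a volume onto a reference grid through a rigid transform
#'
#' For every grid point of `reference`, the transform (rotation about the
#' reference's physical centre, then translation) maps the point into
#' `moving`'s physical space, where the value is interpolated. Points
#' falling outside `moving` are filled with -1024 HU (air) for volumes and
#' 0 for masks.
#'
#' @param moving the volume or mask to resample.
#' @param reference a [CTVolume-class] providing the output grid.
#' @param transform a [RigidTransform-class]; identity by default.
#' @param interpolation `"trilinear"` (default for volumes) or `"nearest"`
#'   (default and required behaviour for masks).
#' @param fill out-of-field value; defaults to -1024 for volumes, 0 for
#'   masks.
#' @return A [CTVolume-class] (or [BinaryMask-class] when `moving` is a
#'   mask) on `reference`'s grid.
#' @examples
#' vol <- ctVolume(array(rnorm(8 * 16 * 16), c(8, 16, 16)))
#' out <- resampleToGrid(vol, vol, rigidTransform())
#' all.equal(voxels(out), voxels(vol))
#' @export
resampleToGrid <- function(moving, reference, transform = rigidTransform(),
                           interpolation = NULL, fill = NULL) {
  isMask <- is(moving, "BinaryMask")
  if (is.null(interpolation))
    interpolation <- if (isMask) "nearest" else "trilinear"
  if (!interpolation %in% c("trilinear", "nearest"))
    stop("unknown interpolation mode: ", interpolation)
  if (is.null(fill)) fill <- if (isMask) 0 else -1024
  aff <- .affineFor(transform, .physCenter(reference))
  out <- cpp_resample(as.numeric(voxels(moving)), dim(moving),
                      dim(reference), spacing(reference), origin(reference),
                      spacing(moving), origin(moving),
                      aff$M, aff$b,
                      if (interpolation == "trilinear") 1L else 0L, fill)
  dim(out) <- dim(reference)
  if (isMask && interpolation == "nearest")
    .maskLike(reference, out)
  else
    ctVolume(out, spacing = spacing(reference), origin = origin(reference),
             patientId = patientId(moving))
}
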