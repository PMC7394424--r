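#' Accessors for CT volumes and masks
#'
#' `voxels()` returns the raw 3-D array (slice, row, col order), `spacing()`
#' and `origin()` the voxel geometry in mm (z, y, x order), and `patientId()`
#' the examination identifier.
#'
#' @param x a [CTVolume-class] or [BinaryMask-class] object.
#' @return `voxels()`: a 3-D array; `spacing()`, `origin()`: numeric
#'   length-3 vectors; `patientId()`: a character scalar.
#' @examples
#' vol <- ctVolume(array(0, c(2, 4, 4)), spacing = c(5, 1, 1))
#' spacing(vol)
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname voxels
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname voxels
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname voxels
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' CT volume in Hounsfield units
#'
#' The common currency of the pipeline: a 3-D scalar field of radiodensity
#' values with voxel geometry. The array is stored in (slice, row, col)
#' order, i.e. axial slices first; `spacing` and `origin` are (z, y, x)
#' in mm. The physical position of voxel (i, j, k) (0-based) is
#' `origin + c(i, j, k) * spacing`.
#'
#' @slot voxels 3-D numeric array of HU values.
#' @slot spacing numeric(3), voxel spacing in mm (z, y, x); all > 0.
#' @slot origin numeric(3), position of voxel (0, 0, 0) in mm.
#' @slot patientId character scalar identifying the examination.
#' @seealso [ctVolume()], [readVolume()], [BinaryMask-class]
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric",
                 origin = "numeric", patientId = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), patientId = ""))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a rank-3 array")
  else if (any(dim(object@voxels) < 1L))
    msg <- c(msg, "all voxel dimensions must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (anyNA(object@voxels) || any(!is.finite(object@voxels)))
    msg <- c(msg, "all voxel values must be finite")
  if (length(object@patientId) != 1L)
    msg <- c(msg, "patientId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Binary mask on a CT volume grid
#'
#' A \{0, 1\}-valued field sharing a [CTVolume-class] geometry: bone masks,
#' vessel labels and model predictions.
#'
#' @seealso [binaryMask()], [thresholdMask()], [generateVesselLabel()]
#' @export
setClass("BinaryMask", contains = "CTVolume")

setValidity("BinaryMask", function(object) {
  if (!all(object@voxels %in% c(0, 1)))
    "mask values must all be 0 or 1" else TRUE
})

#' Construct a CT volume
#'
#' @param voxels 3-D array of HU values, (slice, row, col) order.
#' @param spacing numeric(3) voxel spacing in mm, (z, y, x).
#' @param origin numeric(3) physical position of the first voxel in mm.
#' @param patientId examination identifier.
#' @return A [CTVolume-class] object.
#' @examples
#' vol <- ctVolume(array(rnorm(2 * 4 * 4, 30, 8), c(2, 4, 4)),
#'                 spacing = c(5, 1, 1))
#' dim(voxels(vol))
#' @export
ctVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     patientId = "") {
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), patientId = as.character(patientId))
}

#' Construct a binary mask
#'
#' @param voxels 3-D array over \{0, 1\}.
#' @inheritParams ctVolume
#' @return A [BinaryMask-class] object.
#' @export
binaryMask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       patientId = "") {
  storage.mode(voxels) <- "double"
  new("BinaryMask", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), patientId = as.character(patientId))
}

# Mask inheriting its geometry from a reference volume.
.maskLike <- function(ref, voxels) {
  binaryMask(voxels, spacing = spacing(ref), origin = origin(ref),
             patientId = patientId(ref))
}

#' @rdname voxels
#' @export
setMethod("voxels", "CTVolume", function(x) x@voxels)

#' @rdname voxels
#' @export
setMethod("spacing", "CTVolume", function(x) x@spacing)

#' @rdname voxels
#' @export
setMethod("origin", "CTVolume", function(x) x@origin)

#' @rdname voxels
#' @export
setMethod("patientId", "CTVolume", function(x) x@patientId)

#' @export
#' @rdname voxels
setMethod("dim", "CTVolume", function(x) dim(x@voxels))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("%s %dx%dx%d (slice x row x col), spacing %s mm\n",
              class(object), d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  HU range [%.1f, %.1f]",
              min(object@voxels), max(object@voxels)))
  if (nzchar(object@patientId))
    cat(sprintf(", patient %s", object@patientId))
  cat("\n")
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("BinaryMask %dx%dx%d, %d foreground voxels (%.2f%%)\n",
              d[1], d[2], d[3], sum(object@voxels),
              100 * mean(object@voxels)))
})

# Grids match: same shape and (near-)identical spacing/origin.
.sameGrid <- function(a, b, tol = 1e-6) {
  identical(dim(a@voxels), dim(b@voxels)) &&
    all(abs(a@spacing - b@spacing) < tol) &&
    all(abs(a@origin - b@origin) < tol)
}

#' 6-DOF rigid spatial transform
#'
#' Rotations (degrees, applied about the reference volume's physical centre)
#' and translations (mm), both in (z, y, x) axis order. The transform maps a
#' reference-grid physical point p to the moving volume's physical space as
#' `R (p - c) + c + t`.
#'
#' @slot rotations numeric(3), degrees about the z, y and x axes.
#' @slot translations numeric(3), mm along z, y and x.
#' @seealso [rigidTransform()], [registerRigid()], [resampleToGrid()]
#' @export
setClass("RigidTransform",
  representation(rotations = "numeric", translations = "numeric"),
  prototype(rotations = c(0, 0, 0), translations = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  if (length(object@rotations) != 3L || length(object@translations) != 3L ||
      any(!is.finite(c(object@rotations, object@translations))))
    "rotations and translations must each be 3 finite values" else TRUE
})

#' Construct a rigid transform
#'
#' @param rotations numeric(3), rotation angles in degrees about (z, y, x).
#' @param translations numeric(3), translation in mm along (z, y, x).
#' @return A [RigidTransform-class] object.
#' @examples
#' shift <- rigidTransform(translations = c(3, -2, 1.5))
#' invertTransform(shift)
#' @export
rigidTransform <- function(rotations = c(0, 0, 0),
                           translations = c(0, 0, 0)) {
  new("RigidTransform", rotations = as.numeric(rotations),
      translations = as.numeric(translations))
}

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf(
    "RigidTransform: rot (z,y,x) = (%.3f, %.3f, %.3f) deg, t = (%.3f, %.3f, %.3f) mm\n",
    object@rotations[1], object@rotations[2], object@rotations[3],
    object@translations[1], object@translations[2], object@translations[3]))
})

#' Monotone HU-to-[0,1] percentile mapping
#'
#' Bin edges (knots) at equal percentile steps of the fitting data; applying
#' the mapping makes the mapped intensity distribution approximately uniform.
#'
#' @slot knots numeric, `n_bins + 1` nondecreasing HU values.
#' @seealso [fitPercentileMapping()], [applyPercentileMapping()]
#' @export
setClass("PercentileMapping", representation(knots = "numeric"))

setValidity("PercentileMapping", function(object) {
  if (length(object@knots) < 3L || is.unsorted(object@knots) ||
      any(!is.finite(object@knots)))
    "knots must be >= 3 nondecreasing finite values" else TRUE
})

setMethod("show", "PercentileMapping", function(object) {
  cat(sprintf("PercentileMapping: %d bins over [%.1f, %.1f] HU\n",
              length(object@knots) - 1L, object@knots[1],
              object@knots[length(object@knots)]))
})

#' Paired NCCT/CTA phantom with ground truth
#'
#' One synthetic patient: a non-contrast scan, its contrast-enhanced
#' counterpart, the true vessel mask on the CTA grid, and the rigid
#' transform that realigns the NCCT to the CTA (identity when no
#' misalignment was simulated).
#'
#' @slot ncct,cta [CTVolume-class] members of the pair.
#' @slot truth [BinaryMask-class] of true vessel voxels on the CTA grid.
#' @slot trueTransform [RigidTransform-class] aligning NCCT to CTA.
#' @slot patientSex `"F"` or `"M"` (fixture for subgroup comparisons).
#' @seealso [generatePhantomPair()], [makeCohort()]
#' @export
setClass("PhantomPair",
  representation(ncct = "CTVolume", cta = "CTVolume", truth = "BinaryMask",
                 trueTransform = "RigidTransform", patientSex = "character"))

setValidity("PhantomPair", function(object) {
  msg <- character()
  if (!.sameGrid(object@cta, object@truth))
    msg <- c(msg, "truth grid must match the CTA grid")
  if (sum(object@truth@voxels) == 0)
    msg <- c(msg, "truth mask must be non-empty")
  if (!object@patientSex %in% c("F", "M"))
    msg <- c(msg, "patientSex must be \"F\" or \"M\"")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhantomPair", function(object) {
  cat(sprintf("PhantomPair patient %s (%s): ", patientId(object@ncct),
              object@patientSex))
  d <- dim(object@ncct@voxels)
  cat(sprintf("%dx%dx%d, %d vessel voxels\n", d[1], d[2], d[3],
              sum(object@truth@voxels)))
})

#' Segmentation network
#'
#' A built (and possibly trained) encoder-decoder segmentation model:
#' the layer graph, its parameters, batch-normalization running statistics
#' and the configurations it was built/trained with.
#'
#' @slot config model configuration list (see [modelConfig()]).
#' @slot layers internal layer-graph description executed by compiled code.
#' @slot params named list of parameter arrays.
#' @slot state named list of batch-normalization running statistics.
#' @slot channels channel configuration used at training time (or empty).
#' @slot steps number of optimization steps taken.
#' @seealso [buildModel()], [trainModel()], [predictVolume()]
#' @export
setClass("SegModel",
  representation(config = "list", layers = "list", params = "list",
                 state = "list", channels = "list", steps = "numeric"),
  prototype(steps = 0))

setMethod("show", "SegModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("SegModel (%s): %d input channel(s), base width %d, %s params, %d steps\n",
              object@config$variant, object@config$in_channels,
              object@config$base_width, format(np, big.mark = ","),
              object@steps))
})
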