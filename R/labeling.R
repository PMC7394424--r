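# Weak vessel-label generation from an aligned NCCT/CTA pair: contrast and
# bone both exceed 120 HU, but only the CTA contains contrast, so
# thresholding both scans and subtracting the NCCT (bone) mask from the CTA
# mask leaves the vessels; small isolated residues are then removed.

#' Labeling configuration
#'
#' @param threshold_hu radiodensity threshold; voxels strictly above it are
#'   isolated (default 120 HU, the density contrast-enhanced vessels and
#'   bone both exceed while soft tissue does not).
#' @param min_component_voxels connected components smaller than this are
#'   removed as noise; a component of exactly this size is kept.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners; default, so
#'   vessels crossing slices diagonally remain one component).
#' @param bone_dilation_voxels dilate the NCCT bone mask by this many
#'   voxels before subtraction (guards interpolated bone edges after
#'   registration); 0 gives the plain set difference.
#' @param exclusion_mask optional [BinaryMask-class] zeroed out of the
#'   final label (stands in for manual removal of structures such as dural
#'   venous sinuses).
#' @return A validated list of class `"LabelingConfig"`.
#' @export
labelingConfig <- function(threshold_hu = 120, min_component_voxels = 30,
                           connectivity = 26, bone_dilation_voxels = 0,
                           exclusion_mask = NULL) {
  stopifnot(is.finite(threshold_hu), min_component_voxels >= 1,
            connectivity %in% c(6, 26), bone_dilation_voxels >= 0)
  if (!is.null(exclusion_mask) && !is(exclusion_mask, "BinaryMask"))
    stop("exclusion_mask must be a BinaryMask or NULL")
  structure(list(threshold_hu = threshold_hu,
                 min_component_voxels = as.integer(min_component_voxels),
                 connectivity = as.integer(connectivity),
                 bone_dilation_voxels = as.integer(bone_dilation_voxels),
                 exclusion_mask = exclusion_mask),
            class = "LabelingConfig")
}

#' Threshold a volume at a radiodensity
#'
#' A voxel is foreground iff its HU value is strictly greater than the
#' threshold.
#'
#' @param vol a [CTVolume-class].
#' @param threshold_hu threshold in HU.
#' @return A [BinaryMask-class] on `vol`'s grid.
#' @examples
#' vol <- ctVolume(array(c(119, 120, 121, 500), c(1, 2, 2)))
#' voxels(thresholdMask(vol, 120))
#' @export
thresholdMask <- function(vol, threshold_hu = 120) {
  stopifnot(is.finite(threshold_hu))
  .maskLike(vol, 1 * (voxels(vol) > threshold_hu))
}

#' Subtract a bone mask from a contrast mask
#'
#' `result = cta_mask AND NOT dilate(ncct_mask, dilation_voxels)`; with
#' dilation 0 this is the plain set difference.
#'
#' @param cta_mask,ncct_mask [BinaryMask-class] objects on the same grid.
#' @param dilation_voxels non-negative integer dilation (26-neighbourhood)
#'   applied to `ncct_mask` before subtraction.
#' @return A [BinaryMask-class].
#' @export
subtractMasks <- function(cta_mask, ncct_mask, dilation_voxels = 0) {
  if (!.sameGrid(cta_mask, ncct_mask))
    stop("mask grids do not match")
  bone <- voxels(ncct_mask)
  if (dilation_voxels > 0) {
    b <- cpp_dilate(as.integer(bone), dim(ncct_mask),
                    as.integer(dilation_voxels), 26L)
    dim(b) <- dim(ncct_mask)
    bone <- b
  }
  .maskLike(cta_mask, voxels(cta_mask) * (1 - pmin(bone, 1)))
}

#' Remove small isolated components from a mask
#'
#' Connected components with fewer than `min_voxels` voxels are removed;
#' all others are untouched (a component of exactly `min_voxels` is kept).
#'
#' @param mask a [BinaryMask-class].
#' @param min_voxels minimum component size to keep.
#' @param connectivity 6 or 26.
#' @return A [BinaryMask-class].
#' @export
removeSmallComponents <- function(mask, min_voxels = 30,
                                  connectivity = 26) {
  stopifnot(min_voxels >= 1, connectivity %in% c(6, 26))
  out <- cpp_remove_small(as.integer(voxels(mask)), dim(mask),
                          as.integer(min_voxels), as.integer(connectivity))
  dim(out) <- dim(mask)
  .maskLike(mask, out)
}

#' Generate the binary vessel label from an NCCT/CTA pair
#'
#' The full weak-labeling pipeline on the CTA grid: resample the NCCT
#' through the aligning transform, threshold both scans, subtract the bone
#' mask, remove small isolated components and zero out any exclusion mask.
#' An empty result flags the examination as unusable.
#'
#' @param ncct,cta [CTVolume-class] members of the pair.
#' @param transform [RigidTransform-class] aligning `ncct` to `cta`'s grid
#'   (identity for pre-aligned pairs); typically from [registerRigid()].
#' @param config a [labelingConfig()].
#' @return A [BinaryMask-class] vessel label on the CTA grid.
#' @examples
#' pair <- generatePhantomPair(phantomSpec(seed = 3))
#' label <- generateVesselLabel(pair@ncct, pair@cta)
#' diceCoefficient(label, pair@truth)$dice
#' @export
generateVesselLabel <- function(ncct, cta, transform = rigidTransform(),
                                config = labelingConfig()) {
  ncctAligned <- resampleToGrid(ncct, cta, transform,
                                interpolation = "trilinear")
  ctaMask <- thresholdMask(cta, config$threshold_hu)
  boneMask <- thresholdMask(ncctAligned, config$threshold_hu)
  label <- subtractMasks(ctaMask, boneMask, config$bone_dilation_voxels)
  label <- removeSmallComponents(label, config$min_component_voxels,
                                 config$connectivity)
  if (!is.null(config$exclusion_mask)) {
    if (!.sameGrid(label, config$exclusion_mask))
      stop("exclusion mask grid does not match the CTA grid")
    label <- .maskLike(cta, voxels(label) *
                              (1 - voxels(config$exclusion_mask)))
  }
  if (sum(voxels(label)) == 0)
    stop("empty vessel label: examination flagged as unusable")
  label
}
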