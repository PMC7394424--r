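# 6-DOF rigid registration by coarse-to-fine derivative-free optimization
# of an intensity similarity metric (normalized mutual information or
# normalized cross-correlation). Replaces the external registration tool a
# clinical workflow would use; conventions (rotation about the fixed
# volume's physical centre, (z, y, x) parameter order) are the package's
# own.

#' Registration configuration
#'
#' @param metric `"ncc"` (global normalized cross-correlation; default,
#'   since both members of an NCCT/CTA pair are CT scans and its smooth
#'   optimum supports subvoxel translation recovery), `"lncc"` (locally
#'   normalized cross-correlation in ~7 mm windows) or `"nmi"`
#'   (normalized mutual information, for images whose intensities
#'   correspond only statistically).
#' @param levels multiresolution pyramid levels (>= 1), downsampling by 2
#'   per level.
#' @param iterations simplex iterations per level.
#' @param bins histogram bins per axis for NMI (>= 8).
#' @param tol relative convergence tolerance of the simplex optimizer.
#' @param restarts simplex restarts per level; re-inflating the simplex at
#'   the previous optimum escapes premature collapse along flat
#'   directions.
#' @param smooth_mm isotropic Gaussian pre-smoothing (mm) applied to both
#'   images at every pyramid level. Smoothing makes the images
#'   band-limited, so trilinear interpolation of the moving image is
#'   accurate and the metric optimum is not biased by sharp edges; it is
#'   rotation-equivariant, unlike the interpolation error it removes.
#' @return A validated list of class `"RegistrationConfig"`.
#' @export
registrationConfig <- function(metric = c("ncc", "lncc", "nmi"), levels = 3,
                               iterations = 1200, bins = 32, tol = 1e-8,
                               restarts = 2, smooth_mm = 2) {
  metric <- match.arg(metric)
  stopifnot(levels >= 1, bins >= 8, iterations >= 10, tol > 0,
            restarts >= 0, all(smooth_mm >= 0),
            length(smooth_mm) %in% c(1, 3))
  structure(list(metric = metric, levels = as.integer(levels),
                 iterations = as.integer(iterations), bins = as.integer(bins),
                 tol = tol, restarts = as.integer(restarts),
                 smooth_mm = smooth_mm),
            class = "RegistrationConfig")
}

# Gaussian smoothing of a volume; sigmaMM scalar (isotropic) or per-axis.
.smoothVolume <- function(vol, sigmaMM) {
  if (all(sigmaMM <= 0)) return(vol)
  sv <- rep(sigmaMM, length.out = 3) / spacing(vol)
  out <- cpp_gauss_smooth(as.numeric(voxels(vol)), dim(vol), sv)
  dim(out) <- dim(vol)
  ctVolume(out, spacing = spacing(vol), origin = origin(vol),
           patientId = patientId(vol))
}

#' Image similarity metrics
#'
#' Normalized mutual information `(H(a) + H(b)) / H(a, b)` lies in (0, 2]
#' and is maximal for identical images; normalized cross-correlation lies
#' in [-1, 1].
#'
#' @param a,b [CTVolume-class] objects on the same grid.
#' @param metric `"nmi"` or `"ncc"`.
#' @param bins histogram bins per axis (NMI only).
#' @return A scalar similarity.
#' @examples
#' v <- ctVolume(array(rnorm(4 * 8 * 8), c(4, 8, 8)))
#' similarity(v, v, "ncc")
#' @export
similarity <- function(a, b, metric = c("nmi", "ncc"), bins = 32) {
  metric <- match.arg(metric)
  if (!identical(dim(a), dim(b)))
    stop("volumes must share a grid")
  x <- as.numeric(voxels(a))
  y <- as.numeric(voxels(b))
  if (metric == "ncc") {
    if (sd(x) == 0 || sd(y) == 0)
      stop("NCC undefined for a constant image (zero variance)")
    return(stats::cor(x, y))
  }
  .nmi(x, y, bins)
}

.binIndex <- function(x, bins) {
  r <- range(x)
  if (r[2] <= r[1]) return(rep(1L, length(x)))
  i <- floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin(i, bins)
}

.nmi <- function(x, y, bins) {
  ix <- .binIndex(x, bins)
  iy <- .binIndex(y, bins)
  joint <- tabulate(ix + bins * (iy - 1L), bins * bins)
  p <- joint / length(x)
  px <- tabulate(ix, bins) / length(x)
  py <- tabulate(iy, bins) / length(x)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hxy <- ent(p)
  if (hxy == 0) return(2)        # both images constant: trivially identical
  (ent(px) + ent(py)) / hxy
}

# Downsample by per-axis factors in {1, 2}; geometry follows block centres.
.downsampleVolume <- function(vol, fac) {
  v <- cpp_downsample2(as.numeric(voxels(vol)), dim(vol), as.integer(fac))
  od <- attr(v, "odim")
  out <- as.numeric(v)
  dim(out) <- od
  ctVolume(out, spacing = spacing(vol) * fac,
           origin = origin(vol) + (fac - 1) / 2 * spacing(vol),
           patientId = patientId(vol))
}

.pyramidFactors <- function(d, level) {
  # total per-axis factor 2^level, capped so no axis drops below 8 voxels
  vapply(seq_along(d), function(a) {
    f <- 1L
    while (f < 2^level && d[a] / (f * 2L) >= 8) f <- f * 2L
    f
  }, 1L)
}

# Objective for one pyramid level; NCC uses a fused resample+correlate
# kernel, NMI materializes the resampled volume.
.levelObjective <- function(mv, fx, config) {
  fixVals <- as.numeric(voxels(fx))
  ctr <- .physCenter(fx)
  rad <- pmax(1L, as.integer(round(3 / spacing(fx))))  # ~7 mm windows
  function(p) {
    tr <- rigidTransform(rotations = p[4:6], translations = p[1:3])
    if (config$metric == "ncc") {
      aff <- .affineFor(tr, ctr)
      -cpp_ncc_transformed(as.numeric(voxels(mv)), dim(mv), fixVals,
                           dim(fx), spacing(fx), origin(fx),
                           spacing(mv), origin(mv), aff$M, aff$b,
                           -1024)
    } else if (config$metric == "lncc") {
      res <- resampleToGrid(mv, fx, tr, interpolation = "trilinear")
      -cpp_lncc(as.numeric(voxels(res)), fixVals, dim(fx), rad)
    } else {
      res <- resampleToGrid(mv, fx, tr, interpolation = "trilinear")
      -.nmi(as.numeric(voxels(res)), fixVals, config$bins)
    }
  }
}

#' Rigidly register a moving volume to a fixed volume
#'
#' Maximizes the configured similarity metric over the six rigid parameters
#' with a Nelder-Mead simplex, coarse to fine over a multiresolution
#' pyramid. The returned transform maps fixed-grid points into the moving
#' volume's physical space, i.e. it is directly usable by
#' [resampleToGrid()] and [generateVesselLabel()]. In the intended
#' workflow the NCCT is the moving image and the CTA is fixed, so labels
#' live on the CTA grid. Deterministic given the configuration.
#'
#' @param moving,fixed [CTVolume-class] volumes with substantial overlap.
#' @param config a [registrationConfig()].
#' @param init optional starting [RigidTransform-class].
#' @return A [RigidTransform-class]. If the simplex fails to converge at
#'   the finest level an error of class `"registrationConvergenceError"`
#'   is raised carrying the best transform so far in its
#'   `$transform` field.
#' @examples
#' pair <- generatePhantomPair(phantomSpec(
#'   seed = 2, misalignment = rigidTransform(translations = c(0, 3, -2))))
#' registerRigid(pair@ncct, pair@cta)
#' @export
registerRigid <- function(moving, fixed, config = registrationConfig(),
                          init = rigidTransform()) {
  par <- c(init@translations, init@rotations)
  for (level in seq(config$levels - 1L, 0L)) {
    fac <- .pyramidFactors(dim(fixed), level)
    fx <- if (all(fac == 1L)) fixed else .downsampleVolume(fixed, fac)
    mv <- if (all(fac == 1L)) moving else .downsampleVolume(moving, fac)
    # block-averaged coarse levels are already smooth; the full smoothing
    # budget applies at the finest level, where it equalizes the
    # pose-dependent interpolation blur that otherwise biases the metric
    fx <- .smoothVolume(fx, config$smooth_mm / 2^level)
    mv <- .smoothVolume(mv, config$smooth_mm / 2^level)
    obj <- .levelObjective(mv, fx, config)
    # restarted simplex: re-inflating the simplex at the previous optimum
    # guards against premature collapse along flat directions
    fit <- optim(par, obj, method = "Nelder-Mead",
                 control = list(maxit = config$iterations,
                                reltol = config$tol))
    improving <- TRUE
    for (restart in seq_len(config$restarts)) {
      fit2 <- optim(fit$par, obj, method = "Nelder-Mead",
                    control = list(maxit = config$iterations,
                                   reltol = config$tol))
      improving <- fit2$value < fit$value - 1e-6 * abs(fit$value)
      if (fit2$value <= fit$value) fit <- fit2
    }
    par <- fit$par
    # trilinear interpolation gives the metric a kinked micro-landscape on
    # which the simplex rarely meets a pure function-value tolerance, so
    # non-convergence is declared only when the iteration budget ran out
    # (code 1) while the optimizer was still making material progress;
    # simplex degeneracy (code 10) is a collapsed optimum
    if (level == 0L && fit$convergence == 1L && improving) {
      cond <- structure(
        class = c("registrationConvergenceError", "error", "condition"),
        list(message = sprintf(
               "registration did not converge at the finest level (code %d)",
               fit$convergence),
             call = sys.call(-1),
             transform = rigidTransform(rotations = par[4:6],
                                        translations = par[1:3])))
      stop(cond)
    }
  }
  rigidTransform(rotations = par[4:6], translations = par[1:3])
}
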