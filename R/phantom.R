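# Synthetic paired NCCT/CTA head phantoms with known vessel ground truth.
# The phantom emulates the radiodensity classes the labeling pipeline relies
# on: an ellipsoidal high-HU skull shell, brain parenchyma around 30 HU with
# additive Gaussian noise, and a branching tubular vessel tree whose voxels
# are contrast-enhanced (120-500 HU) only in the CTA member of the pair.
# On the NCCT the same voxels carry unenhanced blood density (45 HU),
# slightly hyperdense to parenchyma, which is the physical signal a
# segmentation network can learn from.

#' Phantom specification
#'
#' Parameters of the paired-phantom generator. Defaults give a desk-scale
#' 32 x 64 x 64 head at (2, 1, 1) mm: thin-slice geometry as used for
#' angiographic reconstructions (thick slabs would break the axial
#' continuity of millimetre-calibre tubes), large enough for vessels
#' several voxels wide, small enough for fast end-to-end runs.
#'
#' @param shape integer(3) voxel counts (slices, rows, cols); all >= 8.
#' @param spacing numeric(3) voxel spacing in mm (z, y, x).
#' @param skull list: `outer_frac`/`inner_frac` of the volume half-extent
#'   bounding the skull shell, per-axis `aspect` multipliers (z, y, x;
#'   the default makes the head longer front-to-back than wide, as real
#'   heads are, so in-plane rotation is identifiable from bone), and
#'   `hu_range` of bone radiodensity.
#' @param brain list: `mean_hu` parenchyma density and `noise_sd` of the
#'   additive Gaussian HU noise applied to both scans.
#' @param vessel list: `n_roots` root vessels, branching `depth`,
#'   `radius_range` (mm), CTA `contrast_range` (HU, lower bound >= 120) and
#'   unenhanced `ncct_hu` blood density.
#' @param aneurysm list: `enabled` flag and saccular `diameter` in mm.
#' @param misalignment optional [RigidTransform-class] applied to the NCCT
#'   member, or `NULL` for a perfectly aligned pair.
#' @param seed integer controlling all randomness of the pair.
#' @return A validated list of class `"PhantomSpec"`.
#' @examples
#' spec <- phantomSpec(seed = 7)
#' pair <- generatePhantomPair(spec)
#' pair
#' @export
phantomSpec <- function(shape = c(32, 64, 64), spacing = c(2, 1, 1),
                        skull = list(outer_frac = 0.92, inner_frac = 0.80,
                                     aspect = c(1, 1.05, 0.82),
                                     hu_range = c(200, 3000)),
                        brain = list(mean_hu = 30, noise_sd = 8),
                        vessel = list(n_roots = 4, depth = 2,
                                      radius_range = c(1.2, 2.5),
                                      contrast_range = c(120, 500),
                                      ncct_hu = 45),
                        aneurysm = list(enabled = FALSE, diameter = 8),
                        misalignment = NULL, seed = 1) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               skull = skull, brain = brain, vessel = vessel,
               aneurysm = aneurysm, misalignment = misalignment,
               seed = as.integer(seed))
  if (length(spec$shape) != 3L || any(spec$shape < 8L))
    stop("shape must be 3 dimensions, all >= 8")
  if (any(spec$spacing <= 0)) stop("spacing must be positive")
  if (any(spec$vessel$radius_range <= 0)) stop("vessel radii must be > 0")
  if (diff(spec$vessel$radius_range) < 0 ||
      diff(spec$vessel$contrast_range) < 0 ||
      diff(spec$skull$hu_range) < 0)
    stop("ranges must be ordered (low, high)")
  if (spec$vessel$contrast_range[1] < 120)
    stop("vessel contrast lower bound must be >= 120 HU")
  if (spec$skull$inner_frac >= spec$skull$outer_frac)
    stop("skull inner_frac must be < outer_frac")
  if (is.null(spec$skull$aspect)) spec$skull$aspect <- c(1, 1.05, 0.82)
  if (any(spec$skull$aspect * spec$skull$outer_frac > 1))
    stop("skull aspect times outer_frac must stay within the volume")
  if (!is.null(spec$misalignment) &&
      !is(spec$misalignment, "RigidTransform"))
    stop("misalignment must be a RigidTransform or NULL")
  class(spec) <- "PhantomSpec"
  spec
}

# Normalized ellipsoid radius of every voxel centre: 0 at the volume centre,
# 1 on the brain (inner-skull) surface.
.ellipsoidNorm <- function(shape, spacing, frac, aspect = c(1, 1, 1)) {
  h <- (shape - 1) * spacing / 2
  ax <- frac * aspect * h
  rz <- (((seq_len(shape[1]) - 1) * spacing[1] - h[1]) / ax[1])^2
  ry <- (((seq_len(shape[2]) - 1) * spacing[2] - h[2]) / ax[2])^2
  rx <- (((seq_len(shape[3]) - 1) * spacing[3] - h[3]) / ax[3])^2
  sqrt(outer(outer(rz, ry, "+"), rx, "+"))
}

.unit <- function(v) v / sqrt(sum(v^2))

# Smooth multiplicative bone-density modulation (period ~2-4 cm),
# evaluated at arbitrary physical coordinates so a rigidly posed head
# carries its texture with it.
.boneTextureXYZ <- function(qz, qy, qx) {
  g <- (sin(2 * pi * qz / 37 + 0.7) + sin(2 * pi * qy / 23 + 1.9) +
          sin(2 * pi * qx / 29 + 0.3)) / 3
  h <- (sin(2 * pi * qz / 19) * sin(2 * pi * qy / 31 + 1.1) +
          sin(2 * pi * qx / 17 + 2.2)) / 2
  1 + 0.35 * g + 0.2 * h
}

# Evaluate the clean anatomy (air / brain / textured skull) and the vessel
# mask on the voxel grid, with the whole head optionally posed through a
# rigid transform: the value at grid point p is the anatomy at q = M p + b.
# A misaligned scan is thus *acquired* at the transformed pose rather than
# interpolated from the aligned one, exactly as on a scanner. The HU field
# is evaluated on a 0.5 mm subgrid and convolved with a Gaussian scanner
# PSF (sigma 1.2 mm along z -- the slice profile -- and 0.6 mm in plane --
# the reconstruction kernel) before decimation to the scan lattice, so the
# scan is band-limited the way real CT reconstructions are; pointwise
# sampling of step edges would alias along 2 mm slices.
.phantomScene <- function(spec, segs, blobRow, transform = NULL) {
  d <- spec$shape
  sp <- spec$spacing
  h <- (d - 1) * sp / 2
  sub <- pmax(1L, as.integer(round(sp / 0.5)))   # subgrid factors per axis
  fd <- (d - 1L) * sub + 1L
  fsp <- sp / sub
  pz <- array(rep((seq_len(fd[1]) - 1) * fsp[1], times = fd[2] * fd[3]), fd)
  py <- array(rep(rep((seq_len(fd[2]) - 1) * fsp[2], each = fd[1]),
                  times = fd[3]), fd)
  px <- array(rep((seq_len(fd[3]) - 1) * fsp[3], each = fd[1] * fd[2]), fd)
  if (!is.null(transform)) {
    aff <- .affineFor(transform, h)
    M <- aff$M; b <- aff$b
    qz <- M[1, 1] * pz + M[1, 2] * py + M[1, 3] * px + b[1]
    qy <- M[2, 1] * pz + M[2, 2] * py + M[2, 3] * px + b[2]
    qx <- M[3, 1] * pz + M[3, 2] * py + M[3, 3] * px + b[3]
    affi <- .affineFor(invertTransform(transform), h)
    segsT <- segs
    for (cc in list(1:3, 4:6)) {
      pts <- affi$M %*% t(segs[, cc, drop = FALSE]) + affi$b
      segsT[, cc] <- t(pts)
    }
    blobT <- if (!is.null(blobRow))
      c(as.numeric(affi$M %*% blobRow[1:3] + affi$b), blobRow[4])
    else NULL
  } else {
    qz <- pz; qy <- py; qx <- px
    segsT <- segs
    blobT <- blobRow
  }
  rm(pz, py, px)
  asp <- spec$skull$aspect
  en <- function(frac)
    sqrt(((qz - h[1]) / (frac * asp[1] * h[1]))^2 +
         ((qy - h[2]) / (frac * asp[2] * h[2]))^2 +
         ((qx - h[3]) / (frac * asp[3] * h[3]))^2)
  rnIn <- en(spec$skull$inner_frac)
  rnOut <- en(spec$skull$outer_frac)
  brainF <- rnIn < 1
  skullF <- !brainF & rnOut < 1
  hu <- array(-1000, fd)
  hu[brainF] <- spec$brain$mean_hu
  prof <- .skullProfile(rnOut[skullF],
                        spec$skull$inner_frac / spec$skull$outer_frac, 1,
                        spec$skull$hu_range)
  tex <- .boneTextureXYZ(qz[skullF], qy[skullF], qx[skullF])
  hu[skullF] <- pmin(spec$skull$hu_range[2],
                     pmax(spec$skull$hu_range[1], prof * tex))
  rm(rnIn, rnOut, skullF, qz, qy, qx)
  hu <- cpp_gauss_smooth(as.numeric(hu), fd, c(1.2, 0.6, 0.6) / fsp)
  dim(hu) <- fd
  base <- hu[seq(1, fd[1], by = sub[1]),
             seq(1, fd[2], by = sub[2]),
             seq(1, fd[3], by = sub[3]), drop = FALSE]
  rm(hu)

  vm <- cpp_rasterize_tubes(d, sp, c(0, 0, 0), segsT)
  dim(vm) <- d
  if (!is.null(blobT)) {
    bl <- cpp_rasterize_spheres(d, sp, c(0, 0, 0), matrix(blobT, 1, 4))
    dim(bl) <- d
    vm <- pmax(vm, bl)
  }
  enc <- function(frac, az, ay, ax2)
    sqrt(((az - h[1]) / (frac * asp[1] * h[1]))^2 +
         ((ay - h[2]) / (frac * asp[2] * h[2]))^2 +
         ((ax2 - h[3]) / (frac * asp[3] * h[3]))^2)
  cz <- array(rep((seq_len(d[1]) - 1) * sp[1], times = d[2] * d[3]), d)
  cy <- array(rep(rep((seq_len(d[2]) - 1) * sp[2], each = d[1]),
                  times = d[3]), d)
  cx <- array(rep((seq_len(d[3]) - 1) * sp[3], each = d[1] * d[2]), d)
  if (!is.null(transform)) {
    aff <- .affineFor(transform, h)
    tz <- aff$M[1, 1] * cz + aff$M[1, 2] * cy + aff$M[1, 3] * cx + aff$b[1]
    ty <- aff$M[2, 1] * cz + aff$M[2, 2] * cy + aff$M[2, 3] * cx + aff$b[2]
    tx <- aff$M[3, 1] * cz + aff$M[3, 2] * cy + aff$M[3, 3] * cx + aff$b[3]
    brainC <- enc(spec$skull$inner_frac, tz, ty, tx) < 1
  } else {
    brainC <- enc(spec$skull$inner_frac, cz, cy, cx) < 1
  }
  vm <- vm * brainC                    # vessels never reach the skull
  list(base = base, vessel = vm, brain = brainC)
}

#' Synthesize a branching vessel-tree centreline
#'
#' Grows piecewise-linear branching centrelines inside the brain region of
#' the phantom (strictly inside the inner skull surface). Deterministic
#' given the seed.
#'
#' @param spec a [phantomSpec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return A data.frame of centreline segments with columns
#'   `z0, y0, x0, z1, y1, x1` (mm), `radius` (mm) and `branch` id.
#' @export
synthesizeVesselTree <- function(spec, seed = spec$seed) {
  .withSeed(seed, {
    h <- (spec$shape - 1) * spec$spacing / 2
    ctr <- h
    ax <- spec$skull$inner_frac * spec$skull$aspect * h
    lim <- 0.85                 # vessels stay well inside the brain surface
    rr <- spec$vessel$radius_range
    nseg <- 5L
    steplen <- 0.32 * min(ax)
    enorm <- function(p) sqrt(sum(((p - ctr) / ax)^2))
    rows <- list()
    branch <- 0L
    queue <- list()
    for (i in seq_len(spec$vessel$n_roots)) {
      th <- 2 * pi * (i - 1) / spec$vessel$n_roots
      start <- ctr + c(-0.45 * ax[1],
                       0.25 * ax[2] * sin(th), 0.25 * ax[3] * cos(th))
      dir <- .unit(c(1.2, 0.5 * sin(th), 0.5 * cos(th)) + rnorm(3, 0, 0.1))
      radius <- runif(1, rr[1] + 0.6 * diff(rr), rr[2])
      queue[[length(queue) + 1L]] <-
        list(p = start, dir = dir, radius = radius,
             depth = spec$vessel$depth)
    }
    while (length(queue)) {
      b <- queue[[1]]
      queue <- queue[-1]
      branch <- branch + 1L
      p <- b$p
      dir <- b$dir
      for (s in seq_len(nseg)) {
        placed <- FALSE
        for (try in seq_len(60)) {
          nd <- .unit(dir + rnorm(3, 0, 0.3))
          q <- p + nd * steplen
          if (enorm(q) < lim) { placed <- TRUE; break }
          dir <- .unit(dir + 0.8 * .unit(ctr - p))   # bend back inward
        }
        if (!placed)
          stop("vessel tree failed to fit inside the brain region")
        rows[[length(rows) + 1L]] <- c(p, q, b$radius, branch)
        p <- q
        dir <- nd
      }
      if (b$depth > 0L) {
        for (k in 1:2) {
          cd <- .unit(dir + rnorm(3, 0, 0.6))
          queue[[length(queue) + 1L]] <-
            list(p = p, dir = cd,
                 radius = max(rr[1], b$radius * 0.7), depth = b$depth - 1L)
        }
      }
    }
    m <- do.call(rbind, rows)
    colnames(m) <- c("z0", "y0", "x0", "z1", "y1", "x1", "radius", "branch")
    as.data.frame(m)
  })
}

# Deterministic bone radiodensity profile across the shell (peak mid-shell),
# shared by both scans so registration has matched structure.
.skullProfile <- function(rn, inner, outer, huRange) {
  mid <- (inner + outer) / 2
  half <- (outer - inner) / 2
  lo <- max(huRange[1], 250)
  hi <- min(huRange[2], 1800)
  pmax(lo, lo + (hi - lo) * (1 - abs(rn - mid) / half))
}

#' Generate a paired NCCT/CTA phantom
#'
#' Builds the clean anatomy (air, brain, skull shell, vessel tree), gives
#' vessel voxels their contrast-enhanced density in the CTA member only,
#' adds independent Gaussian HU noise to each scan, and optionally
#' misaligns the NCCT through a known rigid transform. The returned
#' `trueTransform` realigns the NCCT to the CTA grid (identity when no
#' misalignment is requested). Fully deterministic given `spec$seed`.
#'
#' @param spec a [phantomSpec()].
#' @param patientId identifier stored on the volumes.
#' @param patientSex `"F"` or `"M"` metadata for subgroup fixtures.
#' @return A [PhantomPair-class].
#' @export
generatePhantomPair <- function(spec, patientId = "phantom",
                                patientSex = "F") {
  stopifnot(inherits(spec, "PhantomSpec"))
  seeds <- .childSeeds(spec$seed, 4L)
  d <- spec$shape
  sp <- spec$spacing

  tree <- synthesizeVesselTree(spec, seed = seeds[1])
  segs <- as.matrix(tree[, c("z0", "y0", "x0", "z1", "y1", "x1", "radius")])
  blobRow <- NULL
  if (isTRUE(spec$aneurysm$enabled)) {
    idx <- .withSeed(seeds[2], sample.int(nrow(tree), 1L))
    blobRow <- c(as.numeric(tree[idx, c("z1", "y1", "x1")]),
                 spec$aneurysm$diameter / 2)
  }

  scene <- .phantomScene(spec, segs, blobRow)
  truthVox <- scene$vessel
  if (sum(truthVox) == 0)
    stop("degenerate phantom: empty vessel ground truth")

  # Contrast enhancement is coherent within a vessel (blood-pool filling):
  # each branch gets a mean drawn from the central part of the contrast
  # range plus small within-branch variation, clipped into the range.
  ctaClean <- scene$base
  cr <- spec$vessel$contrast_range
  ctaClean[truthVox == 1] <- mean(cr)
  .withSeed(seeds[3], {
    for (b in unique(tree$branch)) {
      bs <- as.matrix(tree[tree$branch == b,
                           c("z0", "y0", "x0", "z1", "y1", "x1", "radius")])
      bm <- cpp_rasterize_tubes(d, sp, c(0, 0, 0), bs)
      dim(bm) <- d
      sel <- bm == 1L & truthVox == 1
      mu <- runif(1, cr[1] + 0.2 * diff(cr), cr[2] - 0.2 * diff(cr))
      ctaClean[sel] <- pmin(cr[2],
                            pmax(cr[1] + 5, mu + rnorm(sum(sel), 0, 20)))
    }
    if (!is.null(blobRow)) {
      bl <- cpp_rasterize_spheres(d, sp, c(0, 0, 0), matrix(blobRow, 1, 4))
      dim(bl) <- d
      sel <- bl == 1L & truthVox == 1
      mu <- runif(1, cr[1] + 0.2 * diff(cr), cr[2] - 0.2 * diff(cr))
      ctaClean[sel] <- pmin(cr[2],
                            pmax(cr[1] + 5, mu + rnorm(sum(sel), 0, 20)))
    }
  })

  trueTransform <- rigidTransform()
  if (is.null(spec$misalignment)) {
    ncctClean <- scene$base
    ncctClean[truthVox == 1] <- spec$vessel$ncct_hu
  } else {
    sceneM <- .phantomScene(spec, segs, blobRow,
                            transform = spec$misalignment)
    ncctClean <- sceneM$base
    ncctClean[sceneM$vessel == 1] <- spec$vessel$ncct_hu
    trueTransform <- invertTransform(spec$misalignment)
  }

  noise <- .withSeed(seeds[4], {
    list(n = array(rnorm(prod(d), 0, spec$brain$noise_sd), d),
         c = array(rnorm(prod(d), 0, spec$brain$noise_sd), d))
  })
  ncct <- ctVolume(ncctClean + noise$n, spacing = sp,
                   patientId = patientId)
  cta <- ctVolume(ctaClean + noise$c, spacing = sp, patientId = patientId)
  truth <- binaryMask(truthVox, spacing = sp, patientId = patientId)
  new("PhantomPair", ncct = ncct, cta = cta, truth = truth,
      trueTransform = trueTransform, patientSex = patientSex)
}

#' Generate a phantom cohort
#'
#' `n` patients with per-patient seeds derived deterministically from the
#' master seed, alternating sexes (subgroup-test fixture) and intracranial
#' aneurysms in ~45% of patients.
#'
#' @param n number of patients (>= 1).
#' @param baseSpec the shared [phantomSpec()]; per-patient seed and
#'   aneurysm flag are overridden.
#' @param seed master seed.
#' @return A list of [PhantomPair-class] objects with unique patient ids.
#' @export
makeCohort <- function(n, baseSpec = phantomSpec(), seed = 1) {
  stopifnot(n >= 1)
  seeds <- .childSeeds(seed, n)
  aneur <- .withSeed(seed + 1L, runif(n) < 0.45)
  lapply(seq_len(n), function(i) {
    spec <- baseSpec
    spec$seed <- seeds[i]
    spec$aneurysm$enabled <- aneur[i]
    generatePhantomPair(spec, patientId = sprintf("P%03d", i),
                        patientSex = if (i %% 2L == 1L) "F" else "M")
  })
}
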