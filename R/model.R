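# Model-facing API: configuration, construction, the generalized Dice
# loss, training-time augmentation and whole-volume prediction.

#' Model configuration
#'
#' @param variant `"resnet_unet"` (residual encoder in four strided
#'   stages, optional self-attention at the deepest stage, pixel-shuffle
#'   decoder; default) or `"baseline_unet"` (plain double convolutions
#'   with max pooling).
#' @param in_channels 1 or 3; must match the channel configuration used
#'   for preprocessing.
#' @param base_width channels of the first stage (doubling per stage);
#'   16 is the desk-scale default, 64 the full-scale geometry.
#' @param encoder_blocks_per_stage residual blocks per encoder stage
#'   (2 reproduces an 18-layer residual encoder; 1 is the fast default).
#' @param self_attention add one gated self-attention block at the deepest
#'   encoder stage (resnet variant).
#' @param upsampling `"pixel_shuffle_icnr"` (subpixel convolution with
#'   ICNR initialization, suppressing checkerboard artifacts) or
#'   `"transposed"`.
#' @param seed seed for deterministic weight initialization.
#' @return A list of class `"ModelConfig"`.
#' @export
modelConfig <- function(variant = c("resnet_unet", "baseline_unet"),
                        in_channels = 3, base_width = 16,
                        encoder_blocks_per_stage = 1,
                        self_attention = TRUE,
                        upsampling = c("pixel_shuffle_icnr", "transposed"),
                        seed = 1) {
  variant <- match.arg(variant)
  upsampling <- match.arg(upsampling)
  stopifnot(in_channels %in% c(1, 3), base_width >= 4,
            encoder_blocks_per_stage >= 1)
  structure(list(variant = variant, in_channels = as.integer(in_channels),
                 base_width = as.integer(base_width),
                 encoder_blocks_per_stage =
                   as.integer(encoder_blocks_per_stage),
                 self_attention = isTRUE(self_attention),
                 upsampling = upsampling, seed = as.integer(seed)),
            class = "ModelConfig")
}

#' Augmentation configuration
#'
#' Random training-time transforms: horizontal flip with probability 0.5,
#' rotation up to 10 degrees bidirectional with probability 0.75, and zoom
#' from 1.0 up to 1.2 with probability 0.75.
#'
#' @param flip_prob probability of a horizontal flip.
#' @param rotation_max_deg,rotation_prob rotation range and probability.
#' @param zoom_range,zoom_prob zoom factor range and probability.
#' @return A list of class `"AugmentationConfig"`.
#' @export
augmentationConfig <- function(flip_prob = 0.5, rotation_max_deg = 10,
                               rotation_prob = 0.75,
                               zoom_range = c(1.0, 1.2),
                               zoom_prob = 0.75) {
  stopifnot(flip_prob >= 0, flip_prob <= 1, rotation_prob >= 0,
            rotation_prob <= 1, zoom_prob >= 0, zoom_prob <= 1,
            zoom_range[1] <= zoom_range[2], zoom_range[1] > 0)
  structure(list(flip_prob = flip_prob,
                 rotation_max_deg = rotation_max_deg,
                 rotation_prob = rotation_prob, zoom_range = zoom_range,
                 zoom_prob = zoom_prob),
            class = "AugmentationConfig")
}

#' Build a segmentation model
#'
#' Constructs the layer graph and deterministically initializes its
#' parameters: He-style weights, ICNR replication for pixel-shuffle
#' convolutions, a zero-initialized two-class head and a zero attention
#' gate (so the attention block starts as the identity map).
#'
#' @param config a [modelConfig()].
#' @return A [SegModel-class].
#' @examples
#' model <- buildModel(modelConfig(base_width = 4))
#' model
#' @export
buildModel <- function(config = modelConfig()) {
  stopifnot(inherits(config, "ModelConfig"))
  arch <- .netArchitecture(config)
  params <- .initParams(arch, config$seed)
  cfg <- unclass(config)
  cfg$kinds <- arch$kinds
  cfg$icnr <- arch$icnr
  new("SegModel", config = cfg, layers = arch$layers, params = params,
      state = .initBNState(arch), channels = list(), steps = 0)
}

#' Verify the ICNR property of the pixel-shuffle layers
#'
#' True iff, for every pixel-shuffle upsampling layer, shuffling the
#' layer's convolution output on random input equals nearest-neighbour
#' upsampling of the convolution restricted to one sub-kernel (every
#' fourth output channel). Holds at initialization by construction and is
#' generally destroyed by the first gradient step.
#'
#' @param model a [SegModel-class] built with pixel-shuffle upsampling.
#' @param tol numeric comparison tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
icnrCheck <- function(model, tol = 1e-4) {
  if (model@config$upsampling != "pixel_shuffle_icnr")
    stop("model was not built with pixel_shuffle_icnr upsampling")
  .withSeed(404L, {
    for (wn in model@config$icnr) {
      w <- model@params[[wn]]
      b <- model@params[[sub("\\.w$", ".b", wn)]]
      d <- dim(w)
      cin <- d[3]; cout4 <- d[4]; cout <- cout4 %/% 4L
      x <- array(rnorm(8 * 8 * cin), c(8, 8, cin))
      y1 <- cpp_pixel_shuffle(cpp_conv2d(x, w, as.numeric(b), 1L, 0L), 2L)
      sub <- seq(1L, cout4, by = 4L)
      ysub <- cpp_conv2d(x, w[, , , sub, drop = FALSE], as.numeric(b[sub]),
                         1L, 0L)
      y2 <- array(0, dim(y1))
      for (cc in seq_len(cout))
        y2[, , cc] <- kronecker(ysub[, , cc], matrix(1, 2, 2))
      if (max(abs(y1 - y2)) > tol) return(FALSE)
    }
    TRUE
  })
}

#' Generalized Dice loss
#'
#' `GDL = 1 - 2 * sum_l w_l sum_n r_ln p_ln / sum_l w_l sum_n (r_ln +
#' p_ln)` with inverse-squared class-volume weights `w_l = 1 / (sum_n
#' r_ln)^2`; classes absent from the reference get zero weight. The value
#' lies in [0, 1], is 0 iff the prediction equals the reference exactly,
#' and 1 when every pixel's probability mass is on the wrong class.
#'
#' @param pred array of per-pixel class probabilities with classes in the
#'   last dimension; rows must sum to 1.
#' @param target one-hot array of the same shape.
#' @return The scalar loss.
#' @examples
#' pred <- array(c(0.9, 0.1, 0.1, 0.9), c(1, 2, 2))  # 2 pixels, 2 classes
#' target <- array(c(1, 0, 0, 1), c(1, 2, 2))
#' generalizedDiceLoss(pred, target)
#' @export
generalizedDiceLoss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)))
    stop("pred and target shapes do not match")
  nd <- length(dim(pred))
  nc <- dim(pred)[nd]
  pm <- matrix(pred, ncol = nc)
  tm <- matrix(target, ncol = nc)
  r <- colSums(tm)
  p <- colSums(pm)
  i <- colSums(tm * pm)
  w <- ifelse(r > 0, 1 / r^2, 0)
  den <- sum(w * (r + p))
  if (den == 0) return(0)
  1 - 2 * sum(w * i) / den
}

#' Jointly augment an image/mask pair
#'
#' Draws flip, rotation and zoom according to the configuration from the
#' current RNG stream and applies the identical geometric transform to the
#' image (bilinear) and the mask (nearest neighbour), so mask pixels stay
#' on their image structures. Deterministic given the RNG state.
#'
#' @param image numeric array (H, W, C).
#' @param mask numeric matrix (H, W) of labels in \{0, 1\}.
#' @param config an [augmentationConfig()].
#' @return A list with elements `image` and `mask`.
#' @export
augmentPair <- function(image, mask, config = augmentationConfig()) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  doFlip <- runif(1) < config$flip_prob
  theta <- if (runif(1) < config$rotation_prob)
    runif(1, -config$rotation_max_deg, config$rotation_max_deg) else 0
  zoom <- if (runif(1) < config$zoom_prob)
    runif(1, config$zoom_range[1], config$zoom_range[2]) else 1
  if (!doFlip && theta == 0 && zoom == 1)
    return(list(image = image, mask = mask))
  a <- theta * pi / 180
  Rinv <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  Fm <- diag(c(1, if (doFlip) -1 else 1))
  L <- (Rinv / zoom) %*% Fm
  ctr <- c((H - 1) / 2, (W - 1) / 2)
  A <- cbind(L, ctr - L %*% ctr)
  img <- cpp_warp2d(as.numeric(image), dim(image), A, 1L, 0)
  dim(img) <- d
  msk <- cpp_warp2d(as.numeric(mask), c(dim(mask), 1L), A, 0L, 0)
  dim(msk) <- dim(mask)
  list(image = img, mask = msk)
}

#' Predict a vessel mask for a whole volume
#'
#' Preprocesses each axial slice with the stored (or given) channel
#' configuration, forwards the slices through the network in batches, and
#' binarizes by per-pixel argmax over the two classes (vessel probability
#' > 0.5).
#'
#' @param model a trained [SegModel-class].
#' @param ncct a [CTVolume-class] non-contrast scan.
#' @param channels a [channelConfig()]; defaults to the configuration the
#'   model was trained with.
#' @param mapping optional [PercentileMapping-class] for uniform mode;
#'   fitted on `ncct` itself when omitted.
#' @param batchSize slices per forward pass.
#' @return A [BinaryMask-class] prediction on `ncct`'s grid.
#' @export
predictVolume <- function(model, ncct, channels = NULL, mapping = NULL,
                          batchSize = 16) {
  if (is.null(channels)) {
    if (!length(model@channels))
      stop("no channel configuration stored on the model; supply `channels`")
    channels <- model@channels$config
  }
  if (channels$n_channels != model@config$in_channels)
    stop(sprintf("channel mismatch: model expects %d input channels, %d given",
                 model@config$in_channels, channels$n_channels))
  if (is.null(mapping)) mapping <- .mappingFor(ncct, channels)
  xs <- makeChannels(ncct, channels, mapping)
  d <- dim(xs)
  nz <- d[1]
  pred <- array(0, dim(ncct))
  for (start in seq(1, nz, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, nz)
    x <- aperm(xs[idx, , , , drop = FALSE], c(2, 3, 4, 1))
    probs <- .netForward(model, x, train = FALSE)
    pv <- array(probs[, , 2, , drop = FALSE] > 0.5,
                dim(probs)[c(1, 2, 4)])
    pred[idx, , ] <- aperm(pv, c(3, 1, 2))
  }
  .maskLike(ncct, 1 * pred)
}

#' Print the stage geometry of a model
#'
#' @param model a [SegModel-class].
#' @param inputSize spatial input size (must be divisible by 8).
#' @return Invisibly, a data.frame of layers and output shapes.
#' @export
modelSummary <- function(model, inputSize = 64) {
  .checkInputSize(inputSize, inputSize)
  x <- array(0, c(inputSize, inputSize, model@config$in_channels, 1L))
  probs <- .netForward(model, x)
  rows <- data.frame(
    op = vapply(model@layers, `[[`, "", "op"),
    params = vapply(model@layers, function(l)
      sum(vapply(l$pn, function(p) length(model@params[[p]]), 1)), 1))
  cat(sprintf("%s: input %dx%dx%d -> output %dx%dx%d\n",
              model@config$variant, inputSize, inputSize,
              model@config$in_channels, dim(probs)[1], dim(probs)[2],
              dim(probs)[3]))
  agg <- stats::aggregate(params ~ op, rows, sum)
  print(agg, row.names = FALSE)
  invisible(rows)
}

#' Save and load model checkpoints
#'
#' Checkpoints embed the model and channel configurations, so inference
#' always uses the preprocessing the model was trained with.
#'
#' @param model a [SegModel-class].
#' @param path checkpoint file path (RDS).
#' @return `loadModel()` returns the [SegModel-class].
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "SegModel"))
  model
}
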