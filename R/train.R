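# Training: Adam with decoupled weight decay under a 1cycle learning-rate
# policy, on axial slices with joint image/mask augmentation and the
# pooled generalized Dice loss.

#' Training configuration
#'
#' Defaults follow the reference hyperparameters: peak learning rate 1e-4,
#' 16 epochs, batches of 20 slices, weight decay 1e-2, Adam. The 1cycle
#' schedule rises from `lr_max / lr_div` to `lr_max` over the first
#' `pct_start` of the steps and anneals to `lr_max / (lr_div *
#' final_div)`; both phases are cosine.
#'
#' @param lr_max peak learning rate.
#' @param epochs training epochs.
#' @param batch_size slices per batch.
#' @param weight_decay decoupled weight decay on convolution weights.
#' @param lr_div starting divisor of the schedule.
#' @param final_div final divisor (relative to `lr_max / lr_div`).
#' @param pct_start warmup fraction in (0, 1).
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @param seed seed controlling shuffling and augmentation draws.
#' @return A list of class `"TrainConfig"`.
#' @export
trainConfig <- function(lr_max = 1e-4, epochs = 16, batch_size = 20,
                        weight_decay = 1e-2, lr_div = 25, final_div = 1e4,
                        pct_start = 0.3, beta1 = 0.9, beta2 = 0.99,
                        eps = 1e-8, seed = 1) {
  stopifnot(lr_max > 0, epochs > 0, batch_size > 0, weight_decay >= 0,
            lr_div > 0, final_div > 0, pct_start > 0, pct_start < 1)
  structure(list(lr_max = lr_max, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, lr_div = lr_div,
                 final_div = final_div, pct_start = pct_start,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' 1cycle learning rate at a given step
#'
#' Cosine rise from `lr_max / lr_div` to `lr_max` over the first
#' `pct_start` of `total_steps`, then cosine fall to
#' `lr_max / (lr_div * final_div)`. Continuous and single-peaked.
#'
#' @param step 0-based step index in `[0, total_steps)`.
#' @param total_steps total optimization steps (>= 2).
#' @param config a [trainConfig()].
#' @return The learning rate.
#' @examples
#' oneCycleLR(0, 100, trainConfig())       # lr_max / 25
#' oneCycleLR(30, 100, trainConfig())      # lr_max at the peak
#' @export
oneCycleLR <- function(step, total_steps, config = trainConfig()) {
  if (any(step < 0) || any(step >= total_steps))
    stop("step out of range [0, total_steps)")
  lr0 <- config$lr_max / config$lr_div
  lrEnd <- lr0 / config$final_div
  peak <- round(config$pct_start * total_steps)
  peak <- max(1, min(peak, total_steps - 2))
  ifelse(step <= peak,
         lr0 + (config$lr_max - lr0) * (1 - cos(pi * step / peak)) / 2,
         lrEnd + (config$lr_max - lrEnd) *
           (1 + cos(pi * (step - peak) / (total_steps - 1 - peak))) / 2)
}

# Accept either a PhantomPair or a list(ncct =, label =) exam record.
.examNcct <- function(e) if (is(e, "PhantomPair")) e@ncct else e$ncct
.examLabel <- function(e) if (is(e, "PhantomPair")) e@truth else e$label
.examId <- function(e) patientId(.examNcct(e))
.examSex <- function(e) {
  if (is(e, "PhantomPair")) e@patientSex
  else if (!is.null(e$sex)) e$sex else NA_character_
}

# Assemble the axial-slice dataset: list of (H, W, C) inputs and (H, W)
# label matrices. Slices with empty labels are kept.
.sliceDataset <- function(cohort, channels) {
  xs <- list(); ys <- list()
  for (e in cohort) {
    ncct <- .examNcct(e)
    lab <- .examLabel(e)
    if (!.sameGrid(ncct, lab))
      stop("label grid does not match its exam for patient ", .examId(e))
    mapping <- .mappingFor(ncct, channels)
    ch <- makeChannels(ncct, channels, mapping)
    lv <- voxels(lab)
    for (i in seq_len(dim(ch)[1])) {
      xs[[length(xs) + 1L]] <- array(ch[i, , , ], dim(ch)[2:4])
      ys[[length(ys) + 1L]] <- matrix(lv[i, , ], dim(ch)[2], dim(ch)[3])
    }
  }
  list(x = xs, y = ys)
}

.adamInit <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

#' Train a segmentation model
#'
#' Assembles an axial-slice dataset from the cohort, then optimizes the
#' pooled generalized Dice loss with Adam (decoupled weight decay on
#' convolution weights) under the 1cycle schedule, applying the configured
#' augmentations per sample. Deterministic given the training seed.
#'
#' @param model a [SegModel-class] from [buildModel()].
#' @param cohort list of [PhantomPair-class] objects or of
#'   `list(ncct =, label =, sex =)` exam records.
#' @param channels a [channelConfig()] matching the model's input
#'   channels.
#' @param config a [trainConfig()].
#' @param augment an [augmentationConfig()]; pass probabilities of 0 to
#'   disable.
#' @param verbose print per-epoch losses.
#' @return A list with the trained `model` (channel configuration
#'   embedded) and `history`, the per-epoch mean training loss.
#' @export
trainModel <- function(model, cohort, channels = preprocPreset("simple-multi"),
                       config = trainConfig(),
                       augment = augmentationConfig(), verbose = FALSE) {
  stopifnot(length(cohort) >= 1)
  if (channels$n_channels != model@config$in_channels)
    stop("channel configuration does not match the model's input channels")
  ds <- .sliceDataset(cohort, channels)
  n <- length(ds$x)
  if (config$batch_size > n)
    stop(sprintf("batch size %d larger than dataset (%d slices)",
                 config$batch_size, n))
  spe <- n %/% config$batch_size
  total <- config$epochs * spe
  d1 <- dim(ds$x[[1]])
  decay <- names(model@params)[
    vapply(model@params, is.array, TRUE) &
      unlist(model@config$kinds[names(model@params)]) %in%
        c("conv", "convt", "icnr", "head", "attn")]
  opt <- .adamInit(model@params)
  history <- numeric(config$epochs)
  .withSeed(config$seed, {
    t <- 0L
    for (epoch in seq_len(config$epochs)) {
      perm <- sample(n)
      losses <- numeric(spe)
      for (s in seq_len(spe)) {
        idx <- perm[((s - 1L) * config$batch_size + 1L):
                      (s * config$batch_size)]
        nb <- length(idx)
        x <- array(0, c(d1, nb))
        tg <- array(0, c(d1[1], d1[2], 2L, nb))
        for (j in seq_len(nb)) {
          au <- augmentPair(ds$x[[idx[j]]], ds$y[[idx[j]]], augment)
          x[, , , j] <- au$image
          tg[, , 1L, j] <- 1 - au$mask
          tg[, , 2L, j] <- au$mask
        }
        res <- .netTrainStep(model, x, tg)
        model@state <- res$bn
        t <- t + 1L
        lr <- oneCycleLR(t - 1L, total, config)
        b1 <- config$beta1; b2 <- config$beta2
        for (k in names(model@params)) {
          g <- res$grads[[k]]
          opt[[k]]$m <- b1 * opt[[k]]$m + (1 - b1) * g
          opt[[k]]$v <- b2 * opt[[k]]$v + (1 - b2) * g * g
          mh <- opt[[k]]$m / (1 - b1^t)
          vh <- opt[[k]]$v / (1 - b2^t)
          upd <- mh / (sqrt(vh) + config$eps)
          if (k %in% decay)
            upd <- upd + config$weight_decay * model@params[[k]]
          model@params[[k]] <- model@params[[k]] - lr * upd
        }
        losses[s] <- res$loss
      }
      history[epoch] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %d/%d: mean GDL %.4f", epoch,
                        config$epochs, history[epoch]))
    }
    model@steps <- model@steps + total
  })
  model@channels <- list(config = channels)
  list(model = model, history = history)
}
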