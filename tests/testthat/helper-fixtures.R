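# Desk-scale fixtures used across the suite. The tiny phantom keeps unit
# tests fast; the default phantomSpec() is exercised in the acceptance
# tests.

tinySpec <- function(seed = 1, noise_sd = 8, misalignment = NULL) {
  phantomSpec(shape = c(8, 16, 16), spacing = c(2, 1, 1),
              brain = list(mean_hu = 30, noise_sd = noise_sd),
              vessel = list(n_roots = 1, depth = 0,
                            radius_range = c(1.5, 2.5),
                            contrast_range = c(120, 500), ncct_hu = 45),
              aneurysm = list(enabled = FALSE, diameter = 4),
              misalignment = misalignment, seed = seed)
}

microModelConfig <- function(seed = 1, ...) {
  modelConfig(base_width = 4, in_channels = 3, seed = seed, ...)
}

microTrainConfig <- function(epochs = 2, seed = 1, lr = 1e-2) {
  trainConfig(lr_max = lr, epochs = epochs, batch_size = 8, seed = seed)
}

noAugment <- function() augmentationConfig(0, 0, 0, c(1, 1), 0)

randomMask <- function(d, p = 0.3) {
  binaryMask(array(rbinom(prod(d), 1, p), d))
}

# Reference flood-fill component filter (independent of the compiled path).
refRemoveSmall <- function(vox, minVoxels, connectivity) {
  d <- dim(vox)
  lab <- array(0L, d)
  nb <- if (connectivity == 6) {
    rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    as.matrix(expand.grid(-1:1, -1:1, -1:1))[-14, ]
  }
  out <- array(0, d)
  nextLab <- 0L
  for (i in which(vox == 1)) {
    if (lab[i] != 0L) next
    nextLab <- nextLab + 1L
    comp <- integer(0)
    stack <- i
    lab[i] <- nextLab
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, cur)
      iz <- (cur - 1) %% d[1] + 1
      iy <- ((cur - 1) %/% d[1]) %% d[2] + 1
      ix <- (cur - 1) %/% (d[1] * d[2]) + 1
      for (k in seq_len(nrow(nb))) {
        z <- iz + nb[k, 1]; y <- iy + nb[k, 2]; x <- ix + nb[k, 3]
        if (z < 1 || y < 1 || x < 1 || z > d[1] || y > d[2] || x > d[3])
          next
        j <- z + d[1] * (y - 1) + d[1] * d[2] * (x - 1)
        if (vox[j] == 1 && lab[j] == 0L) { lab[j] <- nextLab; stack <- c(stack, j) }
      }
    }
    if (length(comp) >= minVoxels) out[comp] <- 1
  }
  out
}

# Exact two-sided rank-sum p by brute-force enumeration of all group
# assignments (oracle for the shift-algorithm implementation).
refRankSumP <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  wObs <- sum(r[seq_len(na)])
  combs <- utils::combn(na + nb, na)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  pLe <- mean(ws <= wObs + 1e-9)
  pGe <- mean(ws >= wObs - 1e-9)
  min(1, 2 * min(pLe, pGe))
}
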