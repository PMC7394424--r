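# Layer-graph construction for the two architectures. The graph is a flat
# list of op descriptors with explicit node references (node 0 is the
# input; layer i produces node i); a compiled executor runs forward and
# backward passes over it.

.newArch <- function() {
  env <- new.env(parent = emptyenv())
  env$layers <- list()
  env$node <- 0L           # last produced node id
  env$shapes <- list()     # param name -> dim
  env$kinds <- list()      # param name -> init kind
  env$bn <- character()    # bn layer names
  env$icnr <- character()  # pixel-shuffle conv weight names
  env
}

.addLayer <- function(env, op, ..., pn = character()) {
  spec <- list(op = op, pn = pn, ...)
  env$layers[[length(env$layers) + 1L]] <- spec
  env$node <- length(env$layers)
  env$node
}

.addConv <- function(env, name, k, cin, cout, stride = 1L, from = NULL,
                     kind = "conv") {
  wn <- paste0(name, ".w"); bn <- paste0(name, ".b")
  env$shapes[[wn]] <- c(k, k, cin, cout)
  env$shapes[[bn]] <- cout
  env$kinds[[wn]] <- kind
  env$kinds[[bn]] <- "bias"
  if (kind == "icnr") env$icnr <- c(env$icnr, wn)
  if (is.null(from))
    .addLayer(env, "conv", k = k, stride = stride, pn = c(wn, bn))
  else
    .addLayer(env, "conv", k = k, stride = stride, from = from,
              pn = c(wn, bn))
}

.addBN <- function(env, name, c) {
  gn <- paste0(name, ".g"); bn <- paste0(name, ".b")
  env$shapes[[gn]] <- c; env$shapes[[bn]] <- c
  env$kinds[[gn]] <- "bn_g"; env$kinds[[bn]] <- "bn_b"
  env$bn <- c(env$bn, name)
  .addLayer(env, "bn", name = name, pn = c(gn, bn))
}

.addConvBNRelu <- function(env, name, k, cin, cout, stride = 1L,
                           from = NULL) {
  .addConv(env, name, k, cin, cout, stride, from)
  .addBN(env, paste0(name, ".bn"), cout)
  .addLayer(env, "relu")
}

# Basic residual block: conv-bn-relu-conv-bn + projected shortcut, relu.
.addResBlock <- function(env, name, cin, cout, stride = 1L) {
  inNode <- env$node
  .addConv(env, paste0(name, ".c1"), 3L, cin, cout, stride)
  .addBN(env, paste0(name, ".bn1"), cout)
  .addLayer(env, "relu")
  .addConv(env, paste0(name, ".c2"), 3L, cout, cout, 1L)
  .addBN(env, paste0(name, ".bn2"), cout)
  mainNode <- env$node
  if (stride != 1L || cin != cout) {
    .addConv(env, paste0(name, ".sk"), 1L, cin, cout, stride, from = inNode)
    .addBN(env, paste0(name, ".skbn"), cout)
    skipNode <- env$node
  } else {
    skipNode <- inNode
  }
  .addLayer(env, "add", from = mainNode, with = skipNode)
  .addLayer(env, "relu")
}

.addStage <- function(env, name, cin, cout, stride, blocks) {
  .addResBlock(env, paste0(name, ".b1"), cin, cout, stride)
  if (blocks > 1L)
    for (b in 2:blocks)
      .addResBlock(env, paste0(name, ".b", b), cout, cout, 1L)
}

.addAttention <- function(env, name, c) {
  c8 <- max(1L, c %/% 8L)
  pn <- paste0(name, c(".f", ".g", ".h", ".gamma"))
  env$shapes[[pn[1]]] <- c(c, c8)
  env$shapes[[pn[2]]] <- c(c, c8)
  env$shapes[[pn[3]]] <- c(c, c)
  env$shapes[[pn[4]]] <- 1
  env$kinds[[pn[1]]] <- "attn"; env$kinds[[pn[2]]] <- "attn"
  env$kinds[[pn[3]]] <- "attn"; env$kinds[[pn[4]]] <- "gamma0"
  .addLayer(env, "sattn", pn = pn)
}

# Upsampling step: ICNR pixel shuffle (1x1 conv to 4x channels, shuffle) or
# a 2x2 stride-2 transposed convolution.
.addUpsample <- function(env, name, cin, cout, mode) {
  if (mode == "pixel_shuffle_icnr") {
    .addConv(env, paste0(name, ".up"), 1L, cin, 4L * cout, 1L,
             kind = "icnr")
    .addLayer(env, "pshuffle", r = 2L)
  } else {
    wn <- paste0(name, ".up.w"); bn <- paste0(name, ".up.b")
    env$shapes[[wn]] <- c(2L, 2L, cin, cout)
    env$shapes[[bn]] <- cout
    env$kinds[[wn]] <- "convt"; env$kinds[[bn]] <- "bias"
    .addLayer(env, "convt", pn = c(wn, bn))
  }
}

.addDecoderBlock <- function(env, name, cin, cout, skipNode, skipC, mode) {
  .addUpsample(env, name, cin, cout, mode)
  .addLayer(env, "concat", from = env$node, with = skipNode)
  .addConvBNRelu(env, paste0(name, ".m"), 3L, cout + skipC, cout)
}

.buildResnetUnet <- function(env, config) {
  w <- config$base_width
  b <- config$encoder_blocks_per_stage
  .addStage(env, "enc1", config$in_channels, w, 1L, b)
  e1 <- env$node
  .addStage(env, "enc2", w, 2L * w, 2L, b)
  e2 <- env$node
  .addStage(env, "enc3", 2L * w, 4L * w, 2L, b)
  e3 <- env$node
  .addStage(env, "enc4", 4L * w, 8L * w, 2L, b)
  if (isTRUE(config$self_attention))
    .addAttention(env, "attn", 8L * w)
  .addDecoderBlock(env, "dec3", 8L * w, 4L * w, e3, 4L * w,
                   config$upsampling)
  .addDecoderBlock(env, "dec2", 4L * w, 2L * w, e2, 2L * w,
                   config$upsampling)
  .addDecoderBlock(env, "dec1", 2L * w, w, e1, w, config$upsampling)
  .addConv(env, "head", 1L, w, 2L, kind = "head")
  .addLayer(env, "softmax")
}

.addDoubleConv <- function(env, name, cin, cout) {
  .addConvBNRelu(env, paste0(name, ".c1"), 3L, cin, cout)
  .addConvBNRelu(env, paste0(name, ".c2"), 3L, cout, cout)
}

.buildBaselineUnet <- function(env, config) {
  w <- config$base_width
  .addDoubleConv(env, "down1", config$in_channels, w)
  e1 <- env$node
  .addLayer(env, "maxpool")
  .addDoubleConv(env, "down2", w, 2L * w)
  e2 <- env$node
  .addLayer(env, "maxpool")
  .addDoubleConv(env, "down3", 2L * w, 4L * w)
  e3 <- env$node
  .addLayer(env, "maxpool")
  .addDoubleConv(env, "bott", 4L * w, 8L * w)
  .addUpsample(env, "up3", 8L * w, 4L * w, config$upsampling)
  .addLayer(env, "concat", from = env$node, with = e3)
  .addDoubleConv(env, "up3.m", 8L * w, 4L * w)
  .addUpsample(env, "up2", 4L * w, 2L * w, config$upsampling)
  .addLayer(env, "concat", from = env$node, with = e2)
  .addDoubleConv(env, "up2.m", 4L * w, 2L * w)
  .addUpsample(env, "up1", 2L * w, w, config$upsampling)
  .addLayer(env, "concat", from = env$node, with = e1)
  .addDoubleConv(env, "up1.m", 2L * w, w)
  .addConv(env, "head", 1L, w, 2L, kind = "head")
  .addLayer(env, "softmax")
}

.netArchitecture <- function(config) {
  env <- .newArch()
  if (config$variant == "resnet_unet") .buildResnetUnet(env, config)
  else .buildBaselineUnet(env, config)
  # compiled executor uses 0-based node ids; R side records 1-based
  layers <- lapply(env$layers, function(l) {
    if (!is.null(l$from)) l$from <- as.integer(l$from)
    if (!is.null(l$with)) l$with <- as.integer(l$with)
    l
  })
  list(layers = layers, shapes = env$shapes, kinds = env$kinds,
       bn = env$bn, icnr = env$icnr)
}

# He-style initialization; ICNR replication for pixel-shuffle convs;
# zero-initialized classification head; identity-gated attention.
.initParams <- function(arch, seed) {
  .withSeed(seed, {
    params <- list()
    for (nm in names(arch$shapes)) {
      d <- arch$shapes[[nm]]
      kind <- arch$kinds[[nm]]
      p <- switch(kind,
        conv = array(rnorm(prod(d), 0, sqrt(2 / (d[1] * d[2] * d[3]))), d),
        convt = array(rnorm(prod(d), 0, sqrt(2 / (2 * 2 * d[3]))), d),
        icnr = {
          cout <- d[4] %/% 4L
          base <- array(rnorm(prod(d[1:3]) * cout, 0,
                              sqrt(2 / (d[1] * d[2] * d[3]))),
                        c(d[1], d[2], d[3], cout))
          full <- array(0, d)
          for (cc in seq_len(cout))
            for (j in 1:4)
              full[, , , (cc - 1L) * 4L + j] <- base[, , , cc]
          full
        },
        head = array(0, d),
        attn = array(rnorm(prod(d), 0, sqrt(2 / d[1])), d),
        gamma0 = array(0, 1),
        bn_g = array(1, d),
        bn_b = array(0, d),
        bias = array(0, d))
      params[[nm]] <- p
    }
    params
  })
}

.initBNState <- function(arch) {
  state <- list()
  for (nm in arch$bn) {
    c <- arch$shapes[[paste0(nm, ".g")]]
    state[[paste0(nm, ".mean")]] <- rep(0, c)
    state[[paste0(nm, ".var")]] <- rep(1, c)
  }
  state
}

.checkInputSize <- function(h, w) {
  if (h %% 8L != 0L || w %% 8L != 0L)
    stop("input spatial size must be divisible by 8 (total downsampling ",
         "factor); got ", h, "x", w)
}

# Forward pass -> per-pixel class probabilities (H, W, 2, N).
.netForward <- function(model, x, train = FALSE) {
  .checkInputSize(dim(x)[1], dim(x)[2])
  res <- cpp_net_run(model@layers, model@params, model@state, x, NULL,
                     train)
  res$probs
}

# One training evaluation: pooled generalized Dice loss, parameter
# gradients and updated batch-norm running statistics.
.netTrainStep <- function(model, x, target) {
  .checkInputSize(dim(x)[1], dim(x)[2])
  cpp_net_run(model@layers, model@params, model@state, x, target, TRUE)
}
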