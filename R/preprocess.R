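# Intensity preprocessing: convert HU volumes into model-ready multi-channel
# inputs in [0, 1], either by linear windowing (single or per-channel
# windows) or by percentile uniformization (a monotone HU -> [0,1] mapping
# that flattens the bimodal CT histogram).

#' Radiodensity window
#'
#' @param low_hu,high_hu window bounds in HU, `low_hu < high_hu`.
#' @return A list of class `"WindowSpec"`.
#' @export
windowSpec <- function(low_hu, high_hu) {
  stopifnot(is.finite(low_hu), is.finite(high_hu), low_hu < high_hu)
  structure(list(low_hu = low_hu, high_hu = high_hu), class = "WindowSpec")
}

#' Channel configuration
#'
#' How a HU volume becomes the network's input channels. `"simple"` mode
#' clips to one window (replicated over `n_channels`) or to three
#' per-channel windows; `"uniform"` mode applies a fitted
#' [PercentileMapping-class] (optionally after clipping) and replicates it.
#'
#' @param mode `"simple"` or `"uniform"`.
#' @param windows a [windowSpec()] or list of 1 or 3 of them (simple mode).
#' @param clip optional [windowSpec()] clip range (uniform mode).
#' @param n_bins percentile bins for uniform mode (>= 2).
#' @param n_channels 1 or 3.
#' @return A list of class `"ChannelConfig"`.
#' @seealso [preprocPreset()] for the four standard configurations.
#' @export
channelConfig <- function(mode = c("simple", "uniform"), windows = NULL,
                          clip = NULL, n_bins = 100, n_channels = 3) {
  mode <- match.arg(mode)
  stopifnot(n_channels %in% c(1, 3))
  if (mode == "simple") {
    if (inherits(windows, "WindowSpec")) windows <- list(windows)
    if (is.null(windows) || !length(windows) %in% c(1, 3) ||
        !all(vapply(windows, inherits, TRUE, "WindowSpec")))
      stop("simple mode needs 1 or 3 WindowSpec windows")
    if (length(windows) == 3 && n_channels != 3)
      stop("three windows require n_channels = 3")
  } else {
    stopifnot(n_bins >= 2)
    if (!is.null(clip) && !inherits(clip, "WindowSpec"))
      stop("clip must be a WindowSpec or NULL")
  }
  structure(list(mode = mode, windows = windows, clip = clip,
                 n_bins = as.integer(n_bins),
                 n_channels = as.integer(n_channels)),
            class = "ChannelConfig")
}

#' Standard preprocessing presets
#'
#' The four tested configurations: `"simple-single"` ((-100, 300) HU on all
#' three channels), `"simple-multi"` ((-40, 120), (-100, 300), (300, 2000)
#' HU over the three channels), `"uniform-full"` (percentile uniformization
#' of the full range) and `"uniform-clip"` (uniformization after clipping
#' to (-100, 300) HU).
#'
#' @param name preset name.
#' @param n_channels 1 or 3 (simple-single and uniform presets only).
#' @return A [channelConfig()].
#' @export
preprocPreset <- function(name = c("simple-single", "simple-multi",
                                   "uniform-full", "uniform-clip"),
                          n_channels = 3) {
  switch(match.arg(name),
    "simple-single" = channelConfig("simple",
                                    windows = windowSpec(-100, 300),
                                    n_channels = n_channels),
    "simple-multi" = channelConfig("simple",
                                   windows = list(windowSpec(-40, 120),
                                                  windowSpec(-100, 300),
                                                  windowSpec(300, 2000)),
                                   n_channels = 3),
    "uniform-full" = channelConfig("uniform", n_channels = n_channels),
    "uniform-clip" = channelConfig("uniform",
                                   clip = windowSpec(-100, 300),
                                   n_channels = n_channels))
}

#' Linear window scaling
#'
#' `v -> clip((v - low) / (high - low), 0, 1)`.
#'
#' @param vol a [CTVolume-class] or numeric array.
#' @param window a [windowSpec()].
#' @return An array of the same shape with values in [0, 1].
#' @examples
#' windowScale(array(c(-200, -100, 100, 300, 400), c(1, 1, 5)),
#'             windowSpec(-100, 300))
#' @export
windowScale <- function(vol, window) {
  stopifnot(inherits(window, "WindowSpec"))
  v <- if (is(vol, "CTVolume")) voxels(vol) else vol
  pmin(pmax((v - window$low_hu) / (window$high_hu - window$low_hu), 0), 1)
}

#' Fit a percentile mapping
#'
#' Knots are the empirical percentiles at `i / n_bins`, `i = 0..n_bins`, of
#' the pooled (optionally clipped) voxel values of one or more volumes.
#' Repeated HU values may collapse adjacent knots; see
#' [applyPercentileMapping()] for the tie rule.
#'
#' @param volumes a [CTVolume-class] or list of them.
#' @param n_bins number of percentile bins (>= 2), default 100.
#' @param clip optional [windowSpec()]; values are clipped into it first.
#' @return A [PercentileMapping-class].
#' @export
fitPercentileMapping <- function(volumes, n_bins = 100, clip = NULL) {
  stopifnot(n_bins >= 2)
  if (is(volumes, "CTVolume")) volumes <- list(volumes)
  vals <- unlist(lapply(volumes, function(v) as.numeric(voxels(v))))
  if (!is.null(clip)) {
    stopifnot(inherits(clip, "WindowSpec"))
    vals <- pmin(pmax(vals, clip$low_hu), clip$high_hu)
  }
  if (!length(vals)) stop("no voxels to fit the mapping on")
  if (max(vals) <= min(vals))
    stop("degenerate percentile mapping: all values identical")
  knots <- unname(quantile(vals, probs = seq(0, 1, length.out = n_bins + 1),
                           type = 7))
  new("PercentileMapping", knots = knots)
}

#' Apply a percentile mapping
#'
#' Piecewise-linear interpolation through `(knot_i, i / n_bins)`; values
#' beyond the knot range are clipped to 0/1. Where repeated values collapse
#' knots, the zero-width bin maps to its lower output edge, keeping the
#' mapping deterministic and nondecreasing.
#'
#' @param vol a [CTVolume-class] or numeric array.
#' @param mapping a [PercentileMapping-class].
#' @return An array of the same shape with values in [0, 1].
#' @export
applyPercentileMapping <- function(vol, mapping) {
  stopifnot(is(mapping, "PercentileMapping"))
  v <- if (is(vol, "CTVolume")) voxels(vol) else vol
  n <- length(mapping@knots) - 1L
  out <- approx(mapping@knots, seq(0, 1, length.out = n + 1L), xout = v,
                rule = 2, ties = min)$y
  if (!is.null(dim(v))) dim(out) <- dim(v)
  out
}

#' Build the model input channels for a volume
#'
#' Returns a 4-D array (slice, row, col, channel) in [0, 1] according to
#' the channel configuration: one scaled field replicated over channels, or
#' one channel per window in the listed order.
#'
#' @param vol a [CTVolume-class].
#' @param config a [channelConfig()].
#' @param mapping a fitted [PercentileMapping-class]; required in uniform
#'   mode, ignored otherwise.
#' @return A numeric 4-D array.
#' @examples
#' vol <- ctVolume(array(200, c(1, 2, 2)))
#' makeChannels(vol, preprocPreset("simple-multi"))[1, 1, 1, ]
#' @export
makeChannels <- function(vol, config, mapping = NULL) {
  stopifnot(inherits(config, "ChannelConfig"))
  d <- dim(vol)
  out <- array(0, c(d, config$n_channels))
  if (config$mode == "simple") {
    if (length(config$windows) == 1L) {
      f <- windowScale(vol, config$windows[[1]])
      for (ch in seq_len(config$n_channels)) out[, , , ch] <- f
    } else {
      for (ch in 1:3) out[, , , ch] <- windowScale(vol, config$windows[[ch]])
    }
  } else {
    if (is.null(mapping))
      stop("uniform mode requires a fitted PercentileMapping")
    f <- applyPercentileMapping(vol, mapping)
    for (ch in seq_len(config$n_channels)) out[, , , ch] <- f
  }
  out
}

# Fit the mapping a channel config needs for one volume (NULL for simple).
.mappingFor <- function(vol, config) {
  if (config$mode == "uniform")
    fitPercentileMapping(vol, n_bins = config$n_bins, clip = config$clip)
  else NULL
}
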