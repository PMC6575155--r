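#' Locate the highest activation of a feature map
#'
#' Finds the maximum of one feature map over the final convolution grid
#' (post-rectification, before the last pool). Ties are broken towards the
#' smallest row-major grid index.
#'
#' @param model a [TissueCNN-class].
#' @param image H x W x 3 array matching the network input size.
#' @param featureMap feature-map index (1-based).
#' @param layer convolution layer to inspect (default the last).
#' @return list with `featureMap`, `gridRow`, `gridCol` (1-based), `value`.
#' @export
locatePeak <- function(model, image, featureMap,
                       layer = paste0("conv", length(model@config@convMaps))) {
  stopifnot(is(model, "TissueCNN"))
  nMaps <- model@config@convMaps[length(model@config@convMaps)]
  if (featureMap < 1L || featureMap > nMaps)
    stopf("featureMap must lie in [1, %d], got %s", nMaps, featureMap)
  grid <- layerActivations(model, image, layer)[, , featureMap]
  ## row-major tie-break: scan transposed so earlier rows win first
  tg <- t(grid)
  idx <- which.max(tg)  # first maximum in row-major order of `grid`
  gridRow <- (idx - 1L) %/% ncol(grid) + 1L
  gridCol <- (idx - 1L) %% ncol(grid) + 1L
  list(featureMap = as.integer(featureMap), gridRow = gridRow,
       gridCol = gridCol, value = as.numeric(tg[idx]))
}

#' Receptive-field box of a grid unit
#'
#' Standard receptive-field recurrence through the stride-1 zero-padded
#' convolutions and window-stride pools: the field size grows by
#' `(kernel - 1) * jump` per convolution and `(window - 1) * jump` per pool,
#' and the jump multiplies by each pool window. For the default
#' architecture the field of a final-convolution unit is 164 pixels wide
#' with a jump of 40 between neighbouring units.
#'
#' @param config a [NetworkConfig-class].
#' @param gridRow,gridCol 1-based unit position in the layer's grid.
#' @param layer `"convL"` or `"poolL"` name.
#' @return list with `rowRange`, `colRange` (1-based pixel bounds, clipped
#'   to the image), `clipped` flag, `center` (may lie outside the image for
#'   border units), `fieldSize` (analytic, unclipped) and `jump` (pixel
#'   stride between neighbouring units).
#' @export
receptiveFieldBox <- function(config, gridRow, gridCol, layer = "conv4") {
  stopifnot(is(config, "NetworkConfig"))
  L <- length(config@convMaps)
  m <- regmatches(layer, regexec("^(conv|pool)([0-9]+)$", layer))[[1]]
  if (length(m) != 3L || as.integer(m[3]) < 1L || as.integer(m[3]) > L)
    stopf("unknown layer '%s'", layer)
  upto <- as.integer(m[3])
  kind <- m[2]
  rf <- 1
  jump <- 1
  start <- 0  # centre of unit (1,1), 0-based pixel coordinates
  for (l in seq_len(upto)) {
    rf <- rf + (config@convKernels[l] - 1) * jump  # same padding: no shift
    if (kind == "conv" && l == upto) break
    w <- config@poolWindows[l]
    rf <- rf + (w - 1) * jump
    start <- start + (w - 1) / 2 * jump
    jump <- jump * w
  }
  side <- config@inputSize
  gridSide <- if (kind == "conv") {
    s <- config@inputSize
    if (upto > 1) for (l in seq_len(upto - 1L)) s <- s %/% config@poolWindows[l]
    s
  } else {
    s <- config@inputSize
    for (l in seq_len(upto)) s <- s %/% config@poolWindows[l]
    s
  }
  if (gridRow < 1L || gridRow > gridSide || gridCol < 1L ||
      gridCol > gridSide)
    stopf("grid position (%d, %d) outside the %dx%d %s grid", gridRow,
          gridCol, gridSide, gridSide, layer)
  center <- c(row = start + (gridRow - 1) * jump + 1,
              col = start + (gridCol - 1) * jump + 1)  # 1-based
  half <- (rf - 1) / 2
  rowRange <- c(center[["row"]] - half, center[["row"]] + half)
  colRange <- c(center[["col"]] - half, center[["col"]] + half)
  clipped <- rowRange[1] < 1 || colRange[1] < 1 || rowRange[2] > side ||
    colRange[2] > side
  list(rowRange = pmin(pmax(round(rowRange), 1L), side),
       colRange = pmin(pmax(round(colRange), 1L), side),
       clipped = clipped, center = center, fieldSize = rf, jump = jump)
}

## Crop a square segment of the requested side centred on `center`,
## clipped at the image borders.
cropSegment <- function(image, center, side) {
  H <- dim(image)[1]
  W <- dim(image)[2]
  half <- (side - 1) / 2
  rows <- max(1L, round(center[1] - half)):min(H, round(center[1] + half))
  cols <- max(1L, round(center[2] - half)):min(W, round(center[2] + half))
  image[rows, cols, , drop = FALSE]
}

## Peak of every feature map from a single forward pass.
imagePeaks <- function(model, image) {
  layer <- paste0("conv", length(model@config@convMaps))
  acts <- layerActivations(model, image, layer)
  lapply(seq_len(dim(acts)[3]), function(m) {
    tg <- t(acts[, , m])
    idx <- which.max(tg)
    list(featureMap = m,
         gridRow = (idx - 1L) %/% ncol(acts) + 1L,
         gridCol = (idx - 1L) %% ncol(acts) + 1L,
         value = as.numeric(tg[idx]))
  })
}

## Turn a located peak into a segment record (crop + provenance).
peakToSegment <- function(model, image, peak, segmentSide, sourceId) {
  rf <- receptiveFieldBox(model@config, peak$gridRow, peak$gridCol,
                          paste0("conv", length(model@config@convMaps)))
  list(pixels = cropSegment(image, rf$center, segmentSide),
       sourceId = sourceId, center = rf$center, value = peak$value,
       featureMap = as.integer(peak$featureMap), fieldBox = rf)
}

## Trace one feature map's peak on one image to a segment record.
traceSegment <- function(model, image, featureMap, segmentSide = 142L,
                         sourceId = "image") {
  peak <- locatePeak(model, image, featureMap)
  peakToSegment(model, image, peak, segmentSide, sourceId)
}

#' Highest-activation segments across an image set
#'
#' For one feature map, locates the per-image peak activation, traces each
#' peak to its receptive-field centre in the source image, and returns the
#' `k` highest per-image peaks (descending) as fixed-size square crops
#' (default side 142, the reported segment size; the analytic receptive
#' field is available from each record's `fieldBox`). Crops are clipped at
#' image borders.
#'
#' @param model a [TissueCNN-class].
#' @param images list of H x W x 3 arrays.
#' @param featureMap feature-map index.
#' @param k segments to return (default 9); when fewer images are
#'   available, all are returned with a warning.
#' @param segmentSide square crop side in pixels.
#' @param sourceIds identifiers per image.
#' @return list of segment records ordered by non-increasing activation.
#' @export
topKSegments <- function(model, images, featureMap, k = 9L,
                         segmentSide = 142L,
                         sourceIds = paste0("image", seq_along(images))) {
  stopifnot(is(model, "TissueCNN"))
  if (k < 1L) stopf("k must be at least 1")
  if (length(images) == 0L) stopf("at least one image is required")
  segs <- mapply(function(img, id)
    traceSegment(model, img, featureMap, segmentSide, id),
    images, sourceIds, SIMPLIFY = FALSE)
  vals <- vapply(segs, function(s) s$value, 0)
  ord <- order(-vals)
  if (length(segs) < k) {
    warnf("only %d image peak(s) available for k = %d", length(segs), k)
    k <- length(segs)
  }
  segs[ord[seq_len(k)]]
}

#' Export a segment gallery
#'
#' Writes each segment crop as a PNG plus a tab-separated index
#' (map, rank, source, centre, activation value).
#'
#' @param segments list of segment records from [topKSegments()].
#' @param outDir output directory.
#' @return the index path, invisibly.
#' @export
writeSegmentGallery <- function(segments, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  idx <- data.frame(
    map = vapply(segments, function(s) s$featureMap, 0L),
    rank = seq_along(segments),
    source = vapply(segments, function(s) s$sourceId, ""),
    center_row = vapply(segments, function(s) round(s$center[1]), 0),
    center_col = vapply(segments, function(s) round(s$center[2]), 0),
    value = vapply(segments, function(s) s$value, 0))
  for (i in seq_along(segments))
    writeImageFile(segments[[i]]$pixels,
                   file.path(outDir, sprintf("map%02d_rank%02d.png",
                                             idx$map[i], i)))
  path <- file.path(outDir, "segments.tsv")
  utils::write.table(idx, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Hand-constructed blob-detector network
#'
#' Builds a network of the given architecture whose first feature map
#' responds to local darkness (negative mean-intensity filter with a
#' positive bias) and whose deeper layers pass that map through unchanged
#' (centre-tap identity kernels). The final-layer peak of map 1 therefore
#' sits on the darkest local structure of the input — a known ground truth
#' for validating the activation traceback.
#'
#' @param config a [NetworkConfig-class].
#' @param threshold background intensity (0..1 scale) above which the
#'   darkness response is zero.
#' @return An untrained-weight [TissueCNN-class] with deterministic,
#'   hand-set weights.
#' @export
blobDetectorModel <- function(config, threshold = 0.7) {
  stopifnot(is(config, "NetworkConfig"))
  model <- buildModel(config, seed = 0L)
  w <- model@weights
  cin <- config@nChannels
  for (l in seq_along(config@convMaps)) {
    k <- config@convKernels[l]
    cout <- config@convMaps[l]
    W <- matrix(0, k * k * cin, cout)
    b <- numeric(cout)
    if (l == 1L) {
      # map 1: bias - mean local intensity over all channels
      W[, 1] <- -1 / (k * k * cin)
      b[1] <- threshold
    } else {
      # identity centre tap map1 -> map1; row index of (dr, dc, ci):
      # dr + k * (dc + k * ci) with dr = dc = (k-1)/2, ci = 0
      mid <- (k - 1L) %/% 2L
      W[mid + k * mid + 1L, 1] <- 1
    }
    w$conv[[l]]$W <- W
    w$conv[[l]]$b <- b
    cin <- cout
  }
  model@weights <- w
  model
}
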