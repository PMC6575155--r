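## Image preparation: slide tiling, training/test patch extraction with
## reflections, and colour augmentation (gamma correction, optional CLAHE).
##
## Patches are lightweight lists with elements `pixels` (H x W x 3 array,
## 0..255), `sourceId`, `offset` (1-based top-left row/col in the source),
## `reflection` ("none", "horizontal" or "vertical") and `gamma` (NA until
## colour augmentation is applied). Bulk stages keep them as plain lists.

newPatch <- function(pixels, sourceId, offset, reflection = "none",
                     gamma = NA_real_) {
  structure(list(pixels = pixels, sourceId = sourceId,
                 offset = as.integer(offset), reflection = reflection,
                 gamma = gamma),
            class = "biopsyPatch")
}

#' @export
print.biopsyPatch <- function(x, ...) {
  cat(sprintf("biopsyPatch %dx%d from %s at (%d,%d), reflection %s\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$sourceId,
              x$offset[1], x$offset[2], x$reflection))
  invisible(x)
}

reflectPixels <- function(px, reflection) {
  switch(reflection,
         none = px,
         horizontal = px[, dim(px)[2]:1, , drop = FALSE],
         vertical = px[dim(px)[1]:1, , , drop = FALSE],
         stopf("unknown reflection '%s'", reflection))
}

#' Tile a slide image into fixed-size frames
#'
#' Cuts the non-overlapping row-major grid of `tileHeight` x `tileWidth`
#' frames out of a slide image; partial border strips are discarded so every
#' tile has the full fixed size. The default tile is 1360 wide by 1024 high.
#'
#' @param image H x W x 3 array (0..255).
#' @param tileHeight,tileWidth tile size in pixels.
#' @param sourceId identifier recorded on each tile.
#' @return list of patch objects (one per tile, offsets 1-based); an empty
#'   list with a warning when the image is smaller than one tile.
#' @export
#' @examples
#' img <- array(128, c(2048, 2720, 3))
#' length(tileSlide(img))  # 4 tiles
tileSlide <- function(image, tileHeight = 1024L, tileWidth = 1360L,
                      sourceId = "slide") {
  assertImage(image)
  H <- dim(image)[1]
  W <- dim(image)[2]
  nr <- H %/% tileHeight
  nc <- W %/% tileWidth
  if (nr < 1L || nc < 1L) {
    warnf("image %dx%d is smaller than one %dx%d tile; no tiles produced",
          H, W, tileHeight, tileWidth)
    return(list())
  }
  out <- vector("list", nr * nc)
  i <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      r0 <- (r - 1L) * tileHeight + 1L
      c0 <- (cc - 1L) * tileWidth + 1L
      i <- i + 1L
      out[[i]] <- newPatch(
        image[r0:(r0 + tileHeight - 1L), c0:(c0 + tileWidth - 1L), ,
              drop = FALSE],
        sourceId, c(r0, c0))
    }
  }
  out
}

#' Augmentation configuration
#'
#' @param nTrainPatches random base patches per image (each emitted with its
#'   two reflections, so the patch count per image is `3 * nTrainPatches`
#'   when reflections are on).
#' @param patchSize square patch side in pixels.
#' @param gammaRange interval the per-patch gamma is drawn from.
#' @param claheEnabled apply contrast-limited adaptive histogram equalization
#'   to the luminance channel after gamma (off by default; gamma alone is the
#'   recommended augmentation).
#' @param reflections emit horizontal/vertical reflections of each base patch.
#' @param gammaAugment draw and apply a random gamma per training patch.
#' @param seed integer seed for offset and gamma draws.
#' @return list of class `augmentationConfig`.
#' @export
augmentationConfig <- function(nTrainPatches = 10L, patchSize = 1000L,
                               gammaRange = c(0.5, 2.0),
                               claheEnabled = FALSE, reflections = TRUE,
                               gammaAugment = FALSE, seed = 1L) {
  if (any(gammaRange <= 0)) stopf("gammaRange must be positive")
  if (nTrainPatches < 1L) stopf("nTrainPatches must be at least 1")
  structure(list(nTrainPatches = as.integer(nTrainPatches),
                 patchSize = as.integer(patchSize),
                 gammaRange = as.numeric(gammaRange),
                 claheEnabled = isTRUE(claheEnabled),
                 reflections = isTRUE(reflections),
                 gammaAugment = isTRUE(gammaAugment),
                 seed = as.integer(seed)),
            class = "augmentationConfig")
}

#' Sample random training patches
#'
#' Draws `cfg$nTrainPatches` uniformly random square offsets and emits each
#' base patch together with its horizontal and vertical reflections (when
#' `cfg$reflections` is on), multiplying the per-image patch count by three.
#' When `cfg$gammaAugment` is on, a gamma from `cfg$gammaRange` is drawn and
#' applied independently per emitted patch.
#'
#' @param image H x W x 3 array (0..255), at least `patchSize` in both
#'   dimensions.
#' @param cfg an [augmentationConfig()].
#' @param sourceId identifier recorded on each patch.
#' @param seed RNG seed; defaults to `cfg$seed`. Pass `NULL` to use the
#'   current RNG state.
#' @return list of patch objects.
#' @export
sampleTrainingPatches <- function(image, cfg = augmentationConfig(),
                                  sourceId = "image", seed = cfg$seed) {
  assertImage(image)
  ps <- cfg$patchSize
  H <- dim(image)[1]
  W <- dim(image)[2]
  if (H < ps || W < ps)
    stopf("image %dx%d is smaller than the %dx%d patch", H, W, ps, ps)
  withSeed(seed, {
    rows <- sample.int(H - ps + 1L, cfg$nTrainPatches, replace = TRUE)
    cols <- sample.int(W - ps + 1L, cfg$nTrainPatches, replace = TRUE)
    refl <- if (cfg$reflections) c("none", "horizontal", "vertical")
            else "none"
    out <- vector("list", cfg$nTrainPatches * length(refl))
    i <- 0L
    for (b in seq_len(cfg$nTrainPatches)) {
      base <- image[rows[b]:(rows[b] + ps - 1L),
                    cols[b]:(cols[b] + ps - 1L), , drop = FALSE]
      for (rf in refl) {
        i <- i + 1L
        p <- newPatch(reflectPixels(base, rf), sourceId,
                      c(rows[b], cols[b]), rf)
        if (cfg$gammaAugment) p <- colorAugment(p, cfg, seed = NULL)
        out[[i]] <- p
      }
    }
    out
  })
}

#' Extract the fixed 15-patch test layout
#'
#' Deterministically extracts one central and four corner patches and emits
#' each with its horizontal and vertical reflections: always 15 patches. The
#' centre offset uses floor division; offsets are 1-based.
#'
#' @param image H x W x 3 array (0..255), at least `patchSize` in both
#'   dimensions.
#' @param patchSize square patch side.
#' @param sourceId identifier recorded on each patch.
#' @return list of exactly 15 patch objects.
#' @export
extractTestPatches <- function(image, patchSize = 1000L,
                               sourceId = "image") {
  assertImage(image)
  ps <- patchSize
  H <- dim(image)[1]
  W <- dim(image)[2]
  if (H < ps || W < ps)
    stopf("image %dx%d is smaller than the %dx%d patch", H, W, ps, ps)
  offs <- list(c(1L, 1L),
               c(1L, W - ps + 1L),
               c(H - ps + 1L, 1L),
               c(H - ps + 1L, W - ps + 1L),
               c((H - ps) %/% 2L + 1L, (W - ps) %/% 2L + 1L))
  out <- vector("list", 15L)
  i <- 0L
  for (o in offs) {
    base <- image[o[1]:(o[1] + ps - 1L), o[2]:(o[2] + ps - 1L), ,
                  drop = FALSE]
    for (rf in c("none", "horizontal", "vertical")) {
      i <- i + 1L
      out[[i]] <- newPatch(reflectPixels(base, rf), sourceId, o, rf)
    }
  }
  out
}

#' Gamma / CLAHE colour augmentation
#'
#' Applies the power-law intensity transform
#' `out = round(255 * (in / 255)^gamma)` per channel, with gamma drawn
#' uniformly from `cfg$gammaRange` when not given explicitly. When
#' `cfg$claheEnabled`, contrast-limited adaptive histogram equalization is
#' applied to the luminance channel after the gamma step and the RGB
#' channels are rescaled by the luminance ratio.
#'
#' @param patch a patch object or an H x W x 3 array (0..255).
#' @param cfg an [augmentationConfig()].
#' @param gamma explicit gamma; `NULL` draws from the configured range.
#' @param seed RNG seed for the draw (`NULL` uses the current RNG state).
#' @return The augmented patch (same type as the input), with the applied
#'   gamma recorded on patch objects.
#' @export
colorAugment <- function(patch, cfg = augmentationConfig(), gamma = NULL,
                         seed = NULL) {
  isPatch <- inherits(patch, "biopsyPatch")
  px <- if (isPatch) patch$pixels else patch
  assertImage(px, "patch")
  if (is.null(gamma))
    gamma <- withSeed(seed,
      stats::runif(1, cfg$gammaRange[1], cfg$gammaRange[2]))
  if (gamma <= 0) stopf("gamma must be positive, got %g", gamma)
  out <- round(255 * (px / 255)^gamma)
  if (cfg$claheEnabled) out <- claheLuminance(out)
  out <- clip255(out)
  if (isPatch) {
    patch$pixels <- out
    patch$gamma <- gamma
    patch
  } else out
}

## CLAHE on the luminance channel; RGB rescaled by the luminance ratio.
claheLuminance <- function(px) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stopf("CLAHE requires the EBImage package")
  y <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  eq <- EBImage::clahe(EBImage::Image(t(y) / 255), nx = 8, ny = 8)
  yNew <- t(EBImage::imageData(eq)) * 255
  ratio <- ifelse(y > 0, yNew / y, 1)
  out <- px
  for (ch in 1:3) out[, , ch] <- px[, , ch] * ratio
  clip255(out)
}
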