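## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

## Clip numeric values to the 8-bit intensity range.
clip255 <- function(x) pmin(pmax(x, 0), 255)

## Assert an H x W x 3 numeric array with 8-bit-range values.
assertImage <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stopf("%s must be an H x W x 3 array", what)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stopf("%s must have positive dimensions", what)
  invisible(img)
}

## Derive a reproducible child seed from a parent seed and a stream index,
## staying within the 32-bit integer range.
childSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 1299709) %% 2147483647)
}

## Run code with a temporarily-set RNG state, restoring the caller's state.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Read an 8-bit RGB PNG or TIFF into an H x W x 3 array of 0..255 values.
readImageFile <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '%s' (use png or tiff): %s", ext, path))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

## Write an H x W x 3 array of 0..255 values as 8-bit PNG or TIFF.
writeImageFile <- function(img, path) {
  assertImage(img)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  scaled <- clip255(round(img)) / 255
  ext <- tolower(tools::file_ext(path))
  ok <- switch(ext,
    png = {
      png::writePNG(scaled, path)
      TRUE
    },
    tif = ,
    tiff = {
      tiff::writeTIFF(scaled, path, bits.per.sample = 8L)
      TRUE
    },
    stopf("unsupported image format '%s' (use png or tiff): %s", ext, path))
  invisible(path)
}
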