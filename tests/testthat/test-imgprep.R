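test_that("tiling cuts the exact non-overlapping grid, row-major", {
  img <- array(runif(2048 * 2720 * 3, 0, 255), c(2048, 2720, 3))
  tiles <- tileSlide(img)
  expect_length(tiles, 4L)
  offs <- t(vapply(tiles, function(t) t$offset, integer(2)))
  expect_equal(offs, rbind(c(1L, 1L), c(1L, 1361L),
                           c(1025L, 1L), c(1025L, 1361L)))
  expect_equal(dim(tiles[[1]]$pixels), c(1024L, 1360L, 3L))
  # tile content matches the source block exactly
  expect_identical(tiles[[4]]$pixels,
                   img[1025:2048, 1361:2720, , drop = FALSE])
})

test_that("tiling edge cases: identity, floor division, too-small", {
  one <- array(1, c(1024, 1360, 3))
  tiles <- tileSlide(one)
  expect_length(tiles, 1L)
  expect_equal(tiles[[1]]$offset, c(1L, 1L))
  # 1100x1500: floor(1100/1024) * floor(1500/1360) = 1 tile
  expect_length(tileSlide(array(0, c(1100, 1500, 3))), 1L)
  expect_warning(small <- tileSlide(array(0, c(500, 500, 3))),
                 "smaller than one")
  expect_length(small, 0L)
})

test_that("tiles are pairwise disjoint and within source bounds", {
  set.seed(4)
  for (rep in 1:5) {
    H <- sample(60:400, 1)
    W <- sample(60:400, 1)
    th <- sample(20:70, 1)
    tw <- sample(20:70, 1)
    tiles <- suppressWarnings(
      tileSlide(array(0, c(H, W, 3)), tileHeight = th, tileWidth = tw))
    expect_length(tiles, (H %/% th) * (W %/% tw))
    if (!length(tiles)) next
    covered <- matrix(0L, H, W)
    for (t in tiles) {
      r <- t$offset[1]:(t$offset[1] + th - 1L)
      cc <- t$offset[2]:(t$offset[2] + tw - 1L)
      expect_true(max(r) <= H && max(cc) <= W)
      covered[r, cc] <- covered[r, cc] + 1L
    }
    expect_lte(max(covered), 1L)
  }
})

test_that("training augmentation yields 3 x nTrainPatches seeded patches", {
  img <- array(runif(1024 * 1360 * 3, 0, 255), c(1024, 1360, 3))
  cfg <- augmentationConfig(nTrainPatches = 10L, patchSize = 1000L)
  ps <- sampleTrainingPatches(img, cfg, seed = 5)
  expect_length(ps, 30L)
  expect_true(all(vapply(ps, function(p)
    all(dim(p$pixels) == c(1000, 1000, 3)), TRUE)))
  ps2 <- sampleTrainingPatches(img, cfg, seed = 5)
  expect_identical(lapply(ps, `[[`, "offset"), lapply(ps2, `[[`, "offset"))
  # offsets stay within bounds
  offs <- t(vapply(ps, function(p) p$offset, integer(2)))
  expect_true(all(offs[, 1] >= 1 & offs[, 1] <= 25))
  expect_true(all(offs[, 2] >= 1 & offs[, 2] <= 361))
})

test_that("patch-sized image forces all base offsets to the origin", {
  img <- array(runif(50 * 50 * 3, 0, 255), c(50, 50, 3))
  ps <- sampleTrainingPatches(img, augmentationConfig(nTrainPatches = 10L,
                                                      patchSize = 50L),
                              seed = 1)
  expect_length(ps, 30L)
  expect_true(all(vapply(ps, function(p) all(p$offset == 1L), TRUE)))
  grids <- unique(vapply(ps, function(p) paste(p$pixels, collapse = ","), ""))
  expect_lte(length(grids), 3L)
  expect_error(
    sampleTrainingPatches(array(0, c(40, 40, 3)),
                          augmentationConfig(patchSize = 50L)),
    "40x40.*50x50")
})

test_that("test patches follow the corner/centre scheme, always 15", {
  img <- array(runif(1024 * 1360 * 3, 0, 255), c(1024, 1360, 3))
  ps <- extractTestPatches(img, patchSize = 1000L)
  expect_length(ps, 15L)
  offs <- unique(t(vapply(ps, function(p) p$offset, integer(2))))
  expect_equal(offs, rbind(c(1L, 1L), c(1L, 361L), c(25L, 1L),
                           c(25L, 361L), c(13L, 181L)))
  expect_equal(vapply(ps, function(p) p$reflection, "")[1:3],
               c("none", "horizontal", "vertical"))
  # degenerate geometry: image equals the patch
  same <- extractTestPatches(array(runif(300, 0, 255), c(10, 10, 3)),
                             patchSize = 10L)
  expect_length(same, 15L)
  expect_length(unique(vapply(same, function(p)
    paste(p$pixels, collapse = ","), "")), 3L)
})

test_that("reflections are involutive and preserve the pixel multiset", {
  img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  ps <- extractTestPatches(img, patchSize = 64L)
  base <- ps[[1]]$pixels
  h <- ps[[2]]$pixels
  v <- ps[[3]]$pixels
  expect_identical(h[, 64:1, ], base)
  expect_identical(v[64:1, , ], base)
  expect_equal(sort(as.numeric(h)), sort(as.numeric(base)))
  expect_equal(sort(as.numeric(v)), sort(as.numeric(base)))
})

test_that("gamma correction follows the closed-form power law", {
  cfg <- augmentationConfig()
  px <- array(64, c(2, 2, 3))
  expect_equal(colorAugment(px, cfg, gamma = 2),
               array(round(255 * (64 / 255)^2), c(2, 2, 3)))  # 16
  expect_equal(colorAugment(px, cfg, gamma = 2)[1], 16)
  img <- array(runif(300, 0, 255), c(10, 10, 3))
  expect_equal(colorAugment(img, cfg, gamma = 1), round(img))
  expect_error(colorAugment(img, cfg, gamma = 0), "positive")
})

test_that("drawn gammas stay inside the configured range", {
  cfg <- augmentationConfig(gammaRange = c(0.5, 2.0))
  img <- array(128, c(4, 4, 3))
  p <- newPatchForTest <- structure(
    list(pixels = img, sourceId = "s", offset = c(1L, 1L),
         reflection = "none", gamma = NA_real_), class = "biopsyPatch")
  set.seed(10)
  gs <- replicate(1000, colorAugment(p, cfg)$gamma)
  expect_true(all(gs >= 0.5 & gs <= 2.0))
  expect_gt(max(gs), 1.8)  # the draw actually spans the range
  expect_lt(min(gs), 0.7)
})

test_that("gamma is monotone and round-trips with its inverse", {
  cfg <- augmentationConfig()
  ramp <- array(seq(0, 255, length.out = 256), c(256, 1, 3))
  for (g in c(0.5, 0.8, 1.7)) {
    out <- colorAugment(ramp, cfg, gamma = g)
    expect_true(all(diff(out[, 1, 1]) >= 0))
    back <- colorAugment(out, cfg, gamma = 1 / g)
    interior <- ramp > 20 & ramp < 235
    expect_lte(max(abs(back[interior] - round(ramp[interior]))), 1)
  }
})

test_that("CLAHE augmentation stays within the intensity range", {
  skip_if_not_installed("EBImage")
  cfg <- augmentationConfig(claheEnabled = TRUE)
  set.seed(2)
  img <- syntheticTissueImage(64, 64, blobDensity = 800)
  out <- colorAugment(img, cfg, gamma = 1.2)
  expect_true(all(out >= 0 & out <= 255))
  expect_equal(dim(out), dim(img))
})

test_that("image files round trip through PNG and TIFF", {
  td <- withr::local_tempdir()
  img <- round(array(runif(300, 0, 255), c(10, 10, 3)))
  for (ext in c("png", "tiff")) {
    p <- file.path(td, paste0("x.", ext))
    writeImageFile(img, p)
    expect_equal(readImageFile(p), img)
  }
})
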