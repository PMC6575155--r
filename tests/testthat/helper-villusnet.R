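# Shared fixtures: tiny network configurations, small synthetic cohorts and
# independent statistical oracles, all built in code at test time.

# Two-layer 12x12 network: fast enough for exhaustive gradient loops.
tinyConfig <- function(dropout = 0) {
  networkConfig(convMaps = c(2L, 3L), convKernels = c(3L, 3L),
                poolWindows = c(2L, 2L), inputSize = 12L, fcWidth = 8L,
                dropout = dropout)
}

# Full-depth but narrow network on 40x40 inputs (pools 2,2,2,5).
deepTinyConfig <- function(dropout = 0) {
  networkConfig(convMaps = c(2L, 2L, 2L, 2L), convKernels = c(3L, 3L, 3L, 3L),
                poolWindows = c(2L, 2L, 2L, 5L), inputSize = 40L,
                fcWidth = 6L, dropout = dropout)
}

randomImage <- function(side, seed = NULL, lo = 0, hi = 255) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(side * side * 3, lo, hi), c(side, side, 3))
}

# Class-banded intensity images: trivially separable without texture.
bandedImages <- function(n, side = 12) {
  lapply(seq_len(n), function(i) {
    cl <- (i - 1) %% 3
    array(runif(side * side * 3, cl * 90, cl * 90 + 70), c(side, side, 3))
  })
}

bandedLabels <- function(n) rep(tissueClasses(), length.out = n)

# Texture parameters that keep the three classes widely separated at a
# given image size (densities are per megapixel).
separableTexture <- function() {
  data.frame(class = tissueClasses(),
             blobDensity = c(125, 750, 2000),
             blobEcc = c(1.2, 1.8, 2.5),
             ridgeAmp = c(30, 15, 5))
}

smallCohort <- function(dir, nPerClass = 2, imagesPerCase = 2, side = 120,
                        seed = 7, hueShift = list(site1 = c(0, 0, 0)),
                        texture = separableTexture()) {
  generateCohort(cohortSpec(
    nCasesPerClass = nPerClass, imagesPerCase = imagesPerCase,
    imageHeight = side, imageWidth = side, classTextureParams = texture,
    siteHueShift = hueShift, seed = seed), dir)
}

# Independent Welch oracle: textbook unequal-variance two-sample statistic
# with a one-sided (greater) p value.
welchOracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = pt(t, df, lower.tail = FALSE))
}

# Independent receptive-field recurrence oracle.
rfOracle <- function(kernels, pools, uptoConv) {
  rf <- 1; jump <- 1
  for (l in seq_len(uptoConv)) {
    rf <- rf + (kernels[l] - 1) * jump
    if (l == uptoConv) break
    rf <- rf + (pools[l] - 1) * jump
    jump <- jump * pools[l]
  }
  list(rf = rf, jump = jump)
}

# Count dark connected components (simple blob-count oracle).
countBlobs <- function(img, threshold = 130) {
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  if (requireNamespace("EBImage", quietly = TRUE)) {
    max(EBImage::bwlabel(EBImage::Image(t(lum < threshold))))
  } else {
    # 4-connected flood count in plain R
    mask <- lum < threshold
    lab <- matrix(0L, nrow(mask), ncol(mask))
    nlab <- 0L
    for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
      if (!mask[i, j] || lab[i, j] != 0L) next
      nlab <- nlab + 1L
      queue <- list(c(i, j)); lab[i, j] <- nlab
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
              q[2] <= ncol(mask) && mask[q[1], q[2]] &&
              lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- nlab
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
    nlab
  }
}
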