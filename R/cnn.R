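#' Construct a network architecture
#'
#' Defaults describe the compact biopsy classifier: four convolution layers
#' with 16, 32, 32 and 32 feature maps, 5x5, 5x5, 5x5 and 3x3 kernels
#' (stride 1, zero-padded so spatial size is preserved), max-pooling windows
#' of 2, 4, 5 and 5 (pool stride equals the window, so the pools jointly
#' divide the spatial side by 200), a 1024-wide fully connected layer with
#' dropout 0.5, and a softmax over the three tissue classes. For a
#' 1000x1000x3 input the fourth convolution emits a 25x25x32 grid and the
#' fourth pool a 5x5x32 grid, giving a flattened fan-in of 800.
#'
#' @param convMaps integer feature maps per convolution layer.
#' @param convKernels integer odd kernel sides per layer.
#' @param poolWindows integer pool windows per layer.
#' @param inputSize spatial input side in pixels; must be divisible by
#'   `prod(poolWindows)`.
#' @param nChannels input channels.
#' @param fcWidth fully connected hidden width.
#' @param dropout dropout probability on the hidden layer.
#' @param nClasses number of output classes.
#' @return A [NetworkConfig-class] object.
#' @export
#' @examples
#' cfg <- networkConfig(inputSize = 200)
#' layerShapes(cfg)
networkConfig <- function(convMaps = c(16L, 32L, 32L, 32L),
                          convKernels = c(5L, 5L, 5L, 3L),
                          poolWindows = c(2L, 4L, 5L, 5L),
                          inputSize = 1000L, nChannels = 3L,
                          fcWidth = 1024L, dropout = 0.5, nClasses = 3L) {
  new("NetworkConfig",
      convMaps = as.integer(convMaps), convKernels = as.integer(convKernels),
      poolWindows = as.integer(poolWindows), inputSize = as.integer(inputSize),
      nChannels = as.integer(nChannels), fcWidth = as.integer(fcWidth),
      dropout = as.numeric(dropout), nClasses = as.integer(nClasses))
}

#' Layer shape arithmetic
#'
#' Spatial sides and channel counts through the network, plus the flattened
#' fan-in of the fully connected layer and per-layer parameter counts.
#' Convolutions preserve the spatial side (stride 1, same padding); each pool
#' divides it by its window.
#'
#' @param config a [NetworkConfig-class].
#' @return data.frame with one row per stage (`conv1`, `pool1`, ...) holding
#'   the output side, channel count, activation count, and parameter count;
#'   the fully connected fan-in is attached as attribute `fanIn`.
#' @export
layerShapes <- function(config) {
  stopifnot(is(config, "NetworkConfig"))
  side <- config@inputSize
  cin <- config@nChannels
  rows <- list()
  for (l in seq_along(config@convMaps)) {
    k <- config@convKernels[l]
    cout <- config@convMaps[l]
    rows[[length(rows) + 1L]] <- data.frame(
      layer = paste0("conv", l), side = side, channels = cout,
      activations = side^2 * cout, params = (k * k * cin + 1L) * cout)
    side <- side %/% config@poolWindows[l]
    rows[[length(rows) + 1L]] <- data.frame(
      layer = paste0("pool", l), side = side, channels = cout,
      activations = side^2 * cout, params = 0L)
    cin <- cout
  }
  fanIn <- side^2 * cin
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "fc", side = 1L, channels = config@fcWidth,
    activations = config@fcWidth, params = (fanIn + 1L) * config@fcWidth)
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "softmax", side = 1L, channels = config@nClasses,
    activations = config@nClasses,
    params = (config@fcWidth + 1L) * config@nClasses)
  out <- do.call(rbind, rows)
  attr(out, "fanIn") <- fanIn
  out
}

## NetworkConfig -> plain list for the C++ engine
cfgList <- function(config) {
  list(maps = config@convMaps, kernels = config@convKernels,
       pools = config@poolWindows, input_size = config@inputSize,
       n_channels = config@nChannels, fc_width = config@fcWidth,
       n_classes = config@nClasses, dropout = config@dropout)
}

#' Build an untrained model
#'
#' Allocates and seeds the layer weights (scaled normal initialisation with
#' variance 2/fan-in for the rectified layers, zero biases).
#'
#' @param config a [NetworkConfig-class].
#' @param seed integer initialisation seed.
#' @param classOrder character label order; defaults to [tissueClasses()].
#' @return An untrained [TissueCNN-class].
#' @export
#' @examples
#' m <- buildModel(networkConfig(inputSize = 200), seed = 1)
buildModel <- function(config, seed = 1L,
                       classOrder = tissueClasses()[seq_len(config@nClasses)]) {
  stopifnot(is(config, "NetworkConfig"))
  validObject(config)
  withSeed(childSeed(seed, 0L), {
    cin <- config@nChannels
    conv <- vector("list", length(config@convMaps))
    for (l in seq_along(config@convMaps)) {
      k <- config@convKernels[l]
      cout <- config@convMaps[l]
      fan <- k * k * cin
      conv[[l]] <- list(
        W = matrix(stats::rnorm(fan * cout, sd = sqrt(2 / fan)), fan, cout),
        b = numeric(cout))
      cin <- cout
    }
    fanIn <- attr(layerShapes(config), "fanIn")
    weights <- list(
      conv = conv,
      fc1 = list(W = matrix(stats::rnorm(fanIn * config@fcWidth,
                                         sd = sqrt(2 / fanIn)),
                            fanIn, config@fcWidth),
                 b = numeric(config@fcWidth)),
      fc2 = list(W = matrix(stats::rnorm(config@fcWidth * config@nClasses,
                                         sd = sqrt(1 / config@fcWidth)),
                            config@fcWidth, config@nClasses),
                 b = numeric(config@nClasses)))
    new("TissueCNN", config = config, weights = weights,
        classOrder = classOrder, trained = FALSE, seed = as.integer(seed),
        lossHistory = numeric())
  })
}

## Coerce a patch list (arrays or objects with $pixels) to a list of arrays.
patchPixels <- function(patches) {
  lapply(patches, function(p) {
    px <- if (is.list(p) && !is.null(p$pixels)) p$pixels else p
    assertImage(px, "patch")
    px
  })
}

#' Train the classifier
#'
#' Minibatch adaptive-moment gradient descent on the softmax cross-entropy,
#' with inverted dropout on the fully connected layer. Twenty epochs is the
#' default, deliberately short to limit overfitting on small cohorts. Runs
#' are deterministic for a fixed seed on fixed hardware/thread settings.
#'
#' @param model an untrained or trained [TissueCNN-class].
#' @param patches list of H x W x 3 arrays (0..255) or patch objects with a
#'   `$pixels` element, each matching the network input size.
#' @param labels character/factor class per patch, drawn from the model's
#'   class order.
#' @param epochs training epochs (default 20).
#' @param batchSize minibatch size.
#' @param learningRate adaptive-moment step size.
#' @param seed integer seed for shuffling and dropout.
#' @return The trained [TissueCNN-class] with `lossHistory` filled.
#' @export
trainModel <- function(model, patches, labels, epochs = 20L, batchSize = 32L,
                       learningRate = 1e-3, seed = model@seed) {
  stopifnot(is(model, "TissueCNN"))
  if (length(patches) == 0L) stopf("no training patches supplied")
  labels <- as.character(labels)
  if (length(labels) != length(patches))
    stopf("labels (%d) and patches (%d) differ in length",
          length(labels), length(patches))
  bad <- setdiff(unique(labels), model@classOrder)
  if (length(bad))
    stopf("unknown class label(s): %s", paste(bad, collapse = ", "))
  missing <- setdiff(model@classOrder, unique(labels))
  if (length(missing))
    stopf("class absent from training data: %s",
          paste(missing, collapse = ", "))
  y <- match(labels, model@classOrder)
  fit <- cpp_train(model@weights, cfgList(model@config), patchPixels(patches),
                   as.integer(y), as.integer(epochs), as.integer(batchSize),
                   learningRate, childSeed(seed, 1L))
  model@weights <- fit$weights
  model@lossHistory <- as.numeric(fit$loss)
  model@trained <- TRUE
  model@seed <- as.integer(seed)
  model
}

#' Patch-level class probabilities
#'
#' Deterministic forward pass (dropout off) returning the softmax triple.
#'
#' @param model a [TissueCNN-class].
#' @param patch H x W x 3 array (0..255) matching the network input size, or
#'   a patch object with `$pixels`.
#' @return Named numeric vector of class probabilities (sums to 1).
#' @export
predictPatch <- function(model, patch) {
  stopifnot(is(model, "TissueCNN"))
  px <- patchPixels(list(patch))
  p <- cpp_predict(model@weights, cfgList(model@config), px)
  stats::setNames(as.numeric(p[1L, ]), model@classOrder)
}

#' Image-level class probabilities
#'
#' Extracts the fixed 15-patch test layout (centre + 4 corners, each with
#' horizontal and vertical reflections) and averages the patch probability
#' triples. Geometrically duplicated patches (which arise when the image
#' equals the patch size) are forwarded once and weighted by multiplicity.
#'
#' @param model a [TissueCNN-class].
#' @param image H x W x 3 array (0..255), at least the input size in both
#'   dimensions.
#' @return Named numeric probability vector.
#' @export
predictImage <- function(model, image) {
  stopifnot(is(model, "TissueCNN"))
  assertImage(image)
  ps <- model@config@inputSize
  patches <- extractTestPatches(image, patchSize = ps)
  key <- vapply(patches, function(p)
    paste(p$offset[1], p$offset[2], p$reflection), "")
  uniq <- !duplicated(key)
  wts <- as.numeric(table(key)[key[uniq]])
  probs <- cpp_predict(model@weights, cfgList(model@config),
                       patchPixels(patches[uniq]))
  out <- colSums(probs * (wts / sum(wts)))
  stats::setNames(as.numeric(out), model@classOrder)
}

#' Case-level prediction
#'
#' Averages the image-level probability triples over all of a case's images
#' and assigns the argmax label; exact probability ties are broken towards
#' the earlier class in the model's class order.
#'
#' @param model a [TissueCNN-class].
#' @param images list of H x W x 3 arrays, or a list of precomputed
#'   image-level probability vectors (each summing to 1).
#' @return list with `probabilities` (named numeric) and `label` (character).
#' @export
predictCase <- function(model, images) {
  stopifnot(is(model, "TissueCNN"))
  if (length(images) == 0L) stopf("a case needs at least one image")
  triples <- lapply(images, function(x) {
    if (is.numeric(x) && !is.array(x)) x else predictImage(model, x)
  })
  probs <- colMeans(do.call(rbind, triples))
  label <- model@classOrder[which.max(probs)]
  list(probabilities = stats::setNames(as.numeric(probs), model@classOrder),
       label = label)
}

#' Layer activation grids
#'
#' Post-rectification activations of a convolution layer (`conv1` ..
#' `convL`) or its pooled output (`pool1` .. `poolL`) for one input. For the
#' default architecture and a 1000x1000 input, `conv4` is a 25x25x32 grid.
#'
#' @param model a [TissueCNN-class].
#' @param image H x W x 3 array matching the input size, or a patch object.
#' @param layer layer name.
#' @return numeric array rows x cols x feature maps.
#' @export
layerActivations <- function(model, image, layer = "conv4") {
  stopifnot(is(model, "TissueCNN"))
  L <- length(model@config@convMaps)
  valid <- c(paste0("conv", seq_len(L)), paste0("pool", seq_len(L)))
  if (!layer %in% valid)
    stopf("unknown layer '%s'; valid layers: %s", layer,
          paste(valid, collapse = ", "))
  px <- patchPixels(list(image))[[1L]]
  acts <- cpp_activations(model@weights, cfgList(model@config), px)
  acts[[layer]]
}

## Loss and analytic gradients (double precision, dropout off); used by the
## gradient-check property tests.
cnnGradients <- function(model, patch, label) {
  y <- match(label, model@classOrder)
  px <- patchPixels(list(patch))[[1L]]
  cpp_loss_grad(model@weights, cfgList(model@config), px, as.integer(y))
}

cnnLoss <- function(model, patch, label) {
  y <- match(label, model@classOrder)
  px <- patchPixels(list(patch))[[1L]]
  cpp_loss(model@weights, cfgList(model@config), px, as.integer(y))
}
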