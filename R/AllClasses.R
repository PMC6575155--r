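#' @import methods
NULL

#' Fixed tissue class order
#'
#' All labels in the package come from this three-level set, in this order:
#' healthy control, celiac disease (CD), environmental enteropathy (EE).
#' Argmax ties in case prediction are broken towards the earlier class.
#'
#' @return Character vector of the three class labels.
#' @export
#' @examples tissueClasses()
tissueClasses <- function() c("control", "CD", "EE")

#' Network architecture description
#'
#' Describes the compact four-layer convolutional classifier: per-layer
#' feature-map counts, square kernel sides (stride 1, zero "same" padding),
#' max-pooling windows (pool stride equals the window), one fully connected
#' hidden layer with dropout, and a softmax read-out over the tissue classes.
#' The spatial input side must be divisible by the product of the pool
#' windows (200 for the default pools 2, 4, 5, 5).
#'
#' @slot convMaps integer feature-map counts per convolution layer.
#' @slot convKernels integer odd kernel sides per layer.
#' @slot poolWindows integer pooling windows per layer.
#' @slot inputSize integer spatial input side in pixels.
#' @slot nChannels integer input channels (3 for RGB).
#' @slot fcWidth integer width of the fully connected hidden layer.
#' @slot dropout numeric dropout probability on the hidden layer.
#' @slot nClasses integer number of output classes.
#' @export
setClass("NetworkConfig", representation(
  convMaps = "integer", convKernels = "integer", poolWindows = "integer",
  inputSize = "integer", nChannels = "integer", fcWidth = "integer",
  dropout = "numeric", nClasses = "integer"
))

setValidity("NetworkConfig", function(object) {
  msgs <- character()
  L <- length(object@convMaps)
  if (L < 1) msgs <- c(msgs, "at least one convolution layer is required")
  if (length(object@convKernels) != L || length(object@poolWindows) != L)
    msgs <- c(msgs, "convMaps, convKernels and poolWindows must share length")
  if (any(object@convMaps < 1) || any(object@convKernels < 1) ||
      any(object@poolWindows < 1))
    msgs <- c(msgs, "all layer counts must be positive")
  if (any(object@convKernels %% 2 == 0))
    msgs <- c(msgs, "convolution kernels must be odd (same zero padding)")
  poolProd <- prod(object@poolWindows)
  if (length(object@inputSize) == 1 && object@inputSize %% poolProd != 0)
    msgs <- c(msgs, sprintf(
      "inputSize (%d) must be divisible by the product of pool windows (%d)",
      object@inputSize, poolProd))
  if (object@dropout < 0 || object@dropout >= 1)
    msgs <- c(msgs, "dropout must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Convolutional tissue classifier
#'
#' Holds the architecture, the layer weights, the fixed class order and the
#' training provenance (seed, per-epoch loss). Created untrained by
#' [buildModel()] and fitted by [trainModel()].
#'
#' @slot config a [NetworkConfig-class].
#' @slot weights list of layer weight arrays.
#' @slot classOrder character, fixed label order (see [tissueClasses()]).
#' @slot trained logical flag.
#' @slot seed integer seed used for weight initialisation / training.
#' @slot lossHistory numeric per-epoch mean training cross-entropy.
#' @export
setClass("TissueCNN", representation(
  config = "NetworkConfig", weights = "list", classOrder = "character",
  trained = "logical", seed = "integer", lossHistory = "numeric"
))

setValidity("TissueCNN", function(object) {
  if (length(object@classOrder) != object@config@nClasses)
    return("classOrder length must equal nClasses")
  TRUE
})

#' Cohort manifest
#'
#' One record per case: identifier, tissue class, acquisition site, and the
#' ordered image files belonging to the case. Synthetic cohorts additionally
#' carry the latent texture parameters that generated each case, persisted in
#' a sidecar next to the manifest so biomarker links are reproducible.
#'
#' @slot caseId character case identifiers (unique).
#' @slot classLabel character class per case, from [tissueClasses()].
#' @slot siteId character acquisition site per case.
#' @slot imagePaths list of character vectors of image paths per case,
#'   relative to `root`.
#' @slot latents data.frame of latent texture parameters per case (may have
#'   zero rows for real cohorts).
#' @slot root character directory that image paths are relative to.
#' @export
setClass("CohortManifest", representation(
  caseId = "character", classLabel = "character", siteId = "character",
  imagePaths = "list", latents = "data.frame", root = "character"
))

setValidity("CohortManifest", function(object) {
  msgs <- character()
  n <- length(object@caseId)
  if (anyDuplicated(object@caseId))
    msgs <- c(msgs, "case ids must be unique")
  if (length(object@classLabel) != n || length(object@siteId) != n ||
      length(object@imagePaths) != n)
    msgs <- c(msgs, "per-case slots must share length")
  bad <- setdiff(unique(object@classLabel), tissueClasses())
  if (length(bad))
    msgs <- c(msgs, paste0("unknown class label(s): ",
                           paste(bad, collapse = ", ")))
  if (nrow(object@latents) > 0 && nrow(object@latents) != n)
    msgs <- c(msgs, "latents must have one row per case")
  if (length(msgs)) msgs else TRUE
})

#' Case-preserving fold assignment
#'
#' Maps every case to exactly one of `k` folds, stratified by class so fold
#' sizes within a class differ by at most one. All images of a case share its
#' fold, so no case ever crosses the train/test boundary.
#'
#' @slot assignment data.frame with columns `case_id`, `class`, `fold`.
#' @slot k integer fold count.
#' @slot seed integer seed used for the shuffle.
#' @export
setClass("FoldAssignment", representation(
  assignment = "data.frame", k = "integer", seed = "integer"
))

setValidity("FoldAssignment", function(object) {
  a <- object@assignment
  if (!all(c("case_id", "class", "fold") %in% names(a)))
    return("assignment needs case_id, class and fold columns")
  if (anyDuplicated(a$case_id)) return("a case may appear in only one fold")
  if (any(a$fold < 1 | a$fold > object@k)) return("fold index out of range")
  TRUE
})

#' Cross-validation evaluation report
#'
#' Aggregate of a case-preserving k-fold run: per-image and per-case
#' accuracies, the screening false-negative rate, the case-level 3x3
#' confusion matrix (rows true, columns predicted, class order fixed), and
#' the per-fold breakdown.
#'
#' @slot perImageAccuracy numeric fraction in [0, 1].
#' @slot perCaseAccuracy numeric fraction in [0, 1].
#' @slot falseNegativeRate numeric fraction in [0, 1].
#' @slot confusion 3x3 integer matrix of case counts.
#' @slot perFold data.frame of per-fold metrics.
#' @slot imageResults data.frame of per-image truth/prediction.
#' @slot caseResults data.frame of per-case truth/prediction/probabilities.
#' @export
setClass("EvaluationReport", representation(
  perImageAccuracy = "numeric", perCaseAccuracy = "numeric",
  falseNegativeRate = "numeric", confusion = "matrix",
  perFold = "data.frame", imageResults = "data.frame",
  caseResults = "data.frame"
))

#' Case-level activation targets
#'
#' For one class of interest, the case-by-feature-map matrix of maximal
#' fourth-layer activations (maximum over all of a case's images of the
#' per-image grid maxima) plus the traced source-pixel segment behind every
#' (case, map) maximum.
#'
#' @slot values numeric matrix, rows = cases, columns = feature maps.
#' @slot segments list (per case) of lists (per map) of segment records.
#' @slot classLabel character scalar, the class the targets were built on.
#' @export
setClass("ActivationTargets", representation(
  values = "matrix", segments = "list", classLabel = "character"
))

setValidity("ActivationTargets", function(object) {
  if (any(object@values < 0)) return("activations must be nonnegative")
  if (length(object@segments) &&
      length(object@segments) != nrow(object@values))
    return("segments must align with the rows of values")
  TRUE
})

#' Sparse marker-to-activation model set
#'
#' One lasso model per feature map mapping standardized biomarkers to the
#' map's case-level activation target: an intercept + coefficient matrix on a
#' shared marker ordering, the selected penalty per map, and the
#' standardization parameters estimated on the training cases.
#'
#' @slot coefficients numeric matrix, (1 + markers) x maps; first row is the
#'   intercept.
#' @slot lambda numeric selected penalty per map.
#' @slot center,scale numeric standardization parameters per marker.
#' @slot markerNames character marker ordering shared by all models.
#' @export
setClass("LassoModelSet", representation(
  coefficients = "matrix", lambda = "numeric", center = "numeric",
  scale = "numeric", markerNames = "character"
))

setValidity("LassoModelSet", function(object) {
  if (nrow(object@coefficients) != length(object@markerNames) + 1L)
    return("coefficient rows must be 1 + number of markers")
  if (ncol(object@coefficients) != length(object@lambda))
    return("one penalty per model is required")
  if (any(object@lambda < 0)) return("penalties must be nonnegative")
  TRUE
})
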