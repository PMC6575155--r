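#' Number of cases in an object
#' @param x object with case records.
#' @return integer count.
#' @export
setGeneric("nCases", function(x) standardGeneric("nCases"))

#' Case identifiers
#' @param x object with case records.
#' @return character vector.
#' @export
setGeneric("caseIds", function(x) standardGeneric("caseIds"))

#' Class labels per case
#' @param x object with case records.
#' @return character vector.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname nCases
#' @export
setMethod("nCases", "CohortManifest", function(x) length(x@caseId))
#' @rdname caseIds
#' @export
setMethod("caseIds", "CohortManifest", function(x) x@caseId)
#' @rdname classLabels
#' @export
setMethod("classLabels", "CohortManifest", function(x) {
  stats::setNames(x@classLabel, x@caseId)
})
#' @rdname caseIds
#' @export
setMethod("caseIds", "ActivationTargets", function(x) rownames(x@values))

#' Accessors for fitted objects
#'
#' `netConfig()`, `modelWeights()`, `lossHistory()` and `classOrder()` read
#' the corresponding slots of a [TissueCNN-class]; `confusionMatrix()` reads
#' the case-level confusion matrix of an [EvaluationReport-class];
#' `activationValues()` reads the case-by-map matrix of an
#' [ActivationTargets-class]; `lassoCoefficients()` reads the
#' intercept+coefficient matrix of a [LassoModelSet-class].
#'
#' @param x the object.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("netConfig", function(x) standardGeneric("netConfig"))
#' @rdname accessors
#' @export
setMethod("netConfig", "TissueCNN", function(x) x@config)

#' @rdname accessors
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))
#' @rdname accessors
#' @export
setMethod("modelWeights", "TissueCNN", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))
#' @rdname accessors
#' @export
setMethod("lossHistory", "TissueCNN", function(x) x@lossHistory)

#' @rdname accessors
#' @export
setGeneric("classOrder", function(x) standardGeneric("classOrder"))
#' @rdname accessors
#' @export
setMethod("classOrder", "TissueCNN", function(x) x@classOrder)

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setMethod("confusionMatrix", "EvaluationReport", function(x) x@confusion)

#' @rdname accessors
#' @export
setGeneric("activationValues",
           function(x) standardGeneric("activationValues"))
#' @rdname accessors
#' @export
setMethod("activationValues", "ActivationTargets", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("lassoCoefficients",
           function(x) standardGeneric("lassoCoefficients"))
#' @rdname accessors
#' @export
setMethod("lassoCoefficients", "LassoModelSet", function(x) x@coefficients)

setMethod("show", "NetworkConfig", function(object) {
  cat("NetworkConfig:", length(object@convMaps), "conv layers\n")
  cat("  feature maps:", paste(object@convMaps, collapse = ", "), "\n")
  cat("  kernels:     ", paste(object@convKernels, collapse = ", "), "\n")
  cat("  pools:       ", paste(object@poolWindows, collapse = ", "), "\n")
  cat("  input:", object@inputSize, "x", object@inputSize, "x",
      object@nChannels, " fc:", object@fcWidth, " dropout:", object@dropout,
      " classes:", object@nClasses, "\n")
})

setMethod("show", "TissueCNN", function(object) {
  cat("TissueCNN (", if (object@trained) "trained" else "untrained", ")\n",
      sep = "")
  show(object@config)
  cat("  class order:", paste(object@classOrder, collapse = ", "), "\n")
  if (length(object@lossHistory))
    cat("  final training loss:",
        signif(utils::tail(object@lossHistory, 1), 4), "after",
        length(object@lossHistory), "epochs\n")
})

setMethod("show", "CohortManifest", function(object) {
  cat("CohortManifest:", nCases(object), "cases,",
      sum(lengths(object@imagePaths)), "images\n")
  print(table(class = object@classLabel, site = object@siteId))
})

setMethod("show", "FoldAssignment", function(object) {
  cat("FoldAssignment: k =", object@k, "over",
      nrow(object@assignment), "cases\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  cat("  per-image accuracy:", signif(object@perImageAccuracy, 4), "\n")
  cat("  per-case accuracy: ", signif(object@perCaseAccuracy, 4), "\n")
  cat("  false-negative rate:", signif(object@falseNegativeRate, 4), "\n")
  cat("  case confusion matrix (rows = true):\n")
  print(object@confusion)
})

setMethod("show", "ActivationTargets", function(object) {
  cat("ActivationTargets:", nrow(object@values), "cases x",
      ncol(object@values), "feature maps (class ", object@classLabel, ")\n",
      sep = "")
})

setMethod("show", "LassoModelSet", function(object) {
  nz <- colSums(object@coefficients[-1, , drop = FALSE] != 0)
  cat("LassoModelSet:", ncol(object@coefficients), "models over",
      length(object@markerNames), "markers;",
      "median nonzero coefficients:", stats::median(nz), "\n")
})
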