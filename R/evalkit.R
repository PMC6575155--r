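#' Case-preserving stratified folds
#'
#' Partitions cases into `k` folds, stratified by class: within each class
#' the shuffled cases are dealt round-robin, so per-class fold sizes differ
#' by at most one, and every image of a case inherits the case's fold.
#'
#' @param manifest a [CohortManifest-class].
#' @param k fold count (default 10).
#' @param seed shuffle seed.
#' @return A [FoldAssignment-class].
#' @export
makeCasePreservingFolds <- function(manifest, k = 10L, seed = 1L) {
  stopifnot(is(manifest, "CohortManifest"))
  k <- as.integer(k)
  counts <- table(manifest@classLabel)
  if (any(counts < k))
    stopf("k = %d exceeds the %d case(s) of class %s", k, min(counts),
          names(counts)[which.min(counts)])
  withSeed(seed, {
    ## deal shuffled cases class by class, continuing the fold cycle across
    ## classes: per-class fold sizes differ by <= 1 (stratification) and so
    ## do the fold totals (global balance)
    byClass <- split(seq_len(nCases(manifest)), manifest@classLabel)
    rows <- list()
    cursor <- 0L
    for (cl in names(byClass)) {
      ix <- byClass[[cl]][sample.int(length(byClass[[cl]]))]
      fold <- (cursor + seq_along(ix) - 1L) %% k + 1L
      cursor <- cursor + length(ix)
      rows[[cl]] <- data.frame(row = ix, fold = fold)
    }
    a <- do.call(rbind, rows)
    assignment <- data.frame(case_id = manifest@caseId[a$row],
                             class = manifest@classLabel[a$row],
                             fold = a$fold, row.names = NULL)
    assignment <- assignment[order(match(assignment$case_id,
                                         manifest@caseId)), ]
    rownames(assignment) <- NULL
    new("FoldAssignment", assignment = assignment, k = k,
        seed = as.integer(seed))
  })
}

#' Write / read a fold assignment
#' @param folds a [FoldAssignment-class].
#' @param path file path (tab-separated `case_id`, `class`, `fold`).
#' @return the path invisibly / the restored object.
#' @export
writeFolds <- function(folds, path) {
  utils::write.table(folds@assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeFolds
#' @param k,seed metadata for the restored object.
#' @export
readFolds <- function(path, k = max(df$fold), seed = NA_integer_) {
  df <- utils::read.delim(path)
  new("FoldAssignment", assignment = df, k = as.integer(k),
      seed = as.integer(seed))
}

#' Confusion matrix, accuracies and false-negative rate
#'
#' Counts the 3x3 confusion matrix over the fixed class order (rows true,
#' columns predicted), the accuracy (trace over total) and the screening
#' false-negative rate: diseased (CD or EE) observations predicted as
#' control, over diseased observations. `fnDenominator = "all"` divides by
#' all observations instead.
#'
#' @param truth,predicted equal-length character/factor label vectors.
#' @param classes class order.
#' @param fnDenominator `"diseased"` (default) or `"all"`.
#' @return list with `confusion`, `accuracy`, `falseNegativeRate`.
#' @export
#' @examples
#' aggregateMetrics(c("EE", "EE", "CD", "control"),
#'                  c("EE", "control", "CD", "control"))
aggregateMetrics <- function(truth, predicted, classes = tissueClasses(),
                             fnDenominator = c("diseased", "all")) {
  fnDenominator <- match.arg(fnDenominator)
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stopf("truth (%d) and predicted (%d) differ in length",
          length(truth), length(predicted))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    stopf("label(s) outside the class set: %s", paste(bad, collapse = ", "))
  confusion <- table(factor(truth, classes), factor(predicted, classes))
  confusion <- matrix(as.integer(confusion), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  accuracy <- sum(diag(confusion)) / max(1L, sum(confusion))
  diseased <- setdiff(classes, "control")
  fn <- sum(confusion[diseased, "control"])
  denom <- if (fnDenominator == "diseased") sum(confusion[diseased, ])
           else sum(confusion)
  list(confusion = confusion, accuracy = accuracy,
       falseNegativeRate = if (denom > 0) fn / denom else 0)
}

## Train a model on one set of cases and predict another; shared by the
## cross-validation driver and the intercountry transfer protocol.
trainAndPredict <- function(manifest, trainIds, testIds, netCfg, augCfg,
                            epochs, batchSize, learningRate, seed,
                            imageCache) {
  trainPatches <- list()
  trainLabels <- character()
  labels <- classLabels(manifest)
  for (id in trainIds) {
    for (img in imageCache(id)) {
      ps <- sampleTrainingPatches(img, augCfg, sourceId = id, seed = NULL)
      trainPatches <- c(trainPatches, ps)
      trainLabels <- c(trainLabels, rep(labels[[id]], length(ps)))
    }
  }
  model <- buildModel(netCfg, seed = seed)
  model <- trainModel(model, trainPatches, trainLabels, epochs = epochs,
                      batchSize = batchSize, learningRate = learningRate,
                      seed = seed)
  imageRows <- list()
  caseRows <- list()
  for (id in testIds) {
    probs <- lapply(imageCache(id), function(img) predictImage(model, img))
    for (j in seq_along(probs)) {
      imageRows[[length(imageRows) + 1L]] <- data.frame(
        case_id = id, image = j, true = labels[[id]],
        predicted = model@classOrder[which.max(probs[[j]])])
    }
    cs <- predictCase(model, probs)
    caseRows[[length(caseRows) + 1L]] <- data.frame(
      case_id = id, true = labels[[id]], predicted = cs$label,
      t(cs$probabilities))
  }
  list(images = do.call(rbind, imageRows), cases = do.call(rbind, caseRows))
}

#' Case-preserving cross-validation of the classifier
#'
#' For every fold: samples training patches from the training cases' images,
#' trains a fresh network, and predicts every test image (15-patch
#' probability mean) and test case (mean of its images' probability
#' triples). Reports aggregate per-image and per-case accuracy, the
#' case-level confusion matrix and false-negative rate, and the per-fold
#' breakdown. Deterministic for fixed folds and seed.
#'
#' @param manifest a [CohortManifest-class].
#' @param folds a [FoldAssignment-class] over the manifest's cases.
#' @param netConfig a [NetworkConfig-class]; its input size must match the
#'   augmentation patch size.
#' @param augConfig an [augmentationConfig()] controlling patch sampling.
#' @param epochs,batchSize,learningRate training settings per fold.
#' @param seed experiment seed (per-fold seeds derive from it).
#' @param verbose print per-fold progress.
#' @return An [EvaluationReport-class].
#' @export
runCrossValidation <- function(manifest, folds, netConfig,
                               augConfig = augmentationConfig(
                                 nTrainPatches = 1L,
                                 patchSize = netConfig@inputSize,
                                 reflections = FALSE),
                               epochs = 20L, batchSize = 32L,
                               learningRate = 1e-3, seed = 1L,
                               verbose = FALSE) {
  stopifnot(is(manifest, "CohortManifest"), is(folds, "FoldAssignment"))
  a <- folds@assignment
  if (!setequal(a$case_id, manifest@caseId))
    stopf("fold assignment does not cover the manifest's cases")
  cache <- new.env(parent = emptyenv())
  imageCache <- function(id) {
    if (is.null(cache[[id]])) cache[[id]] <- caseImages(manifest, id)
    cache[[id]]
  }
  labels <- classLabels(manifest)
  imageRes <- list()
  caseRes <- list()
  perFold <- list()
  for (f in seq_len(folds@k)) {
    testIds <- a$case_id[a$fold == f]
    trainIds <- a$case_id[a$fold != f]
    missing <- setdiff(tissueClasses(), unique(labels[trainIds]))
    if (length(missing))
      stopf("fold %d training set lacks class %s", f,
            paste(missing, collapse = ", "))
    res <- withSeed(childSeed(seed, 100L + f), {
      trainAndPredict(manifest, trainIds, testIds, netConfig, augConfig,
                      epochs, batchSize, learningRate,
                      childSeed(seed, 200L + f), imageCache)
    })
    mImg <- aggregateMetrics(res$images$true, res$images$predicted)
    mCase <- aggregateMetrics(res$cases$true, res$cases$predicted)
    res$images$fold <- f
    res$cases$fold <- f
    imageRes[[f]] <- res$images
    caseRes[[f]] <- res$cases
    perFold[[f]] <- data.frame(fold = f, nTestCases = length(testIds),
                               perImageAccuracy = mImg$accuracy,
                               perCaseAccuracy = mCase$accuracy)
    if (verbose)
      message(sprintf("fold %d/%d: image acc %.3f, case acc %.3f", f,
                      folds@k, mImg$accuracy, mCase$accuracy))
  }
  imageRes <- do.call(rbind, imageRes)
  caseRes <- do.call(rbind, caseRes)
  mImg <- aggregateMetrics(imageRes$true, imageRes$predicted)
  mCase <- aggregateMetrics(caseRes$true, caseRes$predicted)
  new("EvaluationReport",
      perImageAccuracy = mImg$accuracy, perCaseAccuracy = mCase$accuracy,
      falseNegativeRate = mCase$falseNegativeRate,
      confusion = mCase$confusion, perFold = do.call(rbind, perFold),
      imageResults = imageRes, caseResults = caseRes)
}

#' Intercountry leave-one-case-out transfer protocol
#'
#' Emulates the cross-site evaluation: with `n` cases of the class of
#' interest at site A, `n` models are trained, each omitting one site-A
#' case and adding a random allocation of control/CD cases; every model is
#' evaluated on all site-B cases of that class. Returns the 2 x n table of
#' per-image and per-case accuracies on site B.
#'
#' @param siteA a [CohortManifest-class] holding site A's cases of the
#'   class of interest (e.g. EE).
#' @param siteB a [CohortManifest-class] holding site B's cases of the same
#'   class, used only for evaluation.
#' @param sharedOther a [CohortManifest-class] holding the other-class
#'   (control/CD) cases available for random allocation.
#' @param netConfig,augConfig,epochs,batchSize,learningRate as in
#'   [runCrossValidation()].
#' @param allocPerClass other-class cases allocated to each model per class;
#'   default matches the site-A case count.
#' @param namedSubset optional site-A case ids: when given, one additional
#'   model is trained on exactly these cases of the class of interest (plus
#'   an other-class allocation) and evaluated on site B, appended as a
#'   `subset` column.
#' @param seed experiment seed; the random allocations derive from it and
#'   are recorded in the result's `allocations` attribute.
#' @return numeric matrix with rows `per_image`, `per_case` and one column
#'   per model.
#' @export
crossSiteTransfer <- function(siteA, siteB, sharedOther, netConfig,
                              augConfig = augmentationConfig(
                                nTrainPatches = 1L,
                                patchSize = netConfig@inputSize,
                                reflections = FALSE),
                              epochs = 20L, batchSize = 32L,
                              learningRate = 1e-3,
                              allocPerClass = NULL, namedSubset = NULL,
                              seed = 1L) {
  stopifnot(is(siteA, "CohortManifest"), is(siteB, "CohortManifest"),
            is(sharedOther, "CohortManifest"))
  n <- nCases(siteA)
  if (n < 2L) stopf("site A needs at least 2 cases, got %d", n)
  combined <- combineManifests(siteA, siteB, sharedOther)
  cache <- new.env(parent = emptyenv())
  imageCache <- function(id) {
    if (is.null(cache[[id]])) cache[[id]] <- caseImages(combined, id)
    cache[[id]]
  }
  otherByClass <- split(sharedOther@caseId, sharedOther@classLabel)
  if (is.null(allocPerClass)) allocPerClass <- n
  out <- matrix(NA_real_, 2L, n,
                dimnames = list(c("per_image", "per_case"),
                                paste0("model", seq_len(n))))
  allocations <- vector("list", n)
  for (i in seq_len(n)) {
    alloc <- withSeed(childSeed(seed, 300L + i), {
      unlist(lapply(otherByClass, function(ids)
        ids[sample.int(length(ids), min(allocPerClass, length(ids)))]),
        use.names = FALSE)
    })
    allocations[[i]] <- alloc
    trainIds <- c(setdiff(siteA@caseId, siteA@caseId[i]), alloc)
    res <- withSeed(childSeed(seed, 400L + i), {
      trainAndPredict(combined, trainIds, siteB@caseId, netConfig,
                      augConfig, epochs, batchSize, learningRate,
                      childSeed(seed, 500L + i), imageCache)
    })
    out["per_image", i] <-
      mean(res$images$true == res$images$predicted)
    out["per_case", i] <- mean(res$cases$true == res$cases$predicted)
  }
  if (!is.null(namedSubset)) {
    miss <- setdiff(namedSubset, siteA@caseId)
    if (length(miss))
      stopf("namedSubset contains unknown site-A case(s): %s",
            paste(miss, collapse = ", "))
    alloc <- withSeed(childSeed(seed, 600L), {
      unlist(lapply(otherByClass, function(ids)
        ids[sample.int(length(ids), min(allocPerClass, length(ids)))]),
        use.names = FALSE)
    })
    res <- withSeed(childSeed(seed, 601L), {
      trainAndPredict(combined, c(namedSubset, alloc), siteB@caseId,
                      netConfig, augConfig, epochs, batchSize,
                      learningRate, childSeed(seed, 602L), imageCache)
    })
    out <- cbind(out, subset = c(
      per_image = mean(res$images$true == res$images$predicted),
      per_case = mean(res$cases$true == res$cases$predicted)))
    allocations$subset <- alloc
  }
  attr(out, "allocations") <- allocations
  out
}

#' Combine cohort manifests
#'
#' Concatenates the case records of several manifests (case ids must stay
#' unique); image paths are rebased onto each source manifest's root.
#'
#' @param ... [CohortManifest-class] objects.
#' @return A combined [CohortManifest-class] with absolute image paths.
#' @export
combineManifests <- function(...) {
  ms <- list(...)
  paths <- list()
  for (m in ms) {
    stopifnot(is(m, "CohortManifest"))
    for (id in m@caseId)
      paths[[id]] <- file.path(m@root, m@imagePaths[[id]])
  }
  lat <- lapply(ms, function(m) m@latents)
  lat <- if (all(vapply(lat, nrow, 0L) > 0)) do.call(rbind, lat)
         else data.frame()
  new("CohortManifest",
      caseId = unlist(lapply(ms, caseIds), use.names = FALSE),
      classLabel = unlist(lapply(ms, function(m) m@classLabel),
                          use.names = FALSE),
      siteId = unlist(lapply(ms, function(m) m@siteId), use.names = FALSE),
      imagePaths = paths, latents = lat, root = "/")
}
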