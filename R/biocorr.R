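## Biomarker-activation correlation framework: case-level activation
## targets, one lasso model per feature map, clamped prediction, MSE
## evaluation, nearest-activation segment matching, and importance-guided
## backward feature elimination.

#' Build case-level activation targets
#'
#' For every case (optionally restricted to one class), computes the 32
#' per-feature-map activation targets: the maximum over all the case's
#' images of each image's final-convolution grid maximum. The source-pixel
#' segment behind each (case, map) maximum is traced and stored alongside.
#'
#' @param model a [TissueCNN-class].
#' @param manifest a [CohortManifest-class].
#' @param classLabel restrict to one class (e.g. `"EE"`); `NULL` uses all
#'   cases.
#' @param segmentSide traced crop side in pixels (default 142).
#' @return An [ActivationTargets-class].
#' @export
buildActivationTargets <- function(model, manifest, classLabel = "EE",
                                   segmentSide = 142L) {
  stopifnot(is(model, "TissueCNN"), is(manifest, "CohortManifest"))
  ids <- if (is.null(classLabel)) manifest@caseId
         else manifest@caseId[manifest@classLabel == classLabel]
  if (!length(ids)) stopf("no cases with class %s", classLabel)
  nMaps <- model@config@convMaps[length(model@config@convMaps)]
  values <- matrix(0, length(ids), nMaps,
                   dimnames = list(ids, paste0("map", seq_len(nMaps))))
  segments <- vector("list", length(ids))
  names(segments) <- ids
  for (i in seq_along(ids)) {
    imgs <- caseImages(manifest, ids[i])
    if (!length(imgs)) stopf("case %s has no images", ids[i])
    peaks <- lapply(imgs, function(img) imagePeaks(model, img))
    caseSegs <- vector("list", nMaps)
    for (m in seq_len(nMaps)) {
      vals <- vapply(peaks, function(p) p[[m]]$value, 0)
      j <- which.max(vals)  # earliest image wins exact ties
      seg <- peakToSegment(model, imgs[[j]], peaks[[j]][[m]], segmentSide,
                           sourceId = sprintf("%s_%02d", ids[i], j))
      seg$caseId <- ids[i]
      values[i, m] <- seg$value
      caseSegs[[m]] <- seg
    }
    segments[[i]] <- caseSegs
  }
  new("ActivationTargets", values = values, segments = segments,
      classLabel = classLabel %||% "all")
}

## Align a biomarker data.frame with target case ids -> numeric matrix.
markerMatrix <- function(markers, ids) {
  stopifnot(is.data.frame(markers), identical(names(markers)[1], "case_id"))
  if (anyDuplicated(markers$case_id)) stopf("duplicate case ids in markers")
  shared <- intersect(ids, markers$case_id)
  if (!length(shared))
    stopf("marker table and activation targets share no case ids")
  X <- as.matrix(markers[match(shared, markers$case_id), -1, drop = FALSE])
  if (anyNA(X))
    stopf("missing biomarker values for case(s): %s",
          paste(shared[rowSums(is.na(X)) > 0], collapse = ", "))
  rownames(X) <- shared
  X
}

#' Fit the per-map lasso model set
#'
#' One L1-penalized linear model per feature map, mapping standardized
#' biomarkers to the map's case-level activation target. Markers are
#' standardized with statistics from these (training) cases only; the
#' penalty is selected per map by inner cross-validation unless given
#' explicitly.
#'
#' @param markers data.frame with `case_id` first column.
#' @param targets an [ActivationTargets-class] (or a numeric case x map
#'   matrix with case-id rownames).
#' @param lambda explicit penalty (recycled per map); `NULL` selects by
#'   inner cross-validation.
#' @param nfolds inner cross-validation folds for penalty selection.
#' @param seed seed for the inner fold split.
#' @return A [LassoModelSet-class].
#' @export
fitLassoSet <- function(markers, targets, lambda = NULL, nfolds = 5L,
                        seed = 1L) {
  Y <- if (is(targets, "ActivationTargets")) targets@values else targets
  X <- markerMatrix(markers, rownames(Y))
  Y <- Y[rownames(X), , drop = FALSE]
  if (nrow(X) < 3L)
    stopf("at least 3 shared cases are required, got %d", nrow(X))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  nMaps <- ncol(Y)
  coefs <- matrix(0, ncol(X) + 1L, nMaps,
                  dimnames = list(c("(Intercept)", colnames(X)),
                                  colnames(Y)))
  lambdas <- numeric(nMaps)
  withSeed(seed, {
    for (m in seq_len(nMaps)) {
      if (ncol(Xs) == 1L) {
        # the L1 path needs >= 2 predictors; a single marker is plain OLS
        fit <- stats::lm.fit(cbind(1, Xs), Y[, m])
        coefs[, m] <- fit$coefficients
        lambdas[m] <- 0
        next
      }
      if (is.null(lambda)) {
        cv <- glmnet::cv.glmnet(Xs, Y[, m], alpha = 1,
                                nfolds = min(nfolds, nrow(Xs)),
                                standardize = FALSE)
        lambdas[m] <- cv$lambda.min
        cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
      } else {
        lam <- rep_len(lambda, nMaps)[m]
        fit <- glmnet::glmnet(Xs, Y[, m], alpha = 1,
                              standardize = FALSE)
        lambdas[m] <- lam
        cf <- as.matrix(stats::coef(fit, s = lam, exact = TRUE, x = Xs,
                                    y = Y[, m]))
      }
      coefs[, m] <- cf[, 1]
    }
  })
  new("LassoModelSet", coefficients = coefs, lambda = lambdas,
      center = ctr, scale = scl, markerNames = colnames(X))
}

#' Predict activations from biomarkers
#'
#' Linear prediction per feature map from a marker row (or table), using
#' the model set's stored standardization. Rectified activations are
#' nonnegative, so negative raw estimates are clamped to zero by default;
#' `negative = "keep"` returns the raw linear predictions.
#'
#' @param models a [LassoModelSet-class].
#' @param markers named numeric vector covering the model's markers, or a
#'   data.frame with `case_id` first column.
#' @param negative `"clamp"` (default) or `"keep"`.
#' @return numeric vector of per-map estimates (or a case x map matrix).
#' @export
predictActivations <- function(models, markers,
                               negative = c("clamp", "keep")) {
  negative <- match.arg(negative)
  stopifnot(is(models, "LassoModelSet"))
  if (is.data.frame(markers)) {
    X <- markerMatrix(markers, markers$case_id)
  } else {
    miss <- setdiff(models@markerNames, names(markers))
    if (length(miss))
      stopf("missing marker(s): %s", paste(miss, collapse = ", "))
    X <- matrix(markers[models@markerNames], 1,
                dimnames = list(NULL, models@markerNames))
  }
  miss <- setdiff(models@markerNames, colnames(X))
  if (length(miss))
    stopf("missing marker(s): %s", paste(miss, collapse = ", "))
  Xs <- scale(X[, models@markerNames, drop = FALSE],
              center = models@center, scale = models@scale)
  est <- cbind(1, Xs) %*% models@coefficients
  if (negative == "clamp") est[est < 0] <- 0
  if (nrow(est) == 1L && !is.data.frame(markers))
    stats::setNames(est[1, ], colnames(models@coefficients))
  else est
}

#' Mean squared error between estimated and actual activations
#'
#' Per case, the mean over feature maps of the squared estimate error;
#' reported as the mean over cases together with its spread. With a fold
#' assignment, the spread is the variance of per-fold mean MSEs (the
#' cross-validated summary); without, the variance over cases.
#'
#' @param estimated,actual aligned numeric matrices (cases x maps) or
#'   vectors for a single case.
#' @param folds optional integer fold id per case.
#' @return list with `perCase`, `mean`, `variance` and (with folds)
#'   `perFold`.
#' @export
evaluateActivationMSE <- function(estimated, actual, folds = NULL) {
  if (is.null(dim(estimated))) estimated <- matrix(estimated, 1)
  if (is.null(dim(actual))) actual <- matrix(actual, 1)
  if (!all(dim(estimated) == dim(actual)))
    stopf("estimated (%dx%d) and actual (%dx%d) are misaligned",
          nrow(estimated), ncol(estimated), nrow(actual), ncol(actual))
  perCase <- rowMeans((estimated - actual)^2)
  if (!is.null(folds)) {
    if (length(folds) != length(perCase))
      stopf("folds must have one entry per case")
    perFold <- tapply(perCase, folds, mean)
    list(perCase = perCase, mean = mean(perCase),
         variance = stats::var(as.numeric(perFold)),
         perFold = as.numeric(perFold))
  } else {
    list(perCase = perCase, mean = mean(perCase),
         variance = if (length(perCase) > 1) stats::var(perCase) else 0)
  }
}

#' Match estimates to nearest-activation training segments
#'
#' For each feature map, selects the training segment whose stored
#' activation value is closest (absolute difference) to the estimated
#' value; exact ties resolve to the earliest segment in the library. The
#' result is sorted by ascending absolute difference for reporting, and
#' carries the overall mean squared estimate-vs-matched difference.
#'
#' @param estimates numeric per-map estimates (e.g. from
#'   [predictActivations()]).
#' @param library an [ActivationTargets-class] holding the training
#'   segment library (its `segments` slot), or a list of per-map segment
#'   record lists.
#' @return list with `table` (map, estimate, matched value, source,
#'   absolute difference, sorted ascending), `segments` (matched records,
#'   same order) and `mse`.
#' @export
matchSegments <- function(estimates, library) {
  segLib <- if (is(library, "ActivationTargets")) {
    if (!length(library@segments)) stopf("segment library is empty")
    ## flatten per-case lists into per-map libraries, preserving insertion
    nMaps <- ncol(library@values)
    lapply(seq_len(nMaps), function(m)
      unlist(lapply(library@segments, function(cs) list(cs[[m]])),
             recursive = FALSE))
  } else library
  nMaps <- length(segLib)
  rows <- list()
  matched <- vector("list", nMaps)
  for (m in seq_len(nMaps)) {
    if (!length(segLib[[m]])) stopf("empty segment library for map %d", m)
    vals <- vapply(segLib[[m]], function(s) s$value, 0)
    diffs <- abs(vals - estimates[m])
    pick <- which.min(diffs)  # earliest wins on ties
    matched[[m]] <- segLib[[m]][[pick]]
    rows[[m]] <- data.frame(map = m, estimate = estimates[m],
                            matched = vals[pick],
                            source = matched[[m]]$sourceId %||% NA_character_,
                            absDiff = diffs[pick])
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$absDiff)
  list(table = tab[ord, ], segments = matched[ord],
       mse = mean((tab$estimate - tab$matched)^2))
}

## Cross-validated mean MSE of a lasso set restricted to a marker subset.
subsetCvMse <- function(markers, Y, subset, k, seed) {
  ids <- rownames(Y)
  n <- length(ids)
  folds <- withSeed(childSeed(seed, 17L),
                    rep_len(seq_len(min(k, n)), n)[sample.int(n)])
  sub <- markers[, c("case_id", subset), drop = FALSE]
  perCase <- numeric(n)
  for (f in unique(folds)) {
    trainIds <- ids[folds != f]
    testIds <- ids[folds == f]
    fit <- fitLassoSet(sub[sub$case_id %in% trainIds, , drop = FALSE],
                       Y[trainIds, , drop = FALSE],
                       nfolds = 3L, seed = childSeed(seed, 19L))
    est <- predictActivations(fit, sub[sub$case_id %in% testIds, ,
                                       drop = FALSE])
    perCase[folds == f] <-
      evaluateActivationMSE(est[testIds, , drop = FALSE],
                            Y[testIds, , drop = FALSE])$perCase
  }
  mean(perCase)
}

#' Importance-guided backward feature elimination
#'
#' Ranks biomarkers by random-forest permutation importance (one forest per
#' feature map, importances averaged), then removes the least important
#' marker one at a time, refitting the lasso set and recording the
#' cross-validated mean MSE at every subset size. Reports the curve and the
#' subset minimising it.
#'
#' @param markers data.frame with `case_id` first column.
#' @param targets an [ActivationTargets-class] or case x map matrix.
#' @param k outer cross-validation folds for the curve.
#' @param ntree random-forest size.
#' @param seed seed for forests and fold splits.
#' @return list with `curve` (data.frame: subset size, markers kept, MSE),
#'   `ranking` (markers, most important first) and `bestSubset`.
#' @export
importanceEliminationCurve <- function(markers, targets, k = 5L,
                                       ntree = 500L, seed = 1L) {
  Y <- if (is(targets, "ActivationTargets")) targets@values else targets
  X <- markerMatrix(markers, rownames(Y))
  Y <- Y[rownames(X), , drop = FALSE]
  markerNames <- colnames(X)
  if (length(markerNames) < 2L) {
    warnf("only one marker supplied; the elimination curve is a point")
  }
  imp <- withSeed(childSeed(seed, 23L), {
    per <- vapply(seq_len(ncol(Y)), function(m) {
      rf <- randomForest::randomForest(X, Y[, m], ntree = ntree,
                                       importance = TRUE)
      randomForest::importance(rf, type = 1)[, 1]
    }, numeric(ncol(X)))
    rowMeans(per)
  })
  ranking <- names(sort(imp, decreasing = TRUE))
  markers <- markers[, c("case_id", markerNames), drop = FALSE]
  keep <- ranking
  rows <- list()
  best <- NULL
  while (length(keep) >= 1L) {
    mse <- subsetCvMse(markers, Y, keep, k, childSeed(seed, length(keep)))
    rows[[length(rows) + 1L]] <- data.frame(
      size = length(keep), markers = paste(keep, collapse = ";"),
      mse = mse)
    if (is.null(best) || mse < best$mse)
      best <- list(markers = keep, mse = mse)
    keep <- keep[-length(keep)]  # drop current least important
  }
  curve <- do.call(rbind, rows)
  list(curve = curve, ranking = ranking, bestSubset = best$markers,
       bestMse = best$mse)
}
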