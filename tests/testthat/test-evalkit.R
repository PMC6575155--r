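# Build a manifest skeleton without images (folds/metrics don't read them).
stubManifest <- function(counts = c(control = 10, CD = 10, EE = 10)) {
  ids <- unlist(lapply(names(counts), function(cl)
    sprintf("%s%03d", toupper(substr(cl, 1, 3)), seq_len(counts[[cl]]))))
  classes <- rep(names(counts), counts)
  new("CohortManifest", caseId = ids, classLabel = classes,
      siteId = rep("site1", length(ids)),
      imagePaths = stats::setNames(as.list(paste0(ids, ".png")), ids),
      latents = data.frame(), root = ".")
}

test_that("folds partition the cases and stratify by class", {
  man <- stubManifest()
  folds <- makeCasePreservingFolds(man, k = 10, seed = 1)
  a <- folds@assignment
  expect_setequal(a$case_id, caseIds(man))
  expect_false(anyDuplicated(a$case_id) > 0)
  # 10 cases per class, 10 folds: exactly one case per class per fold
  tab <- table(a$class, a$fold)
  expect_true(all(tab == 1L))
  # train/test case sets never intersect
  for (f in 1:10)
    expect_length(intersect(a$case_id[a$fold == f],
                            a$case_id[a$fold != f]), 0L)
})

test_that("fold sizes stay balanced for uneven cohorts", {
  man <- stubManifest(c(control = 42, CD = 34, EE = 26))  # 102 cases
  folds <- makeCasePreservingFolds(man, k = 10, seed = 2)
  sizes <- table(folds@assignment$fold)
  expect_true(all(sizes %in% c(10L, 11L)))
  # within each class the fold sizes differ by at most one
  for (cl in tissueClasses()) {
    s <- table(folds@assignment$fold[folds@assignment$class == cl])
    expect_lte(max(s) - min(s), 1L)
  }
  expect_error(makeCasePreservingFolds(stubManifest(c(control = 3, CD = 10,
                                                      EE = 10)), k = 10),
               "exceeds")
})

test_that("fold assignments round trip through disk", {
  td <- withr::local_tempdir()
  folds <- makeCasePreservingFolds(stubManifest(), k = 5, seed = 3)
  p <- file.path(td, "folds.tsv")
  writeFolds(folds, p)
  back <- readFolds(p)
  expect_equal(back@assignment, folds@assignment)
  expect_equal(back@k, 5L)
})

test_that("aggregate metrics match hand-counted confusion", {
  m <- aggregateMetrics(c("EE", "EE", "CD", "control"),
                        c("EE", "control", "CD", "control"))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$falseNegativeRate, 1 / 3)
  expect_equal(m$confusion["EE", "EE"], 1L)
  expect_equal(m$confusion["EE", "control"], 1L)
  expect_equal(sum(m$confusion), 4L)
  perfect <- aggregateMetrics(rep(tissueClasses(), 2), rep(tissueClasses(), 2))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$falseNegativeRate, 0)
  expect_error(aggregateMetrics("EE", "bogus"), "outside the class set")
})

test_that("metrics agree with a brute-force recount oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    truth <- sample(tissueClasses(), n, replace = TRUE)
    pred <- sample(tissueClasses(), n, replace = TRUE)
    m <- aggregateMetrics(truth, pred)
    # loop oracle
    conf <- matrix(0L, 3, 3, dimnames = list(tissueClasses(),
                                             tissueClasses()))
    for (i in seq_len(n)) conf[truth[i], pred[i]] <- conf[truth[i],
                                                          pred[i]] + 1L
    expect_equal(unname(m$confusion), unname(conf))
    expect_equal(m$accuracy, sum(truth == pred) / n)
    dis <- truth %in% c("CD", "EE")
    expected_fn <- if (any(dis)) sum(pred[dis] == "control") / sum(dis) else 0
    expect_equal(m$falseNegativeRate, expected_fn)
    # row sums equal the class counts
    expect_equal(unname(rowSums(m$confusion)),
                 unname(as.integer(table(factor(truth, tissueClasses())))))
    # invariance to joint permutation
    p <- sample(n)
    expect_equal(aggregateMetrics(truth[p], pred[p]), m)
  }
})

test_that("the all-cases false-negative denominator is available", {
  m <- aggregateMetrics(c("EE", "CD", "control", "control"),
                        c("control", "CD", "control", "control"),
                        fnDenominator = "all")
  expect_equal(m$falseNegativeRate, 1 / 4)
})

test_that("cross-validation reports are complete and reproducible", {
  td <- withr::local_tempdir()
  man <- smallCohort(td, nPerClass = 3, imagesPerCase = 2, side = 48,
                     seed = 15)
  folds <- makeCasePreservingFolds(man, k = 3, seed = 1)
  ncfg <- networkConfig(convMaps = c(4L, 4L, 4L, 4L),
                        convKernels = c(3L, 3L, 3L, 3L),
                        poolWindows = c(2L, 2L, 2L, 3L), inputSize = 48L,
                        fcWidth = 16L, dropout = 0.25)
  rep1 <- runCrossValidation(man, folds, ncfg, epochs = 3, batchSize = 4,
                             seed = 8)
  expect_s4_class(rep1, "EvaluationReport")
  expect_equal(nrow(rep1@caseResults), 9L)
  expect_equal(nrow(rep1@imageResults), 18L)
  expect_equal(nrow(rep1@perFold), 3L)
  expect_true(all(rep1@perFold$perImageAccuracy >= 0 &
                    rep1@perFold$perImageAccuracy <= 1))
  expect_equal(sum(confusionMatrix(rep1)), 9L)
  expect_equal(unname(rowSums(confusionMatrix(rep1))), rep(3L, 3))
  # determinism: identical folds and seed give an identical report
  rep2 <- runCrossValidation(man, folds, ncfg, epochs = 3, batchSize = 4,
                             seed = 8)
  expect_equal(rep1@caseResults, rep2@caseResults)
  expect_equal(rep1@perImageAccuracy, rep2@perImageAccuracy)
})

test_that("cross-site transfer produces the per-model accuracy table", {
  tdA <- withr::local_tempdir()
  tdB <- withr::local_tempdir()
  tdO <- withr::local_tempdir()
  # site A and B share the texture distribution (no hue shift)
  manA <- smallCohort(tdA, nPerClass = 3, imagesPerCase = 1, side = 48,
                      seed = 21)
  manB0 <- smallCohort(tdB, nPerClass = 2, imagesPerCase = 1, side = 48,
                       seed = 22, hueShift = list(site2 = c(0, 0, 0)))
  siteA <- subsetCases(manA, caseIds(manA)[classLabels(manA) == "EE"])
  siteB <- subsetCases(manB0, caseIds(manB0)[classLabels(manB0) == "EE"])
  other <- subsetCases(manA, caseIds(manA)[classLabels(manA) != "EE"])
  # rename site-B cases to avoid id collisions in the combined manifest
  siteB@caseId <- paste0("ZB_", siteB@caseId)
  names(siteB@imagePaths) <- siteB@caseId
  rownames(siteB@latents) <- siteB@caseId
  ncfg <- networkConfig(convMaps = c(4L, 4L), convKernels = c(3L, 3L),
                        poolWindows = c(4L, 4L), inputSize = 48L,
                        fcWidth = 16L, dropout = 0)
  tab <- crossSiteTransfer(siteA, siteB, other, ncfg, epochs = 4,
                           batchSize = 4, seed = 5,
                           namedSubset = caseIds(siteA)[1:2])
  expect_equal(dim(tab), c(2L, 4L))
  expect_equal(rownames(tab), c("per_image", "per_case"))
  expect_equal(colnames(tab)[4], "subset")
  expect_true(all(tab >= 0 & tab <= 1))
  expect_length(attr(tab, "allocations"), 4L)
  expect_error(
    crossSiteTransfer(siteA, siteB, other, ncfg, epochs = 1,
                      namedSubset = "nope"), "unknown site-A")
  expect_error(crossSiteTransfer(subsetCases(siteA, caseIds(siteA)[1]),
                                 siteB, other, ncfg), "at least 2")
})
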