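test_that("generated cohort has the requested case and image counts", {
  td <- withr::local_tempdir()
  man <- smallCohort(td, nPerClass = 2, imagesPerCase = 3, side = 48)
  expect_equal(nCases(man), 6L)
  expect_equal(sum(lengths(man@imagePaths)), 18L)
  files <- list.files(file.path(td, "images"), pattern = "\\.png$")
  expect_length(files, 18L)
  expect_setequal(unique(man@classLabel), tissueClasses())
})

test_that("identical spec and seed reproduce the cohort byte for byte", {
  td1 <- withr::local_tempdir()
  td2 <- withr::local_tempdir()
  man1 <- smallCohort(td1, side = 48, seed = 3)
  man2 <- smallCohort(td2, side = 48, seed = 3)
  expect_identical(man1@caseId, man2@caseId)
  expect_identical(man1@latents, man2@latents)
  f1 <- list.files(file.path(td1, "images"), full.names = TRUE)
  f2 <- list.files(file.path(td2, "images"), full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  same <- mapply(function(a, b) identical(readBin(a, "raw", 1e6),
                                          readBin(b, "raw", 1e6)), f1, f2)
  expect_true(all(same))
})

test_that("empirical blob counts order the classes by density", {
  td <- withr::local_tempdir()
  man <- smallCohort(td, nPerClass = 2, imagesPerCase = 2, side = 512,
                     seed = 5,
                     texture = data.frame(class = tissueClasses(),
                                          blobDensity = c(20, 60, 120),
                                          blobEcc = c(1.2, 1.8, 2.5),
                                          ridgeAmp = c(10, 10, 10)))
  counts <- vapply(tissueClasses(), function(cl) {
    ids <- caseIds(man)[classLabels(man) == cl]
    mean(unlist(lapply(ids, function(id)
      vapply(caseImages(man, id), countBlobs, 0))))
  }, 0)
  expect_lt(counts[["control"]], counts[["CD"]])
  expect_lt(counts[["CD"]], counts[["EE"]])
})

test_that("a trivial blob-count classifier separates widely-spread classes", {
  td <- withr::local_tempdir()
  man <- smallCohort(td, nPerClass = 3, imagesPerCase = 2, side = 200,
                     seed = 9)
  counts <- lapply(caseIds(man), function(id)
    vapply(caseImages(man, id), countBlobs, 0))
  x <- unlist(counts)
  y <- rep(classLabels(man), times = lengths(counts))
  centers <- tapply(x, y, mean)
  pred <- names(centers)[apply(abs(outer(x, centers, "-")), 1, which.min)]
  expect_gte(mean(pred == y), 0.95)
})

test_that("invalid cohort specs name the offending fields", {
  expect_error(cohortSpec(nCasesPerClass = 0), "nCasesPerClass")
  expect_error(cohortSpec(imageHeight = 0), "imageHeight")
  expect_error(cohortSpec(siteHueShift = list(a = c(0, 0, 99))),
               "siteHueShift")
  bad <- data.frame(class = tissueClasses(), blobDensity = c(-1, 1, 1),
                    blobEcc = 1.5, ridgeAmp = 5)
  expect_error(cohortSpec(classTextureParams = bad), "classTextureParams")
})

test_that("hue-shifted pixels stay inside the 8-bit range", {
  set.seed(1)
  img <- syntheticTissueImage(64, 64, blobDensity = 500,
                              hueShift = c(30, -30, 30))
  expect_true(all(img >= 0 & img <= 255))
})

test_that("manifest write/read round trip preserves the cohort", {
  td <- withr::local_tempdir()
  man <- smallCohort(td, side = 48)
  path <- file.path(td, "roundtrip.tsv")
  writeManifest(man, path)
  back <- readManifest(path, root = td)
  expect_identical(back@caseId, man@caseId)
  expect_identical(back@classLabel, man@classLabel)
  expect_identical(back@siteId, man@siteId)
  expect_identical(unname(back@imagePaths), unname(man@imagePaths))
  expect_equal(back@latents, man@latents, tolerance = 1e-12)
})

test_that("malformed manifests raise parse errors, not empty objects", {
  td <- withr::local_tempdir()
  p <- file.path(td, "bad.tsv")
  writeLines(c("case_id\tclass\tsite\timages",
               "A\tEE\ts1\ta.png", "A\tCD\ts1\tb.png"), p)
  expect_error(readManifest(p), "duplicated case_id")
  writeLines(character(), p)
  expect_error(readManifest(p), "no data rows")
  writeLines(c("case_id\tclass\tsite\timages", "A\tEE\ts1"), p)
  expect_error(readManifest(p), "line 2")
})

test_that("zero-noise identity link reproduces the latents exactly", {
  td <- withr::local_tempdir()
  man <- smallCohort(td, side = 48)
  link <- biomarkerLinkSpec(c("m1", "m2", "m3"), diag(3), noiseSd = 0)
  bm <- generateBiomarkers(man, link)
  expect_equal(dim(bm), c(6L, 4L))
  expect_equal(bm$m1, man@latents$blobDensity, tolerance = 1e-12)
  expect_equal(bm$m2, man@latents$blobEcc, tolerance = 1e-12)
  expect_equal(bm$m3, man@latents$ridgeAmp, tolerance = 1e-12)
})

test_that("regression on noiseless markers recovers the link weights", {
  td <- withr::local_tempdir()
  man <- smallCohort(td, nPerClass = 4, imagesPerCase = 1, side = 32)
  W <- matrix(c(2, 0.5, -1, 0, 3, 1), 2, 3, byrow = TRUE)
  link <- biomarkerLinkSpec(c("mA", "mB"), W, noiseSd = 0)
  bm <- generateBiomarkers(man, link)
  L <- as.matrix(man@latents)
  for (j in 1:2) {
    fit <- lm.fit(cbind(1, L), bm[[j + 1]])
    expect_equal(unname(fit$coefficients[-1]), unname(W[j, ]),
                 tolerance = 1e-6)
  }
})

test_that("biomarker generation requires latents and matches dimensions", {
  td <- withr::local_tempdir()
  man <- smallCohort(td, nPerClass = 2, imagesPerCase = 1, side = 32)
  stripped <- man
  stripped@latents <- data.frame()
  link <- biomarkerLinkSpec(paste0("m", 1:5),
                            matrix(rnorm(15), 5, 3), noiseSd = 0.1)
  expect_error(generateBiomarkers(stripped, link), "re-generate")
  bm <- generateBiomarkers(man, link)
  expect_equal(dim(bm), c(6L, 6L))
  bm2 <- generateBiomarkers(man, link)
  expect_identical(bm, bm2)
})

test_that("biomarker table IO round trips through disk", {
  td <- withr::local_tempdir()
  tab <- data.frame(case_id = c("a", "b"), il9 = c(1.5, 2.5),
                    reg1 = c(-1, 0))
  p <- file.path(td, "bm.tsv")
  writeBiomarkers(tab, p)
  expect_equal(readBiomarkers(p), tab)
})

test_that("manifest subsetting keeps records aligned", {
  td <- withr::local_tempdir()
  man <- smallCohort(td, side = 48)
  ids <- caseIds(man)[c(3, 5)]
  sub <- subsetCases(man, ids)
  expect_identical(caseIds(sub), ids)
  expect_identical(unname(classLabels(sub)), man@classLabel[c(3, 5)])
  expect_equal(nrow(sub@latents), 2L)
  expect_error(subsetCases(man, "nope"), "unknown case")
})
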