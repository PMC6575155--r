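# Direct construction of a model set with known coefficients (identity
# standardization) for arithmetic checks.
plainModelSet <- function(coefs) {
  new("LassoModelSet", coefficients = coefs,
      lambda = numeric(ncol(coefs)),
      center = setNames(numeric(nrow(coefs) - 1L), rownames(coefs)[-1]),
      scale = setNames(rep(1, nrow(coefs) - 1L), rownames(coefs)[-1]),
      markerNames = rownames(coefs)[-1])
}

test_that("activation targets are elementwise maxima over case images", {
  td <- withr::local_tempdir()
  man <- smallCohort(td, nPerClass = 2, imagesPerCase = 3, side = 200,
                     seed = 31)
  det <- blobDetectorModel(networkConfig(inputSize = 200))
  tg <- buildActivationTargets(det, man, classLabel = "EE",
                               segmentSide = 31)
  expect_s4_class(tg, "ActivationTargets")
  expect_equal(dim(activationValues(tg)), c(2L, 32L))
  expect_true(all(activationValues(tg) >= 0))
  # row equals the elementwise max of the per-image maxima
  for (id in caseIds(tg)) {
    perImage <- t(vapply(caseImages(man, id), function(img) {
      apply(layerActivations(det, img, "conv4"), 3, max)
    }, numeric(32)))
    expect_equal(unname(activationValues(tg)[id, ]),
                 unname(apply(perImage, 2, max)), tolerance = 1e-6)
  }
  # single-image case: the row equals that image's maxima
  one <- subsetCases(man, caseIds(man)[classLabels(man) == "CD"][1])
  one@imagePaths[[1]] <- one@imagePaths[[1]][1]
  tg1 <- buildActivationTargets(det, one, classLabel = "CD",
                                segmentSide = 31)
  img1 <- caseImages(one, caseIds(one))[[1]]
  expect_equal(unname(activationValues(tg1)[1, ]),
               unname(apply(layerActivations(det, img1, "conv4"), 3, max)),
               tolerance = 1e-6)
})

test_that("the lasso set shrinks to the intercept at extreme penalty", {
  set.seed(3)
  n <- 12
  mk <- data.frame(case_id = sprintf("c%02d", 1:n),
                   a = rnorm(n), b = rnorm(n))
  Y <- matrix(rnorm(n * 4, mean = 5), n, 4,
              dimnames = list(mk$case_id, paste0("map", 1:4)))
  fit <- fitLassoSet(mk, Y, lambda = 1e6)
  expect_equal(unname(lassoCoefficients(fit)[-1, ]),
               matrix(0, 2, 4))
  expect_equal(unname(lassoCoefficients(fit)[1, ]),
               unname(colMeans(Y)), tolerance = 1e-8)
  expect_error(fitLassoSet(mk[1:2, ], Y[1:2, ]), "at least 3")
})

test_that("a noiseless single-marker signal is recovered within 5%", {
  set.seed(4)
  n <- 30
  mk <- data.frame(case_id = sprintf("c%02d", 1:n), s = rnorm(n),
                   n1 = rnorm(n), n2 = rnorm(n))
  Y <- matrix(2 * mk$s + 1, n, 3,
              dimnames = list(mk$case_id, paste0("map", 1:3)))
  fit <- fitLassoSet(mk, Y, lambda = 1e-4)
  # coefficients are on the standardized scale; undo it
  raw <- lassoCoefficients(fit)["s", ] / fit@scale[["s"]]
  expect_equal(unname(raw), rep(2, 3), tolerance = 0.05)
  others <- lassoCoefficients(fit)[c("n1", "n2"), ]
  expect_true(all(abs(others) < 0.1))
})

test_that("near-zero penalty reproduces least squares on full-rank data", {
  set.seed(5)
  n <- 40
  mk <- data.frame(case_id = sprintf("c%02d", 1:n), a = rnorm(n),
                   b = rnorm(n), c = rnorm(n))
  Y <- matrix(1 + 0.5 * mk$a - 2 * mk$b + 0.3 * mk$c + rnorm(n, sd = 0.01),
              n, 1, dimnames = list(mk$case_id, "map1"))
  fit <- fitLassoSet(mk, Y, lambda = 1e-8)
  X <- scale(as.matrix(mk[, -1]))
  ls <- lm.fit(cbind(1, X), Y[, 1])$coefficients
  expect_equal(unname(lassoCoefficients(fit)[, 1]), unname(ls),
               tolerance = 1e-4)
})

test_that("activation prediction is the clamped linear form", {
  coefs <- matrix(c(0.5, 1, -1), 3, 1,
                  dimnames = list(c("(Intercept)", "x", "y"), "map1"))
  ms <- plainModelSet(coefs)
  expect_equal(unname(predictActivations(ms, c(x = 2, y = 1))), 1.5)
  # negative raw estimate clamps to zero by default, survives with "keep"
  expect_equal(unname(predictActivations(ms, c(x = 0, y = 1))), 0)
  expect_equal(unname(predictActivations(ms, c(x = 0, y = 1),
                                         negative = "keep")), -0.5)
  # all-zero coefficients return the intercept for every map
  z <- plainModelSet(matrix(c(0.7, 0, 0), 3, 1,
                            dimnames = list(c("(Intercept)", "x", "y"),
                                            "map1")))
  expect_equal(unname(predictActivations(z, c(x = 9, y = -9))), 0.7)
  expect_error(predictActivations(ms, c(x = 1)), "missing marker.*y")
})

test_that("MSE evaluation matches a brute-force loop oracle", {
  est <- matrix(0, 1, 32)
  act <- matrix(0, 1, 32)
  expect_equal(evaluateActivationMSE(est, act)$mean, 0)
  act[1, 7] <- 1
  expect_equal(evaluateActivationMSE(est, act)$mean, 1 / 32)
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(2:8, 1); p <- sample(2:40, 1)
    e <- matrix(rnorm(n * p), n, p)
    a <- matrix(rnorm(n * p), n, p)
    res <- evaluateActivationMSE(e, a)
    oracle <- numeric(n)
    for (i in 1:n) {
      s <- 0
      for (j in 1:p) s <- s + (e[i, j] - a[i, j])^2
      oracle[i] <- s / p
    }
    expect_equal(unname(res$perCase), oracle, tolerance = 1e-12)
    expect_equal(res$mean, mean(oracle), tolerance = 1e-12)
  }
  expect_error(evaluateActivationMSE(matrix(0, 2, 3), matrix(0, 2, 4)),
               "misaligned")
})

test_that("fold-wise MSE summarises mean and fold variance", {
  e <- matrix(c(0, 0, 1, 1), 4, 8)
  a <- matrix(0, 4, 8)
  res <- evaluateActivationMSE(e, a, folds = c(1, 1, 2, 2))
  expect_equal(res$perFold, c(0, 1))
  expect_equal(res$mean, 0.5)
  expect_equal(res$variance, var(c(0, 1)))
})

test_that("clamping never hurts against nonnegative ground truth", {
  set.seed(7)
  for (rep in 1:20) {
    raw <- rnorm(32, mean = 0.3, sd = 1)
    act <- pmax(rnorm(32, 1), 0)
    clamped <- pmax(raw, 0)
    expect_lte(mean((clamped - act)^2), mean((raw - act)^2) + 1e-12)
  }
})

test_that("segment matching picks the nearest activation, earliest on tie", {
  lib <- list(list(
    list(value = 0.2, sourceId = "s1"),
    list(value = 0.6, sourceId = "s2"),
    list(value = 0.6, sourceId = "s3")))
  res <- matchSegments(0.5, lib)
  expect_equal(res$table$matched, 0.6)
  expect_equal(res$table$source, "s2")  # earliest of the tied entries
  expect_equal(res$table$absDiff, 0.1, tolerance = 1e-12)
  exact <- matchSegments(0.2, lib)
  expect_equal(exact$table$absDiff, 0)
  expect_equal(exact$mse, 0)
  expect_error(matchSegments(0.5, list(list())), "map 1")
})

test_that("matching returns one segment per map, sorted by difference", {
  set.seed(8)
  nMaps <- 32
  lib <- lapply(1:nMaps, function(m)
    lapply(1:5, function(i) list(value = runif(1, 0, 3),
                                 sourceId = sprintf("m%d_%d", m, i))))
  est <- runif(nMaps, 0, 3)
  res <- matchSegments(est, lib)
  expect_equal(nrow(res$table), nMaps)
  expect_setequal(res$table$map, 1:nMaps)
  expect_true(all(diff(res$table$absDiff) >= 0))
  # invariant to library shuffling away from ties
  perm <- lapply(lib, function(seglist) rev(seglist))
  res2 <- matchSegments(est, perm)
  expect_equal(res2$table[order(res2$table$map), "absDiff"],
               res$table[order(res$table$map), "absDiff"],
               tolerance = 1e-12)
})

test_that("elimination curve has one point per subset size", {
  set.seed(9)
  n <- 24
  mk <- data.frame(case_id = sprintf("c%02d", 1:n), a = rnorm(n),
                   b = rnorm(n), c = rnorm(n))
  Y <- matrix(2 * mk$a + rnorm(n, sd = 0.05), n, 6,
              dimnames = list(mk$case_id, paste0("map", 1:6)))
  ec <- importanceEliminationCurve(mk, Y, k = 3, ntree = 100, seed = 2)
  expect_equal(ec$curve$size, 3:1)
  expect_true(all(ec$curve$mse >= 0))
  expect_equal(ec$ranking[1], "a")  # the only informative marker ranks first
  expect_true("a" %in% ec$bestSubset)
})
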