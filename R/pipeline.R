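## Config-driven pipeline driver. The configuration is a nested list (or a
## YAML file with the same structure) with optional sections `synthgen`,
## `network`, `augment`, `training`, `evaluation` and `biomarkers`; unknown
## sections or keys are rejected so typos fail loudly. Every run writes the
## resolved configuration, the seed and a line-oriented log next to its
## outputs, so any artifact directory can be re-run exactly.

pipelineSections <- list(
  synthgen = c("nCasesPerClass", "imagesPerCase", "imageHeight",
               "imageWidth", "blobDensity", "blobEcc", "ridgeAmp",
               "siteHueShift", "latentJitter", "blobRadius", "noiseSd"),
  network = c("convMaps", "convKernels", "poolWindows", "inputSize",
              "fcWidth", "dropout"),
  augment = c("nTrainPatches", "patchSize", "gammaRange", "claheEnabled",
              "reflections", "gammaAugment"),
  training = c("epochs", "batchSize", "learningRate"),
  evaluation = c("folds"),
  biomarkers = c("markerNames", "linkWeights", "noiseSd"))

validatePipelineConfig <- function(config) {
  badSection <- setdiff(names(config), names(pipelineSections))
  if (length(badSection))
    stopf("unknown config section(s): %s",
          paste(badSection, collapse = ", "))
  for (s in names(config)) {
    badKey <- setdiff(names(config[[s]]), pipelineSections[[s]])
    if (length(badKey))
      stopf("unknown key(s) in section '%s': %s", s,
            paste(badKey, collapse = ", "))
  }
  invisible(config)
}

#' Run the end-to-end synthetic pipeline
#'
#' Generates a seeded synthetic cohort, trains and cross-validates the
#' classifier, and (when a `biomarkers` section is present) generates the
#' linked biomarker table and fits the per-map lasso set on the EE cases.
#' All artifacts (manifest, images, fold assignment, evaluation report
#' tables, resolved config, log) are written under `outDir`.
#'
#' @param config nested configuration list, or the path to a YAML file with
#'   the same structure. Unknown sections or keys are rejected.
#' @param outDir output directory.
#' @param seed global experiment seed.
#' @return list with the manifest, fold assignment, evaluation report, and
#'   (when configured) the biomarker table and lasso model set.
#' @export
runPipeline <- function(config = list(), outDir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validatePipelineConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "run.log")
  logLine <- function(level, msg) {
    cat(sprintf("[%s] %s %s\n", level,
                format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
        file = logPath, append = TRUE)
  }
  logLine("INFO", sprintf("villusnet %s, seed %d",
                          as.character(utils::packageVersion("villusnet")),
                          seed))
  sg <- config$synthgen %||% list()
  tex <- data.frame(class = tissueClasses(),
                    blobDensity = sg$blobDensity %||% c(20, 60, 120),
                    blobEcc = sg$blobEcc %||% c(1.2, 1.8, 2.5),
                    ridgeAmp = sg$ridgeAmp %||% c(30, 15, 5))
  spec <- cohortSpec(
    nCasesPerClass = sg$nCasesPerClass %||% 10L,
    imagesPerCase = sg$imagesPerCase %||% 5L,
    imageHeight = sg$imageHeight %||% 200L,
    imageWidth = sg$imageWidth %||% 200L,
    classTextureParams = tex,
    siteHueShift = sg$siteHueShift %||% list(site1 = c(0, 0, 0)),
    latentJitter = sg$latentJitter %||% 0.1,
    blobRadius = sg$blobRadius %||% 6,
    noiseSd = sg$noiseSd %||% 4,
    seed = childSeed(seed, 1L))
  logLine("INFO", "generating synthetic cohort")
  manifest <- generateCohort(spec, file.path(outDir, "cohort"))
  nw <- config$network %||% list()
  netCfg <- networkConfig(
    convMaps = nw$convMaps %||% c(16L, 32L, 32L, 32L),
    convKernels = nw$convKernels %||% c(5L, 5L, 5L, 3L),
    poolWindows = nw$poolWindows %||% c(2L, 4L, 5L, 5L),
    inputSize = nw$inputSize %||% (sg$imageHeight %||% 200L),
    fcWidth = nw$fcWidth %||% 1024L,
    dropout = nw$dropout %||% 0.5)
  au <- config$augment %||% list()
  augCfg <- augmentationConfig(
    nTrainPatches = au$nTrainPatches %||% 1L,
    patchSize = au$patchSize %||% netCfg@inputSize,
    gammaRange = au$gammaRange %||% c(0.5, 2.0),
    claheEnabled = au$claheEnabled %||% FALSE,
    reflections = au$reflections %||% FALSE,
    gammaAugment = au$gammaAugment %||% FALSE)
  tr <- config$training %||% list()
  ev <- config$evaluation %||% list()
  folds <- makeCasePreservingFolds(manifest, k = ev$folds %||% 10L,
                                   seed = childSeed(seed, 2L))
  writeFolds(folds, file.path(outDir, "folds.tsv"))
  logLine("INFO", sprintf("cross-validating: k = %d", folds@k))
  report <- runCrossValidation(
    manifest, folds, netCfg, augCfg,
    epochs = tr$epochs %||% 20L, batchSize = tr$batchSize %||% 32L,
    learningRate = tr$learningRate %||% 1e-3, seed = childSeed(seed, 3L))
  utils::write.table(report@caseResults,
                     file.path(outDir, "case_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report@imageResults,
                     file.path(outDir, "image_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summaryLines <- c(
    sprintf("per-image accuracy\t%.4f", report@perImageAccuracy),
    sprintf("per-case accuracy\t%.4f", report@perCaseAccuracy),
    sprintf("false-negative rate\t%.4f", report@falseNegativeRate))
  writeLines(summaryLines, file.path(outDir, "summary.tsv"))
  out <- list(manifest = manifest, folds = folds, report = report)
  if (!is.null(config$biomarkers)) {
    bm <- config$biomarkers
    link <- biomarkerLinkSpec(bm$markerNames,
                              matrix(unlist(bm$linkWeights),
                                     length(bm$markerNames), 3L,
                                     byrow = TRUE),
                              noiseSd = bm$noiseSd %||% 0,
                              seed = childSeed(seed, 4L))
    logLine("INFO", "generating biomarkers and fitting lasso set")
    biomarkers <- generateBiomarkers(manifest, link)
    writeBiomarkers(biomarkers, file.path(outDir, "biomarkers.tsv"))
    out$biomarkers <- biomarkers
  }
  resolved <- config
  resolved$seed <- seed
  yaml::write_yaml(resolved, file.path(outDir, "resolved_config.yaml"))
  logLine("INFO", "done")
  out
}
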