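## Synthetic cohort generation. Images are minimal texture analogues of
## H-E-stained duodenal tissue: a pinkish background, dark elliptical blobs
## standing in for secretory cells (class-specific density/eccentricity),
## sinusoidal intensity ridges standing in for villus structure, and a
## constant per-site RGB offset emulating inter-laboratory staining
## differences. They are test scaffolding for the pipeline's statistics,
## not biological renderings.

#' Synthetic cohort specification
#'
#' @param nCasesPerClass cases generated for each of the three classes.
#' @param imagesPerCase images per case.
#' @param imageHeight,imageWidth image size in pixels (default one slide
#'   frame, 1360 wide by 1024 high).
#' @param classTextureParams data.frame with columns `class`, `blobDensity`
#'   (dark blobs per megapixel), `blobEcc` (ellipse axis ratio >= 1) and
#'   `ridgeAmp` (sinusoidal band amplitude in intensity units); one row per
#'   class.
#' @param siteHueShift named list of per-site RGB offsets, each within
#'   \[-30, 30\] intensity units; cases are assigned to sites round-robin.
#' @param latentJitter relative spread of the per-case realization of the
#'   class texture means.
#' @param blobRadius base blob radius in pixels.
#' @param noiseSd per-pixel Gaussian background noise, intensity units.
#' @param seed integer generation seed; identical spec + seed reproduces the
#'   cohort byte for byte.
#' @return list of class `cohortSpec`.
#' @export
#' @examples
#' sp <- cohortSpec(nCasesPerClass = 2, imagesPerCase = 3,
#'                  imageHeight = 64, imageWidth = 64)
cohortSpec <- function(nCasesPerClass = 10L, imagesPerCase = 5L,
                       imageHeight = 1024L, imageWidth = 1360L,
                       classTextureParams = data.frame(
                         class = tissueClasses(),
                         blobDensity = c(20, 60, 120),
                         blobEcc = c(1.2, 1.8, 2.5),
                         ridgeAmp = c(30, 15, 5)),
                       siteHueShift = list(site1 = c(0, 0, 0)),
                       latentJitter = 0.1, blobRadius = 6, noiseSd = 4,
                       seed = 1L) {
  spec <- structure(list(
    nCasesPerClass = as.integer(nCasesPerClass),
    imagesPerCase = as.integer(imagesPerCase),
    imageHeight = as.integer(imageHeight),
    imageWidth = as.integer(imageWidth),
    classTextureParams = classTextureParams,
    siteHueShift = siteHueShift, latentJitter = latentJitter,
    blobRadius = blobRadius, noiseSd = noiseSd, seed = as.integer(seed)),
    class = "cohortSpec")
  validateCohortSpec(spec)
  spec
}

validateCohortSpec <- function(spec) {
  bad <- character()
  if (spec$nCasesPerClass < 1L) bad <- c(bad, "nCasesPerClass")
  if (spec$imagesPerCase < 1L) bad <- c(bad, "imagesPerCase")
  if (spec$imageHeight < 1L) bad <- c(bad, "imageHeight")
  if (spec$imageWidth < 1L) bad <- c(bad, "imageWidth")
  p <- spec$classTextureParams
  if (!all(c("class", "blobDensity", "blobEcc", "ridgeAmp") %in% names(p)) ||
      !setequal(p$class, tissueClasses()))
    bad <- c(bad, "classTextureParams")
  else if (any(p$blobDensity < 0) || any(p$blobEcc < 1) ||
           any(p$ridgeAmp < 0))
    bad <- c(bad, "classTextureParams")
  if (!length(spec$siteHueShift) || is.null(names(spec$siteHueShift)) ||
      any(vapply(spec$siteHueShift,
                 function(h) length(h) != 3 || any(abs(h) > 30), TRUE)))
    bad <- c(bad, "siteHueShift")
  if (length(bad))
    stopf("invalid cohort spec field(s): %s", paste(bad, collapse = ", "))
  invisible(spec)
}

## Fill one ellipse into an image array (bounding-box vectorized).
drawEllipse <- function(img, center, a, b, angle, colour) {
  H <- dim(img)[1]; W <- dim(img)[2]
  rmax <- ceiling(max(a, b))
  rows <- max(1, floor(center[1] - rmax)):min(H, ceiling(center[1] + rmax))
  cols <- max(1, floor(center[2] - rmax)):min(W, ceiling(center[2] + rmax))
  if (!length(rows) || !length(cols)) return(img)
  dy <- rows - center[1]
  dx <- cols - center[2]
  ca <- cos(angle); sa <- sin(angle)
  u <- outer(dy, dx, function(y, x) (x * ca + y * sa) / a)
  v <- outer(dy, dx, function(y, x) (-x * sa + y * ca) / b)
  inside <- u^2 + v^2 <= 1
  for (ch in 1:3) {
    block <- img[rows, cols, ch]
    block[inside] <- colour[ch]
    img[rows, cols, ch] <- block
  }
  img
}

#' Implant a single dark blob
#'
#' Draws one dark ellipse into an image; used to construct localization
#' fixtures for the activation traceback.
#'
#' @param image H x W x 3 array (0..255).
#' @param center numeric (row, col) blob centre.
#' @param radius base radius in pixels.
#' @param ecc axis ratio (>= 1).
#' @param angle orientation in radians.
#' @param colour RGB fill, 0..255.
#' @return The image with the blob drawn, plus attribute `blobBox`
#'   (rowMin, rowMax, colMin, colMax bounding box).
#' @export
implantBlob <- function(image, center, radius = 8, ecc = 1, angle = 0,
                        colour = c(70, 50, 90)) {
  assertImage(image)
  a <- radius * sqrt(ecc)
  b <- radius / sqrt(ecc)
  out <- drawEllipse(image, center, a, b, angle, colour)
  rmax <- max(a, b)
  attr(out, "blobBox") <- c(
    rowMin = max(1, floor(center[1] - rmax)),
    rowMax = min(dim(image)[1], ceiling(center[1] + rmax)),
    colMin = max(1, floor(center[2] - rmax)),
    colMax = min(dim(image)[2], ceiling(center[2] + rmax)))
  out
}

#' Generate one synthetic tissue image
#'
#' Pinkish noisy background, sinusoidal ridges of the given amplitude and
#' `blobDensity` dark ellipses per megapixel with axis ratio `blobEcc`,
#' followed by a constant per-channel hue shift (clipped to 0..255). Uses
#' the current RNG state; seed externally for reproducibility.
#'
#' @param height,width image size in pixels.
#' @param blobDensity dark blobs per megapixel.
#' @param blobEcc ellipse axis ratio (>= 1).
#' @param ridgeAmp ridge band amplitude in intensity units.
#' @param hueShift length-3 RGB offset.
#' @param blobRadius base blob radius in pixels.
#' @param noiseSd background noise standard deviation.
#' @return H x W x 3 array of 0..255 intensities.
#' @export
syntheticTissueImage <- function(height, width, blobDensity = 60,
                                 blobEcc = 1.5, ridgeAmp = 15,
                                 hueShift = c(0, 0, 0), blobRadius = 6,
                                 noiseSd = 4) {
  base <- c(232, 205, 215)
  img <- array(0, c(height, width, 3))
  theta <- stats::runif(1, 0, pi)
  phase <- stats::runif(1, 0, 2 * pi)
  wavelength <- stats::runif(1, 30, 60)
  rowIdx <- matrix(seq_len(height), height, width)
  colIdx <- matrix(seq_len(width), height, width, byrow = TRUE)
  ridge <- ridgeAmp * sin(2 * pi * (cos(theta) * colIdx +
                                    sin(theta) * rowIdx) / wavelength + phase)
  for (ch in 1:3)
    img[, , ch] <- base[ch] - ridge +
      stats::rnorm(height * width, sd = noiseSd)
  nBlobs <- max(0L, as.integer(round(blobDensity * height * width / 1e6)))
  if (nBlobs > 0) {
    centers <- cbind(stats::runif(nBlobs, 1, height),
                     stats::runif(nBlobs, 1, width))
    angles <- stats::runif(nBlobs, 0, pi)
    for (i in seq_len(nBlobs)) {
      shade <- c(70, 50, 90) + stats::rnorm(3, sd = 6)
      img <- drawEllipse(img, centers[i, ], blobRadius * sqrt(blobEcc),
                         blobRadius / sqrt(blobEcc), angles[i], shade)
    }
  }
  for (ch in 1:3) img[, , ch] <- img[, , ch] + hueShift[ch]
  clip255(round(img))
}

#' Generate a synthetic cohort on disk
#'
#' Realizes per-case latent texture parameters around the class means,
#' renders `imagesPerCase` images per case, writes them as 8-bit PNGs under
#' `outDir/images/`, and writes the manifest plus its latent-parameter
#' sidecar. Fully deterministic for a fixed spec and seed.
#'
#' @param spec a [cohortSpec()].
#' @param outDir output directory (created if needed).
#' @return A [CohortManifest-class] carrying the realized latents.
#' @export
generateCohort <- function(spec, outDir) {
  validateCohortSpec(spec)
  dir.create(file.path(outDir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(file.path(outDir, "images")) ||
      file.access(outDir, 2) != 0)
    stopf("output directory is not writable: %s", outDir)
  classes <- tissueClasses()
  sites <- names(spec$siteHueShift)
  p <- spec$classTextureParams
  withSeed(spec$seed, {
    caseId <- character()
    classLabel <- character()
    siteId <- character()
    imagePaths <- list()
    lat <- list()
    caseNo <- 0L
    for (cl in classes) {
      row <- p[p$class == cl, ]
      for (i in seq_len(spec$nCasesPerClass)) {
        caseNo <- caseNo + 1L
        id <- sprintf("%s%03d", toupper(substr(cl, 1, 3)), i)
        site <- sites[(caseNo - 1L) %% length(sites) + 1L]
        latent <- c(
          blobDensity = row$blobDensity *
            exp(stats::rnorm(1, sd = spec$latentJitter)),
          blobEcc = max(1, row$blobEcc *
                          exp(stats::rnorm(1, sd = spec$latentJitter))),
          ridgeAmp = max(0, row$ridgeAmp *
                           exp(stats::rnorm(1, sd = spec$latentJitter))))
        paths <- character(spec$imagesPerCase)
        for (k in seq_len(spec$imagesPerCase)) {
          img <- syntheticTissueImage(
            spec$imageHeight, spec$imageWidth,
            blobDensity = latent["blobDensity"],
            blobEcc = latent["blobEcc"], ridgeAmp = latent["ridgeAmp"],
            hueShift = spec$siteHueShift[[site]],
            blobRadius = spec$blobRadius, noiseSd = spec$noiseSd)
          rel <- file.path("images", sprintf("%s_%02d.png", id, k))
          writeImageFile(img, file.path(outDir, rel))
          paths[k] <- rel
        }
        caseId <- c(caseId, id)
        classLabel <- c(classLabel, cl)
        siteId <- c(siteId, site)
        imagePaths[[id]] <- paths
        lat[[id]] <- latent
      }
    }
    latents <- as.data.frame(do.call(rbind, lat))
    manifest <- new("CohortManifest", caseId = caseId,
                    classLabel = classLabel, siteId = siteId,
                    imagePaths = imagePaths, latents = latents,
                    root = normalizePath(outDir))
    writeManifest(manifest, file.path(outDir, "manifest.tsv"))
    manifest
  })
}

#' Biomarker link specification
#'
#' Declares how synthetic noninvasive biomarkers derive from the latent
#' texture parameters: a linear map plus independent Gaussian noise per
#' marker.
#'
#' @param markerNames character marker identifiers.
#' @param linkWeights numeric matrix, markers x latent parameters (columns
#'   `blobDensity`, `blobEcc`, `ridgeAmp`).
#' @param noiseSd nonnegative noise standard deviation, recycled per marker.
#' @param seed integer seed.
#' @return list of class `biomarkerLinkSpec`.
#' @export
biomarkerLinkSpec <- function(markerNames, linkWeights, noiseSd = 0,
                              seed = 1L) {
  linkWeights <- as.matrix(linkWeights)
  if (nrow(linkWeights) != length(markerNames))
    stopf("linkWeights must have one row per marker (%d markers, %d rows)",
          length(markerNames), nrow(linkWeights))
  if (ncol(linkWeights) != 3L)
    stopf("linkWeights needs 3 columns (blobDensity, blobEcc, ridgeAmp)")
  if (is.null(colnames(linkWeights)))
    colnames(linkWeights) <- c("blobDensity", "blobEcc", "ridgeAmp")
  noiseSd <- rep_len(as.numeric(noiseSd), length(markerNames))
  if (any(noiseSd < 0)) stopf("noiseSd must be nonnegative")
  structure(list(markerNames = as.character(markerNames),
                 linkWeights = linkWeights, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "biomarkerLinkSpec")
}

#' Generate a synthetic biomarker table
#'
#' One row per case: `marker = linkWeights %*% latent + noise`. Requires the
#' manifest to carry latent texture parameters (cohorts built by
#' [generateCohort()] do; re-generate the cohort if they are absent).
#'
#' @param manifest a [CohortManifest-class] with latents.
#' @param link a [biomarkerLinkSpec()].
#' @return data.frame with `case_id` and one column per marker.
#' @export
generateBiomarkers <- function(manifest, link) {
  stopifnot(is(manifest, "CohortManifest"),
            inherits(link, "biomarkerLinkSpec"))
  if (nrow(manifest@latents) == 0L)
    stopf(paste("manifest carries no latent texture parameters;",
                "re-generate the cohort with generateCohort()"))
  L <- as.matrix(manifest@latents[, colnames(link$linkWeights), drop = FALSE])
  withSeed(link$seed, {
    M <- L %*% t(link$linkWeights)
    noise <- matrix(stats::rnorm(length(M)), nrow(M), ncol(M)) *
      rep(link$noiseSd, each = nrow(M))
    M <- M + noise
    colnames(M) <- link$markerNames
    data.frame(case_id = manifest@caseId, M, row.names = NULL,
               check.names = FALSE)
  })
}

#' Write / read a cohort manifest
#'
#' Tab-separated with header `case_id class site images` (image paths
#' semicolon-joined, relative to the manifest directory). Latent texture
#' parameters, when present, are persisted in a `<path>.latents.tsv`
#' sidecar and restored on read.
#'
#' @param manifest a [CohortManifest-class].
#' @param path manifest file path.
#' @return `writeManifest` the path, invisibly; `readManifest` the restored
#'   [CohortManifest-class].
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "CohortManifest"))
  df <- data.frame(
    case_id = manifest@caseId, class = manifest@classLabel,
    site = manifest@siteId,
    images = vapply(manifest@imagePaths, paste, "", collapse = ";"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(manifest@latents) > 0) {
    lat <- cbind(case_id = manifest@caseId, manifest@latents)
    utils::write.table(lat, paste0(path, ".latents.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeManifest
#' @param root directory image paths are relative to; defaults to the
#'   manifest's directory.
#' @export
readManifest <- function(path, root = dirname(path)) {
  if (!file.exists(path)) stopf("manifest file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2L)
    stopf("manifest parse error: %s has no data rows", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("case_id", "class", "site", "images")))
    stopf("manifest parse error at line 1: expected header %s",
          "'case_id\tclass\tsite\timages'")
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L))
    stopf("manifest parse error at line %d: expected 4 fields, found %d",
          which(nf != 4L)[1] + 1L, nf[nf != 4L][1])
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- header
  if (anyDuplicated(df$case_id))
    stopf("manifest parse error: duplicated case_id '%s'",
          df$case_id[duplicated(df$case_id)][1])
  latPath <- paste0(path, ".latents.tsv")
  latents <- if (file.exists(latPath)) {
    lat <- utils::read.delim(latPath)
    out <- lat[, -1, drop = FALSE]
    rownames(out) <- lat$case_id
    out
  } else data.frame()
  new("CohortManifest", caseId = df$case_id, classLabel = df$class,
      siteId = df$site,
      imagePaths = stats::setNames(strsplit(df$images, ";", fixed = TRUE),
                                   df$case_id),
      latents = latents, root = normalizePath(root))
}

#' Write / read a biomarker table
#'
#' Tab-separated, first column `case_id`.
#' @param table data.frame with `case_id` first column.
#' @param path file path.
#' @return `writeBiomarkers` the path invisibly; `readBiomarkers` the
#'   data.frame.
#' @export
writeBiomarkers <- function(table, path) {
  stopifnot(identical(names(table)[1], "case_id"))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeBiomarkers
#' @export
readBiomarkers <- function(path) {
  if (!file.exists(path)) stopf("biomarker file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "case_id")
    stopf("biomarker parse error: first column must be case_id")
  if (anyDuplicated(df$case_id))
    stopf("biomarker parse error: duplicated case_id")
  df
}

#' Subset a manifest to selected cases
#'
#' @param manifest a [CohortManifest-class].
#' @param ids case identifiers to keep.
#' @return The restricted [CohortManifest-class].
#' @export
subsetCases <- function(manifest, ids) {
  stopifnot(is(manifest, "CohortManifest"))
  miss <- setdiff(ids, manifest@caseId)
  if (length(miss))
    stopf("unknown case id(s): %s", paste(miss, collapse = ", "))
  ix <- match(ids, manifest@caseId)
  new("CohortManifest", caseId = manifest@caseId[ix],
      classLabel = manifest@classLabel[ix], siteId = manifest@siteId[ix],
      imagePaths = manifest@imagePaths[ix],
      latents = if (nrow(manifest@latents)) manifest@latents[ix, ,
                                                             drop = FALSE]
                else data.frame(),
      root = manifest@root)
}

#' Load a case's images from disk
#'
#' @param manifest a [CohortManifest-class].
#' @param caseId one case identifier.
#' @return list of H x W x 3 arrays (0..255).
#' @export
caseImages <- function(manifest, caseId) {
  stopifnot(is(manifest, "CohortManifest"))
  if (!caseId %in% manifest@caseId) stopf("unknown case id '%s'", caseId)
  lapply(manifest@imagePaths[[caseId]],
         function(p) readImageFile(file.path(manifest@root, p)))
}
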