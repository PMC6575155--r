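#' Collect per-filter maximum activations
#'
#' Runs every image through the network and records, per image, the maximum
#' post-rectification activation of each final-convolution feature map (32
#' values for the default architecture). The sampling unit is the image, not
#' the patch, to limit pseudo-replication; pass patches explicitly for
#' patch-level sampling.
#'
#' @param model a [TissueCNN-class].
#' @param images list of H x W x 3 arrays matching the input size.
#' @param labels class label per image.
#' @param imageIds identifiers per image.
#' @return data.frame with `image_id`, `class` and one `map<j>` column per
#'   feature map; all activation values are nonnegative.
#' @export
collectMaxActivations <- function(model, images, labels,
                                  imageIds = paste0("image",
                                                    seq_along(images))) {
  stopifnot(is(model, "TissueCNN"))
  if (length(images) == 0L) stopf("at least one image is required")
  if (length(labels) != length(images))
    stopf("labels (%d) and images (%d) differ in length", length(labels),
          length(images))
  layer <- paste0("conv", length(model@config@convMaps))
  vals <- t(vapply(images, function(img) {
    acts <- layerActivations(model, img, layer)
    apply(acts, 3, max)
  }, numeric(model@config@convMaps[length(model@config@convMaps)])))
  colnames(vals) <- paste0("map", seq_len(ncol(vals)))
  data.frame(image_id = imageIds, class = as.character(labels), vals,
             row.names = NULL)
}

## Welch statistic for constant-variance edge cases handled explicitly.
welchOrConstant <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 0.5))
    return(list(t = if (mean(x) > mean(y)) Inf else -Inf,
                df = length(x) + length(y) - 2,
                p = if (mean(x) > mean(y)) 0 else 1))
  }
  ht <- stats::t.test(x, y, alternative = "greater", var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Per-filter class-activation tests
#'
#' For every feature map, a one-sided two-sample Welch test of the
#' hypothesis that the target class's maximum activations exceed those of
#' the pooled other classes (or of each other class separately with
#' `pairwise = TRUE`). A Holm step-down adjustment across the feature maps
#' is reported alongside the raw p values.
#'
#' @param samples data.frame from [collectMaxActivations()].
#' @param targetClass the class hypothesised to activate more strongly.
#' @param pairwise test against each other class separately instead of the
#'   pooled complement.
#' @param adjust multiple-testing adjustment method (see
#'   [stats::p.adjust()]).
#' @return data.frame with one row per feature map (per comparison when
#'   pairwise): `map`, `t`, `df`, `p`, `p_adj`, `n_target`, `n_rest`.
#' @export
perFilterClassTest <- function(samples, targetClass, pairwise = FALSE,
                               adjust = "holm") {
  stopifnot(is.data.frame(samples), "class" %in% names(samples))
  mapCols <- grep("^map[0-9]+$", names(samples), value = TRUE)
  if (!length(mapCols)) stopf("no map columns found in samples")
  inTarget <- samples$class == targetClass
  if (sum(inTarget) < 2L)
    stopf("need at least 2 samples in target class %s, got %d",
          targetClass, sum(inTarget))
  others <- if (pairwise) setdiff(unique(samples$class), targetClass)
            else "rest"
  out <- list()
  for (other in others) {
    inRest <- if (pairwise) samples$class == other else !inTarget
    if (sum(inRest) < 2L)
      stopf("need at least 2 samples in comparison group %s, got %d",
            other, sum(inRest))
    rows <- lapply(seq_along(mapCols), function(j) {
      x <- samples[[mapCols[j]]][inTarget]
      y <- samples[[mapCols[j]]][inRest]
      ht <- welchOrConstant(x, y)
      data.frame(map = j, comparison = other, t = ht$t, df = ht$df,
                 p = ht$p, n_target = length(x), n_rest = length(y))
    })
    df <- do.call(rbind, rows)
    df$p_adj <- stats::p.adjust(df$p, method = adjust)
    out[[other]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("map", "comparison", "t", "df", "p", "p_adj", "n_target",
          "n_rest")]
}
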