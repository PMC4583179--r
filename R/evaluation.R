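.asEdgeMatrix <- function(x) {
  if (is(x, "EdgeMap")) return(x@.Data)
  if (is(x, "Fixture")) return(x@truth@.Data)
  if (is.matrix(x)) return(edgeMap(x)@.Data)
  stop("expected an EdgeMap, Fixture or matrix")
}

#' Count false edge pixels
#'
#' A false edge pixel is a pixel flagged in `detected` that is absent from
#' the reference edge map. Inputs are coerced through [edgeMap()], so the
#' 1-pixel border frame never contributes. With `tolerance > 0` the
#' reference is first dilated by a square of that radius, forgiving detector
#' edge-thickness differences (off by default: strict pixel identity).
#'
#' @param detected,reference edge maps (or matrices) of identical shape.
#' @param tolerance dilation radius in pixels applied to the reference.
#' @return integer count of falsely flagged pixels.
#' @export
falseEdgeCount <- function(detected, reference, tolerance = 0L) {
  d <- .asEdgeMatrix(detected)
  r <- .asEdgeMatrix(reference)
  if (!identical(dim(d), dim(r)))
    stop("detected and reference maps must have the same shape")
  if (tolerance > 0L) r <- .dilateSquare(r, as.integer(tolerance))
  sum(d & !r)
}

#' Pixel-wise confusion metrics against a ground truth
#'
#' The 2x2 confusion table of detected versus true edge pixels and the
#' derived percentages: sensitivity = TP / (TP + FN), specificity =
#' TN / (TN + FP), both in percent.
#'
#' @param detected,truth edge maps (or matrices) of identical shape.
#' @return named list: `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`.
#' @export
confusionMetrics <- function(detected, truth) {
  d <- .asEdgeMatrix(detected)
  t <- .asEdgeMatrix(truth)
  if (!identical(dim(d), dim(t)))
    stop("detected and truth maps must have the same shape")
  tp <- sum(d & t); fp <- sum(d & !t)
  fn <- sum(!d & t); tn <- sum(!d & !t)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

## Run one detector (the fuzzy method or a named baseline) on an image.
.runDetector <- function(img, method, config, contrast, contrastCfg) {
  if (method == "fuzzy")
    detectEdges(img, config = config, contrast = contrast,
                contrastConfig = contrastCfg)
  else
    edgeBaseline(img, method)
}

#' Multi-detector noise-robustness comparison
#'
#' The quantitative comparison protocol: calibrate salt-and-pepper noise on
#' the clean image to a target PSNR, run every requested detector on the
#' noisy image, and count false edge pixels against a reference. The
#' reference is the analytic ground truth when supplied (synthetic
#' fixtures); otherwise each detector is compared against its own
#' clean-image output, matching the clean-versus-noisy narrative of the
#' protocol. When a truth map is available, sensitivity and specificity are
#' also reported.
#'
#' @param clean a [GreyImage-class], [Fixture-class] or numeric matrix. A
#'   Fixture supplies its own truth unless `truth` is given.
#' @param truth optional reference [EdgeMap-class].
#' @param targetDb target PSNR of the injected noise in dB.
#' @param detectors character vector from "fuzzy", "sobel", "prewitt",
#'   "roberts", "log", "canny".
#' @param seed integer seed for the noise (recorded in the report).
#' @param tolerance dilation radius passed to [falseEdgeCount()].
#' @param config a [DetectorConfig-class] for the fuzzy method.
#' @param contrast run the contrast pre-stage before the fuzzy detector.
#' @param contrastConfig a [ContrastConfig-class].
#' @return data.frame with one row per detector (`detector`, `falseEdges`,
#'   `edgePixels`, and when truth is available `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`); the realized [NoiseReport-class] is
#'   attached as attribute `"noise"`.
#' @examples
#' fx <- makeRainbow(width = 80, height = 60, bandHeight = 8)
#' runComparison(fx, targetDb = 25, detectors = c("fuzzy", "sobel"), seed = 1)
#' @export
runComparison <- function(clean, truth = NULL, targetDb = 25,
                          detectors = c("fuzzy", "sobel", "prewitt",
                                        "roberts", "log", "canny"),
                          seed = 1L, tolerance = 0L,
                          config = edgeDetectorConfig(), contrast = FALSE,
                          contrastConfig = defaultContrastConfig()) {
  if (is(clean, "Fixture") && is.null(truth)) truth <- clean@truth
  img <- .asGreyMatrix(clean)
  if (length(detectors)) {
    bad <- setdiff(detectors, c("fuzzy", "sobel", "prewitt", "roberts",
                                "log", "canny"))
    if (length(bad)) stop("unknown detector(s): ", paste(bad, collapse = ", "))
  }
  cal <- calibrateDensity(img, targetDb = targetDb, seed = seed)
  noisy <- cal$image

  rows <- lapply(detectors, function(det) {
    detMap <- .runDetector(noisy, det, config, contrast, contrastConfig)
    ref <- if (!is.null(truth)) truth
           else .runDetector(img, det, config, contrast, contrastConfig)
    row <- data.frame(detector = det,
                      falseEdges = falseEdgeCount(detMap, ref, tolerance),
                      edgePixels = edgeCount(detMap),
                      stringsAsFactors = FALSE)
    if (!is.null(truth)) {
      cm <- confusionMetrics(detMap, truth)
      row <- cbind(row, as.data.frame(cm))
    }
    row
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(detector = character(), falseEdges = integer(),
                         edgePixels = integer(), stringsAsFactors = FALSE)
  attr(out, "noise") <- cal$report
  out
}
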