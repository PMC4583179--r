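## Compass offsets in (row, col) matrix coordinates.
.compassOffsets <- list(NW = c(-1L, -1L), N = c(-1L, 0L), NE = c(-1L, 1L),
                        W  = c(0L, -1L),                  E  = c(0L, 1L),
                        SW = c(1L, -1L),  S = c(1L, 0L),  SE = c(1L, 1L))

## Row-major scan convention: P1=NW, P2=N, P3=NE, P4=W, P5=E, P6=SW, P7=S, P8=SE.
.defaultNeighborOrder <- c("NW", "N", "NE", "W", "E", "SW", "S", "SE")

#' Construct a GreyImage
#'
#' @param x numeric matrix of integer grey levels in `[0, 255]`, or a logical
#'   matrix (mapped to 0/255).
#' @return a [GreyImage-class].
#' @export
greyImage <- function(x) {
  if (is.logical(x)) x <- x * 255
  storage.mode(x) <- "double"
  new("GreyImage", x)
}

#' Clamp and round arbitrary intensities to valid grey levels
#'
#' @param x numeric matrix or vector.
#' @return values rounded to the nearest integer and clipped to `[0, 255]`.
#' @export
clampGrey <- function(x) pmin(pmax(round(x), 0), 255)

setMethod("show", "GreyImage", function(object) {
  v <- object@.Data
  cat(sprintf("GreyImage %d x %d, grey range [%d, %d]\n",
              nrow(v), ncol(v), as.integer(min(v)), as.integer(max(v))))
})

#' Construct an EdgeMap
#'
#' Coerces a logical (or numeric) matrix to a binary edge map, clearing the
#' 1-pixel border frame (border policy: the mask never reaches it).
#'
#' @param x matrix; nonzero / TRUE marks an edge pixel.
#' @return an [EdgeMap-class].
#' @export
edgeMap <- function(x) {
  v <- matrix(as.logical(x), nrow(x), ncol(x))
  m <- nrow(v); n <- ncol(v)
  if (m >= 1 && n >= 1) {
    v[c(1, m), ] <- FALSE
    v[, c(1, n)] <- FALSE
  }
  new("EdgeMap", v)
}

#' @describeIn edgeMap number of flagged pixels.
#' @export
edgeCount <- function(x) sum(x@.Data)

setMethod("show", "EdgeMap", function(object) {
  cat(sprintf("EdgeMap %d x %d, %d edge pixels\n",
              nrow(object@.Data), ncol(object@.Data), edgeCount(object)))
})

#' Configure the fuzzy edge detector
#'
#' Bundles the input/output fuzzy sets, the rule base, the defuzzification
#' universe, the binarization threshold and the neighbour scan convention.
#' Defaults reproduce the built-in profile: Lower/Higher trapezoids,
#' NonEdge/Edge Gaussians at 10/245 (width 3.5), the 12-rule base, a
#' 512-point universe and a threshold of 127.5 (midpoint of the two output
#' centres).
#'
#' @param inputSets,outputSets,rules,universe see [DetectorConfig-class].
#' @param threshold binarization cut on the crisp score.
#' @param neighborOrder compass labels assigning mask indices 1..8.
#' @return a [DetectorConfig-class].
#' @export
edgeDetectorConfig <- function(inputSets = edgeInputSets(),
                               outputSets = edgeOutputSets(),
                               rules = edgeRuleBase(),
                               universe = outputUniverse(),
                               threshold = 127.5,
                               neighborOrder = .defaultNeighborOrder) {
  new("DetectorConfig", inputSets = inputSets, outputSets = outputSets,
      rules = rules, universe = universe, threshold = threshold,
      neighborOrder = neighborOrder)
}

setMethod("show", "DetectorConfig", function(object) {
  cat(sprintf(paste0("DetectorConfig: %d rules, %d-point universe, ",
                     "threshold %g\n  neighbours: %s\n"),
              length(object@rules), object@universe@n, object@threshold,
              paste(object@neighborOrder, collapse = " ")))
})

#' Binarization threshold of a detector configuration
#' @param config a [DetectorConfig-class].
#' @export
edgeThreshold <- function(config) config@threshold

#' Rule base of a detector configuration
#' @param config a [DetectorConfig-class].
#' @export
ruleBase <- function(config) config@rules

.asGreyMatrix <- function(image) {
  if (is(image, "GreyImage")) return(image@.Data)
  if (is(image, "Fixture")) return(image@image@.Data)
  if (is.matrix(image) && is.numeric(image)) {
    if (anyNA(image) || any(image < 0 | image > 255) ||
        any(image != round(image)))
      stop("image must contain integer grey levels in [0, 255]")
    return(image)
  }
  stop("expected a GreyImage, Fixture or numeric matrix")
}

#' Extract the 3x3 difference neighbourhood at a pixel
#'
#' Returns the absolute differences dPj = |Pj - P| between each of the eight
#' neighbours and the centre pixel, ordered by the configured scan
#' convention.
#'
#' @param image a [GreyImage-class] or numeric matrix.
#' @param row,col 1-based interior coordinates (`2 <= row <= nrow - 1`).
#' @param neighborOrder compass labels for mask indices 1..8.
#' @return named numeric vector `dP1..dP8`.
#' @export
extractDeltas <- function(image, row, col,
                          neighborOrder = .defaultNeighborOrder) {
  img <- .asGreyMatrix(image)
  m <- nrow(img); n <- ncol(img)
  if (row < 2 || row > m - 1 || col < 2 || col > n - 1)
    stop("(row, col) must be an interior pixel; the mask is undefined on the border")
  p <- img[row, col]
  d <- vapply(neighborOrder, function(lab) {
    off <- .compassOffsets[[lab]]
    abs(img[row + off[1], col + off[2]] - p)
  }, 0)
  stats::setNames(d, paste0("dP", seq_len(8L)))
}

#' Crisp edge score of one difference neighbourhood
#'
#' Runs the full Mamdani pipeline on a single 8-vector of differences:
#' rule firing strengths (min t-norm), max aggregation with the implicit
#' else, and centroid defuzzification.
#'
#' @param deltas numeric vector of 8 differences in `[0, 255]`.
#' @param config a [DetectorConfig-class].
#' @return crisp grey level in the output universe.
#' @examples
#' cfg <- edgeDetectorConfig()
#' edgeScore(rep(0, 8), cfg)                        # ~10  (NonEdge centre)
#' edgeScore(c(255, 255, 0, 0, 0, 0, 0, 0), cfg)    # ~245 (rule 1 fires)
#' @export
edgeScore <- function(deltas, config = edgeDetectorConfig()) {
  stopifnot(length(deltas) == 8L, all(deltas >= 0), all(deltas <= 255))
  strengths <- vapply(config@rules, firingStrength, 0,
                      deltas = deltas, inputSets = config@inputSets)
  inferDefuzzify(strengths, config@rules, config@outputSets, config@universe)
}

#' Per-pixel crisp edge scores of an image
#'
#' Vectorized scan of all interior pixels. Border pixels, where the 3x3 mask
#' is undefined, receive `NA`.
#'
#' @param image a [GreyImage-class] or numeric matrix, at least 3x3.
#' @param config a [DetectorConfig-class].
#' @return numeric matrix of scores, same shape as the image.
#' @export
edgeScores <- function(image, config = edgeDetectorConfig()) {
  img <- .asGreyMatrix(image)
  m <- nrow(img); n <- ncol(img)
  if (m < 3 || n < 3)
    stop("image must be at least 3x3 for the window mask")
  ri <- 2:(m - 1); ci <- 2:(n - 1)
  p <- img[ri, ci, drop = FALSE]
  npix <- length(p)

  deltas <- lapply(config@neighborOrder, function(lab) {
    off <- .compassOffsets[[lab]]
    as.vector(abs(img[ri + off[1], ci + off[2], drop = FALSE] - p))
  })

  memb <- list()
  degOf <- function(lab, j) {
    key <- paste0(lab, ".", j)
    val <- memb[[key]]
    if (is.null(val)) {
      val <- memberDegree(config@inputSets[[lab]], deltas[[j]])
      memb[[key]] <<- val
    }
    val
  }
  strengths <- lapply(config@rules, function(rule) {
    idx <- as.integer(names(rule@antecedents))
    Reduce(pmin, mapply(degOf, rule@antecedents, idx, SIMPLIFY = FALSE))
  })

  cons <- vapply(config@rules, function(r) r@consequent, "")
  labs <- names(config@outputSets)
  agg <- lapply(labs, function(lab) {
    hit <- which(cons == lab)
    if (length(hit)) Reduce(pmax, strengths[hit]) else rep(0, npix)
  })
  names(agg) <- labs
  if ("NonEdge" %in% labs) {
    els <- 1 - Reduce(pmax, strengths)
    agg[["NonEdge"]] <- pmax(agg[["NonEdge"]], els)
  }

  scores <- .centroidVec(agg, config@outputSets, config@universe)
  out <- matrix(NA_real_, m, n)
  out[ri, ci] <- matrix(scores, length(ri), length(ci))
  out
}

## Scores within this margin of the threshold count as at-threshold and are
## flagged, so exactly symmetric aggregates (score 127.5) binarize
## deterministically regardless of floating-point summation order.
.thresholdTol <- 1e-9

#' Detect edges with the fuzzy 3x3 mask
#'
#' Scans the image with the difference mask, runs the 12-rule Mamdani system
#' per pixel and flags interior pixels whose crisp score reaches the
#' binarization threshold. Optionally applies the fuzzy contrast
#' intensification stage first (the smooth-image pipeline).
#'
#' @param image a [GreyImage-class], [Fixture-class] or numeric matrix,
#'   at least 3x3.
#' @param config a [DetectorConfig-class].
#' @param contrast if `TRUE`, run [adjustContrast()] before detection.
#' @param contrastConfig a [ContrastConfig-class] for the pre-stage.
#' @return an [EdgeMap-class] of the same shape as the image.
#' @examples
#' fx <- makeStep(16, 16)
#' detectEdges(fx)
#' @export
detectEdges <- function(image, config = edgeDetectorConfig(),
                        contrast = FALSE,
                        contrastConfig = defaultContrastConfig()) {
  img <- .asGreyMatrix(image)
  if (isTRUE(contrast))
    img <- adjustContrast(img, contrastConfig)@.Data
  scores <- edgeScores(img, config)
  flags <- !is.na(scores) & scores >= config@threshold - .thresholdTol
  edgeMap(flags)
}
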