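## Deterministic synthetic images with analytic ground truth, standing in
## for the unavailable rainbow / clinical test images of the evaluation
## protocol.

.fixture <- function(name, img, truth, params)
  new("Fixture", name = name, image = greyImage(img),
      truth = edgeMap(truth), params = params)

setMethod("show", "Fixture", function(object) {
  cat(sprintf("Fixture \"%s\": %d x %d, %d truth edge pixels\n",
              object@name, nrow(object@image@.Data), ncol(object@image@.Data),
              edgeCount(object@truth)))
})

## Mark both sides of every 4-neighbour intensity discontinuity of a
## piecewise-constant image (the border frame is cleared by edgeMap()).
.discontinuityTruth <- function(img) {
  m <- nrow(img); n <- ncol(img)
  tr <- matrix(FALSE, m, n)
  if (m > 1) {
    dv <- img[-m, , drop = FALSE] != img[-1, , drop = FALSE]
    tr[-m, ][dv] <- TRUE
    tr[-1, ][dv] <- TRUE
  }
  if (n > 1) {
    dh <- img[, -n, drop = FALSE] != img[, -1, drop = FALSE]
    tr[, -n][dh] <- TRUE
    tr[, -1][dh] <- TRUE
  }
  tr
}

#' Banded "rainbow" test image
#'
#' Five (by default) full-width horizontal stripes of distinct grey levels,
#' vertically centred on a uniform background: six horizontal interfaces,
#' whose truth map has exactly six straight 8-connected components. The
#' default geometry (314 wide x 192 high, read as width x height) and the
#' "five regions, six boundary lines" structure emulate the banded test
#' image of the evaluation protocol.
#'
#' @param width,height image size in pixels (columns x rows).
#' @param bands number of stripes.
#' @param bandHeight stripe height in rows; `bands * bandHeight <= height`.
#' @param levels stripe grey levels, one per band, each contrasting with its
#'   vertical neighbours by at least 25 grey levels (the foot of the Higher
#'   membership). Default for 5 bands: 30, 80, 130, 55, 105 on background
#'   200 (interface contrasts >= 50).
#' @param background background grey level.
#' @return a [Fixture-class].
#' @examples
#' fx <- makeRainbow()
#' componentCount(fx@truth)   # 6
#' @export
makeRainbow <- function(width = 314, height = 192, bands = 5,
                        bandHeight = 20, levels = NULL, background = 200) {
  if (is.null(levels))
    levels <- if (bands == 5) c(30, 80, 130, 55, 105)
              else rep_len(c(30, 110), bands)
  stopifnot(length(levels) == bands, bands >= 1,
            bands * bandHeight <= height)
  if (any(levels < 0 | levels > 255))
    stop("stripe levels must be grey levels in [0, 255]")
  adj <- abs(diff(c(if (bands * bandHeight < height) background, levels,
                    if (bands * bandHeight < height) background)))
  if (any(adj < 25))
    stop("adjacent stripe/background contrasts must be at least 25 grey levels")
  img <- matrix(background, height, width)
  top <- floor((height - bands * bandHeight) / 2)
  for (b in seq_len(bands))
    img[top + ((b - 1) * bandHeight + 1):(b * bandHeight), ] <- levels[b]
  .fixture("rainbow", img, .discontinuityTruth(img),
           list(width = width, height = height, bands = bands,
                bandHeight = bandHeight, levels = levels,
                background = background))
}

#' Ideal step-edge test image
#'
#' @param width,height image size in pixels.
#' @param orientation "vertical" (left/right halves) or "horizontal".
#' @param lo,hi the two grey levels.
#' @return a [Fixture-class]; truth marks both sides of the step.
#' @export
makeStep <- function(width = 32, height = 32,
                     orientation = c("vertical", "horizontal"),
                     lo = 0, hi = 255) {
  orientation <- match.arg(orientation)
  img <- matrix(lo, height, width)
  if (orientation == "vertical")
    img[, (floor(width / 2) + 1):width] <- hi
  else
    img[(floor(height / 2) + 1):height, ] <- hi
  .fixture("step", img, .discontinuityTruth(img),
           list(width = width, height = height, orientation = orientation,
                lo = lo, hi = hi))
}

#' Uniform test image
#'
#' @param width,height image size in pixels.
#' @param level the constant grey level.
#' @return a [Fixture-class] with an empty truth map.
#' @export
makeUniform <- function(width = 32, height = 32, level = 128) {
  img <- matrix(level, height, width)
  .fixture("uniform", img, matrix(FALSE, height, width),
           list(width = width, height = height, level = level))
}

#' Checkerboard test image
#'
#' @param width,height image size in pixels.
#' @param cell cell size in pixels.
#' @param lo,hi the two grey levels.
#' @return a [Fixture-class]; truth marks both sides of every grid line.
#' @export
makeCheckerboard <- function(width = 32, height = 32, cell = 8,
                             lo = 0, hi = 255) {
  stopifnot(cell >= 1)
  ri <- (seq_len(height) - 1) %/% cell
  ci <- (seq_len(width) - 1) %/% cell
  img <- matrix(ifelse(outer(ri, ci, "+") %% 2 == 0, lo, hi), height, width)
  .fixture("checkerboard", img, .discontinuityTruth(img),
           list(width = width, height = height, cell = cell,
                lo = lo, hi = hi))
}

#' Smooth low-contrast phantom (clinical stand-in)
#'
#' A uniform background carrying a few soft-edged circular blobs of small
#' amplitude: a deterministic stand-in for a smooth clinical MR slice. The
#' default 270 x 290 (width x height) geometry and low amplitude emulate the
#' smooth-image conditions of the evaluation protocol; amplitudes this small
#' leave the edge detector alone with little or no response, which is what
#' the contrast pre-stage is for.
#'
#' @param width,height image size in pixels.
#' @param blobs number of blobs.
#' @param amplitude blob intensity above background (grey levels, <= 40 for
#'   a genuinely smooth image; 0 gives a uniform image with empty truth).
#' @param smoothness softness of the blob edge in pixels (logistic falloff).
#' @param background background grey level.
#' @param seed optional seed; when given, blob centres and radii are drawn
#'   reproducibly, otherwise a fixed rosette layout is used.
#' @return a [Fixture-class]; truth marks both sides of each nominal blob
#'   boundary circle.
#' @export
makeSmoothPhantom <- function(width = 270, height = 290, blobs = 3,
                              amplitude = 35, smoothness = 3,
                              background = 110, seed = NULL) {
  stopifnot(blobs >= 0, amplitude >= 0)
  rmax <- 0.13 * min(width, height)
  if (blobs == 0) {
    centres <- matrix(0, 0, 2); radii <- numeric()
  } else if (is.null(seed)) {
    k <- seq_len(blobs)
    if (blobs == 1) {
      centres <- cbind((height + 1) / 2, (width + 1) / 2)
    } else {
      ang <- 2 * pi * (k - 1) / blobs
      centres <- cbind(height / 2 + 0.27 * height * sin(ang),
                       width / 2 + 0.27 * width * cos(ang))
    }
    radii <- rep(rmax, blobs)
  } else {
    drawn <- .withSeed(seed, list(
      r = stats::runif(blobs, height * 0.25, height * 0.75),
      c = stats::runif(blobs, width * 0.25, width * 0.75),
      rad = stats::runif(blobs, 0.6 * rmax, rmax)))
    centres <- cbind(drawn$r, drawn$c)
    radii <- drawn$rad
  }
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  img <- matrix(background, height, width)
  inside <- matrix(FALSE, height, width)
  for (b in seq_len(blobs)) {
    dist <- sqrt((rr - centres[b, 1])^2 + (cc - centres[b, 2])^2)
    img <- img + amplitude / (1 + exp((dist - radii[b]) / (smoothness / 4)))
    inside <- inside | dist <= radii[b]
  }
  img <- clampGrey(img)
  truth <- if (amplitude == 0) matrix(FALSE, height, width)
           else .discontinuityTruth(ifelse(inside, 1, 0))
  .fixture("phantom", img, truth,
           list(width = width, height = height, blobs = blobs,
                amplitude = amplitude, smoothness = smoothness,
                background = background, seed = seed))
}
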