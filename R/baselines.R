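## Classical comparison detectors. Convolution and Gaussian smoothing are
## delegated to EBImage (filter2 with replicate boundary, gblur); gradient
## thresholds default to Otsu on the gradient magnitude. Non-maximum
## suppression and hysteresis linking for Canny are implemented here.

.kernels <- list(
  sobel   = list(gx = matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3),
                 gy = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)),
  prewitt = list(gx = matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3),
                 gy = matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3)),
  ## 2x2 Roberts cross, embedded in a 3x3 frame for the centred convolution
  roberts = list(gx = matrix(c(0, 0, 0, 0, 1, 0, 0, 0, -1), 3, 3),
                 gy = matrix(c(0, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3)))

.filt <- function(img, k) EBImage::filter2(img, k, boundary = "replicate")

.gblur <- function(img, sigma)
  EBImage::gblur(img, sigma = sigma, boundary = "replicate")

## The FFT-backed convolution leaves responses of order 1e-12 on perfectly
## flat regions; anything below this floor is treated as exactly zero
## (meaningful gradients on the 0..255 scale are >= 1).
.responseFloor <- 1e-6

## Otsu threshold on a non-negative response map, on the map's own scale.
.otsuThreshold <- function(x) {
  mx <- max(x)
  if (mx <= 0) return(Inf)
  EBImage::otsu(EBImage::Image(x / mx), range = c(0, 1), levels = 256) * mx
}

.gradientMagnitude <- function(img, kernel) {
  gx <- .filt(img, kernel$gx)
  gy <- .filt(img, kernel$gy)
  sqrt(gx^2 + gy^2)
}

#' Gradient-kernel baseline detectors (Sobel, Prewitt, Roberts)
#'
#' Convolves with the standard kernel pair and thresholds the gradient
#' magnitude, by Otsu's method on the magnitude histogram (the "automatic"
#' policy) or at a fixed fraction of the maximum magnitude.
#'
#' @param image a [GreyImage-class] or numeric matrix.
#' @param kernel one of "sobel", "prewitt", "roberts".
#' @param thresholdPolicy "otsu" or "fixed".
#' @param fixedFrac threshold as a fraction of the maximum gradient magnitude
#'   (used when `thresholdPolicy = "fixed"`).
#' @return an [EdgeMap-class].
#' @export
gradientDetector <- function(image, kernel = c("sobel", "prewitt", "roberts"),
                             thresholdPolicy = c("otsu", "fixed"),
                             fixedFrac = 0.2) {
  kernel <- match.arg(kernel)
  thresholdPolicy <- match.arg(thresholdPolicy)
  img <- .asGreyMatrix(image)
  mag <- .gradientMagnitude(img, .kernels[[kernel]])
  mag[mag < .responseFloor] <- 0
  th <- switch(thresholdPolicy,
               otsu = .otsuThreshold(mag),
               fixed = fixedFrac * max(mag))
  edgeMap(mag > th)
}

#' Laplacian-of-Gaussian (Marr-Hildreth) baseline detector
#'
#' Gaussian smoothing at `sigma`, Laplacian, then zero-crossings whose local
#' slope (the magnitude of the sign change across opposing neighbours)
#' exceeds `gateFrac` of the maximum slope.
#'
#' @param image a [GreyImage-class] or numeric matrix.
#' @param sigma Gaussian smoothing width in pixels.
#' @param gateFrac magnitude gate as a fraction of the maximum zero-crossing
#'   slope.
#' @return an [EdgeMap-class].
#' @export
logDetector <- function(image, sigma = 2, gateFrac = 0.1) {
  img <- .asGreyMatrix(image)
  sm <- .gblur(img, sigma)
  lap <- .filt(sm, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))
  m <- nrow(lap); n <- ncol(lap)
  shift <- function(dr, dc) {
    out <- matrix(0, m, n)
    out[max(1, 1 - dr):min(m, m - dr), max(1, 1 - dc):min(n, n - dc)] <-
      lap[max(1, 1 + dr):min(m, m + dr), max(1, 1 + dc):min(n, n + dc)]
    out
  }
  strength <- matrix(0, m, n)
  for (pair in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    a <- shift(-pair[1], -pair[2])
    b <- shift(pair[1], pair[2])
    cross <- sign(a) * sign(b) < 0
    strength <- pmax(strength, ifelse(cross, abs(a - b), 0))
  }
  mx <- max(strength)
  if (mx < .responseFloor) return(edgeMap(matrix(FALSE, m, n)))
  edgeMap(strength > gateFrac * mx)
}

#' Canny baseline detector
#'
#' Gaussian smoothing, Sobel gradient, non-maximum suppression along the
#' quantized gradient direction, and hysteresis linking: weak responses are
#' kept only in 8-connected components that contain a strong response.
#'
#' @param image a [GreyImage-class] or numeric matrix.
#' @param sigma Gaussian smoothing width in pixels.
#' @param lowFrac,highFrac hysteresis thresholds as fractions of the maximum
#'   suppressed gradient magnitude (`lowFrac <= highFrac`).
#' @return an [EdgeMap-class].
#' @export
cannyDetector <- function(image, sigma = 1, lowFrac = 0.1, highFrac = 0.2) {
  stopifnot(lowFrac <= highFrac)
  img <- .asGreyMatrix(image)
  sm <- .gblur(img, sigma)
  gx <- .filt(sm, .kernels$sobel$gx)
  gy <- .filt(sm, .kernels$sobel$gy)
  mag <- sqrt(gx^2 + gy^2)
  m <- nrow(mag); n <- ncol(mag)

  ## quantize gradient direction into 4 bins (mod 180 degrees)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180
  bin <- integer(length(ang))
  bin[(ang < 22.5) | (ang >= 157.5)] <- 1L  # horizontal gradient
  bin[ang >= 22.5 & ang < 67.5] <- 2L       # diagonal /
  bin[ang >= 67.5 & ang < 112.5] <- 3L      # vertical gradient
  bin[ang >= 112.5 & ang < 157.5] <- 4L     # diagonal \
  bin <- matrix(bin, m, n)

  shiftM <- function(x, dr, dc) {
    out <- matrix(0, m, n)
    out[max(1, 1 - dr):min(m, m - dr), max(1, 1 - dc):min(n, n - dc)] <-
      x[max(1, 1 + dr):min(m, m + dr), max(1, 1 + dc):min(n, n + dc)]
    out
  }
  offs <- list(`1` = c(0, 1), `2` = c(1, 1), `3` = c(1, 0), `4` = c(1, -1))
  nms <- matrix(0, m, n)
  for (b in 1:4) {
    o <- offs[[b]]
    ## strict on the forward neighbour so plateau ties keep a single pixel
    keep <- bin == b & mag > shiftM(mag, o[1], o[2]) &
      mag >= shiftM(mag, -o[1], -o[2])
    nms[keep] <- mag[keep]
  }

  mx <- max(nms)
  if (mx < .responseFloor) return(edgeMap(matrix(FALSE, m, n)))
  low <- lowFrac * mx
  high <- highFrac * mx
  weak <- nms >= low & nms > 0
  strong <- nms >= high
  lab <- labelComponents(weak, 8L)
  keepLabs <- unique(lab[strong & lab > 0L])
  edgeMap(lab > 0L & lab %in% keepLabs)
}

#' Run a baseline detector by name
#'
#' Dispatcher over the classical comparison detectors. Parameters not named
#' are left at the documented defaults of the individual detectors.
#'
#' @param image a [GreyImage-class] or numeric matrix.
#' @param method one of "sobel", "prewitt", "roberts", "log", "canny".
#' @param ... passed to the underlying detector.
#' @return an [EdgeMap-class].
#' @examples
#' edgeBaseline(makeStep(16, 16)@image, "sobel")
#' @export
edgeBaseline <- function(image,
                         method = c("sobel", "prewitt", "roberts", "log",
                                    "canny"),
                         ...) {
  method <- match.arg(method)
  switch(method,
         sobel = gradientDetector(image, "sobel", ...),
         prewitt = gradientDetector(image, "prewitt", ...),
         roberts = gradientDetector(image, "roberts", ...),
         log = logDetector(image, ...),
         canny = cannyDetector(image, ...))
}
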