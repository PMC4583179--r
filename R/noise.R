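## Run `expr` under a fixed seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a noise report
#'
#' @param density fraction of corrupted pixels.
#' @param seed RNG seed used (or `NA`).
#' @param mse realized mean squared error.
#' @param psnr realized PSNR in dB.
#' @return a [NoiseReport-class].
#' @export
noiseReport <- function(density, seed, mse, psnr)
  new("NoiseReport", density = density,
      seed = as.numeric(if (is.null(seed)) NA else seed),
      mse = mse, psnr = psnr)

setMethod("show", "NoiseReport", function(object) {
  cat(sprintf("NoiseReport: density %.4g, MSE %.4g, PSNR %.3f dB (seed %s)\n",
              object@density, object@mse, object@psnr,
              if (is.na(object@seed)) "none" else format(object@seed)))
})

#' Inject salt-and-pepper noise
#'
#' Each pixel is independently corrupted with probability `p`; corrupted
#' pixels are set to 0 or 255 with equal probability. With a fixed `seed` the
#' corruption pattern is reproducible, and for a given seed the corrupted set
#' grows monotonically with `p` (the same uniform draws are thresholded),
#' which makes PSNR calibration by bisection well behaved.
#'
#' @param image a [GreyImage-class] or numeric matrix.
#' @param p corruption probability in `[0, 1]`.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return a [GreyImage-class].
#' @export
addSaltPepper <- function(image, p, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  img <- .asGreyMatrix(image)
  out <- .withSeed(seed, {
    u <- stats::runif(length(img))
    salt <- stats::runif(length(img)) < 0.5
    v <- img
    hit <- u < p
    v[hit] <- ifelse(salt[hit], 255, 0)
    v
  })
  greyImage(out)
}

#' Mean squared error between two images
#'
#' `mean((a - b)^2)` over all pixels.
#'
#' @param a,b images of identical shape.
#' @return the MSE (grey levels squared).
#' @export
mse <- function(a, b) {
  ma <- .asGreyMatrix(a); mb <- .asGreyMatrix(b)
  if (!identical(dim(ma), dim(mb)))
    stop("images must have the same shape")
  mean((ma - mb)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(255^2 / MSE)` for 8-bit images (peak intensity Qp = 255).
#'
#' @param a,b images of identical shape; must differ somewhere.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b) {
  m <- mse(a, b)
  if (m == 0) stop("PSNR is undefined for identical images (MSE = 0)")
  10 * log10(255^2 / m)
}

#' Calibrate noise density to a target PSNR
#'
#' Bisects on the corruption probability until the realized PSNR of the
#' noisy image is within `tolDb` of `targetDb`. Every probe reuses the same
#' seed, so realized MSE is monotone in the density and the bisection
#' converges.
#'
#' @param image a [GreyImage-class] or numeric matrix.
#' @param targetDb target PSNR in dB (must be attainable: below the PSNR at
#'   full corruption lies an error).
#' @param tolDb tolerance in dB (default 0.25; `Inf` returns after the first
#'   probe).
#' @param seed integer seed used for every probe and the returned image.
#' @param maxIter bisection iteration cap.
#' @return list with elements `density`, `report` (a [NoiseReport-class])
#'   and `image` (the calibrated noisy [GreyImage-class]).
#' @examples
#' fx <- makeUniform(64, 64, 128)
#' cal <- calibrateDensity(fx@image, targetDb = 25, seed = 1)
#' cal$report
#' @export
calibrateDensity <- function(image, targetDb, tolDb = 0.25, seed = 1L,
                             maxIter = 60L) {
  img <- .asGreyMatrix(image)
  stopifnot(is.finite(targetDb), targetDb > 0)
  probe <- function(p) {
    noisy <- addSaltPepper(img, p, seed = seed)
    m <- mse(img, noisy)
    list(image = noisy, mse = m,
         psnr = if (m > 0) 10 * log10(255^2 / m) else Inf)
  }
  if (is.finite(tolDb)) {
    full <- probe(1)
    if (full$psnr > targetDb + tolDb)
      stop(sprintf(
        "target %.2f dB is not bracketable: full corruption realizes %.2f dB",
        targetDb, full$psnr))
  }
  lo <- 0; hi <- 1
  p <- 0.5; r <- probe(p)
  for (i in seq_len(maxIter)) {
    if (abs(r$psnr - targetDb) <= tolDb) break
    if (r$psnr > targetDb) lo <- p else hi <- p
    p <- (lo + hi) / 2
    r <- probe(p)
  }
  if (abs(r$psnr - targetDb) > tolDb)
    stop("bisection did not reach the PSNR tolerance; image may be too small")
  list(density = p,
       report = noiseReport(p, seed, r$mse, r$psnr),
       image = r$image)
}
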