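#' Configure the fuzzy contrast-intensification stage
#'
#' A three-rule single-input Mamdani system (Darker -> Darkest,
#' Grey -> Grey, Brighter -> Brightest) applied independently to every pixel
#' before edge detection on smooth, low-contrast images. The induced
#' intensity transfer is monotone and pushes dark pixels darker and bright
#' pixels brighter, expanding contrast around mid-grey.
#'
#' The default membership functions are symmetric about mid-grey (127.5):
#' input Darker = trapezoid (0, 0, 80, 127), Grey = trapezoid
#' (105, 124, 131, 150), Brighter = trapezoid (128, 175, 255, 255); output
#' Darkest = Gaussian(m = 5, d = 20), Grey = Gaussian(m = 127.5, d = 20),
#' Brightest = Gaussian(m = 250, d = 20). They roughly double mid-range
#' contrast (a 110/145 step maps to about 84/171) while keeping the transfer
#' monotone.
#'
#' @param inputSets named list of three input [FuzzySet-class]s.
#' @param outputSets named list of three output [FuzzySet-class]s.
#' @param rules named character vector mapping input to output labels.
#' @param universe an [OutputUniverse-class].
#' @return a [ContrastConfig-class].
#' @export
contrastConfig <- function(inputSets, outputSets,
                           rules = c(Darker = "Darkest", Grey = "Grey",
                                     Brighter = "Brightest"),
                           universe = outputUniverse()) {
  new("ContrastConfig", inputSets = inputSets, outputSets = outputSets,
      rules = rules, universe = universe)
}

#' @rdname contrastConfig
#' @export
defaultContrastConfig <- function() {
  contrastConfig(
    inputSets = list(
      Darker   = fuzzySet("Darker",   trapezoidalMF(0, 0, 80, 127)),
      Grey     = fuzzySet("Grey",     trapezoidalMF(105, 124, 131, 150)),
      Brighter = fuzzySet("Brighter", trapezoidalMF(128, 175, 255, 255))),
    outputSets = list(
      Darkest   = fuzzySet("Darkest",   gaussianMF(5, 20)),
      Grey      = fuzzySet("Grey",      gaussianMF(127.5, 20)),
      Brightest = fuzzySet("Brightest", gaussianMF(250, 20))))
}

setMethod("show", "ContrastConfig", function(object) {
  cat(sprintf("ContrastConfig: %s\n",
              paste(names(object@rules), object@rules, sep = " -> ",
                    collapse = ", ")))
})

#' Intensity transfer function of the contrast stage
#'
#' Evaluates the crisp Mamdani output for every integer grey level 0..255.
#' Because the stage is pixel-wise, this 256-entry lookup table fully
#' describes [adjustContrast()] (before rounding).
#'
#' @param config a [ContrastConfig-class].
#' @return numeric vector of length 256: unrounded crisp outputs for inputs
#'   0..255.
#' @export
contrastTransfer <- function(config = defaultContrastConfig()) {
  v <- 0:255
  agg <- lapply(names(config@rules), function(inLab)
    memberDegree(config@inputSets[[inLab]], v))
  names(agg) <- unname(config@rules)
  .centroidVec(agg, config@outputSets, config@universe)
}

#' Fuzzy contrast intensification
#'
#' Maps each pixel independently through the three-rule Mamdani system and
#' rounds the defuzzified output to the nearest integer grey level (ties to
#' even).
#'
#' @param image a [GreyImage-class] or numeric matrix.
#' @param config a [ContrastConfig-class].
#' @return a [GreyImage-class] of the same shape.
#' @examples
#' img <- greyImage(matrix(c(110, 145), 8, 8))
#' range(adjustContrast(img))  # wider than the 35-level input range
#' @export
adjustContrast <- function(image, config = defaultContrastConfig()) {
  img <- .asGreyMatrix(image)
  lut <- clampGrey(contrastTransfer(config))
  out <- matrix(lut[img + 1L], nrow(img), ncol(img))
  greyImage(out)
}
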