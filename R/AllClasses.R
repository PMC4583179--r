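#' @import methods
NULL

#' Membership functions
#'
#' Virtual parent of the two membership-function shapes used by the system:
#' trapezoidal (for the eight neighbourhood-difference inputs) and Gaussian
#' (for the Edge/NonEdge output sets).
#'
#' @name MembershipFunction-class
#' @aliases MembershipFunction
#' @exportClass MembershipFunction
setClass("MembershipFunction", representation("VIRTUAL"))

#' @rdname MembershipFunction-class
#' @slot r,s,t,u breakpoints of the trapezoid on the grey-level axis;
#'   degree is 0 outside `[r, u]`, 1 on `[s, t]` and linear in between.
#'   Degenerate plateaus (`r == s`, `t == u`) are allowed.
#' @exportClass TrapezoidalMF
setClass("TrapezoidalMF", contains = "MembershipFunction",
  representation(r = "numeric", s = "numeric", t = "numeric", u = "numeric"),
  validity = function(object) {
    p <- c(object@r, object@s, object@t, object@u)
    if (length(p) != 4L || any(!is.finite(p)))
      return("r, s, t, u must be single finite numbers")
    if (is.unsorted(p))
      return("trapezoid breakpoints must satisfy r <= s <= t <= u")
    TRUE
  })

#' @rdname MembershipFunction-class
#' @slot m centre of the Gaussian bell (grey level, degree 1 exactly at m).
#' @slot d width of the bell (grey levels, strictly positive).
#' @exportClass GaussianMF
setClass("GaussianMF", contains = "MembershipFunction",
  representation(m = "numeric", d = "numeric"),
  validity = function(object) {
    if (length(object@m) != 1L || !is.finite(object@m))
      return("m must be a single finite number")
    if (length(object@d) != 1L || !is.finite(object@d) || object@d <= 0)
      return("d must be a single finite number > 0")
    TRUE
  })

#' Labelled fuzzy set on a bounded grey-level universe
#'
#' @slot label linguistic label, e.g. "Lower", "Higher", "Edge".
#' @slot mf a [MembershipFunction-class] giving the degree curve.
#' @slot universe closed interval (length-2 numeric) on which the set lives;
#'   evaluation outside is clamped to the boundary degree.
#'
#' @exportClass FuzzySet
setClass("FuzzySet",
  representation(label = "character", mf = "MembershipFunction",
                 universe = "numeric"),
  validity = function(object) {
    if (length(object@label) != 1L || !nzchar(object@label))
      return("label must be a single non-empty string")
    u <- object@universe
    if (length(u) != 2L || any(!is.finite(u)) || u[1] >= u[2])
      return("universe must be a finite increasing interval c(lo, hi)")
    TRUE
  })

#' A fuzzy rule over the eight neighbourhood differences
#'
#' Antecedents are a partial mapping from the neighbour index j in 1..8 to a
#' linguistic input label ("Lower"/"Higher"); indices absent from the mapping
#' are don't-care and do not enter the t-norm.
#'
#' @slot antecedents named character vector; names are neighbour indices
#'   ("1".."8"), values are input-set labels.
#' @slot consequent output-set label ("Edge" or "NonEdge").
#'
#' @exportClass FuzzyRule
setClass("FuzzyRule",
  representation(antecedents = "character", consequent = "character"),
  validity = function(object) {
    a <- object@antecedents
    if (length(a) < 1L) return("a rule needs at least one antecedent")
    idx <- suppressWarnings(as.integer(names(a)))
    if (any(is.na(idx)) || any(idx < 1L | idx > 8L))
      return("antecedent names must be neighbour indices in 1..8")
    if (anyDuplicated(idx)) return("duplicate antecedent index")
    if (length(object@consequent) != 1L || !nzchar(object@consequent))
      return("consequent must be a single label")
    TRUE
  })

#' Discretized output universe for centroid defuzzification
#'
#' @slot lo,hi bounds of the crisp output axis (grey levels).
#' @slot n number of evenly spaced sample points (>= 2).
#' @slot points the sample points; `points[1] == lo`, `points[n] == hi`.
#'
#' @exportClass OutputUniverse
setClass("OutputUniverse",
  representation(lo = "numeric", hi = "numeric", n = "integer",
                 points = "numeric"),
  validity = function(object) {
    if (object@n < 2L) return("n must be >= 2")
    if (!is.finite(object@lo) || !is.finite(object@hi) ||
        object@lo >= object@hi)
      return("need finite lo < hi")
    if (length(object@points) != object@n) return("points length must be n")
    TRUE
  })

#' 8-bit greyscale image
#'
#' A numeric matrix (rows x cols) whose entries are integer grey levels in
#' `[0, 255]`. Construct with [greyImage()].
#'
#' @exportClass GreyImage
setClass("GreyImage", contains = "matrix",
  validity = function(object) {
    v <- object@.Data
    if (!is.numeric(v)) return("intensities must be numeric")
    if (anyNA(v) || any(v < 0 | v > 255)) return("grey levels must be in [0, 255]")
    if (any(v != round(v))) return("grey levels must be integers")
    TRUE
  })

#' Binary edge map
#'
#' A logical matrix the same shape as its source image; `TRUE` marks an edge
#' pixel. The outermost 1-pixel frame is never flagged (border policy: the
#' 3x3 mask is undefined there and no padding is invented). Construct with
#' [edgeMap()], which clears the frame.
#'
#' @exportClass EdgeMap
setClass("EdgeMap", contains = "matrix",
  validity = function(object) {
    v <- object@.Data
    if (!is.logical(v)) return("edge flags must be logical")
    if (anyNA(v)) return("edge flags must not contain NA")
    m <- nrow(v); n <- ncol(v)
    if (m >= 1 && n >= 1 &&
        (any(v[c(1, m), ]) || any(v[, c(1, n)])))
      return("border pixels must not be flagged")
    TRUE
  })

#' Configuration of the fuzzy edge detector
#'
#' @slot inputSets named list of [FuzzySet-class]s over the difference inputs
#'   (default labels "Lower" and "Higher").
#' @slot outputSets named list of output [FuzzySet-class]s ("NonEdge","Edge").
#' @slot rules list of [FuzzyRule-class]s (the knowledge base).
#' @slot universe the [OutputUniverse-class] used for defuzzification.
#' @slot threshold binarization cut on the crisp edge score; must lie strictly
#'   between the two output-set centres.
#' @slot neighborOrder character vector of length 8 naming the compass
#'   position of each mask index j (the scan convention).
#'
#' @exportClass DetectorConfig
setClass("DetectorConfig",
  representation(inputSets = "list", outputSets = "list", rules = "list",
                 universe = "OutputUniverse", threshold = "numeric",
                 neighborOrder = "character"),
  validity = function(object) {
    if (!all(vapply(object@inputSets, is, TRUE, "FuzzySet")))
      return("inputSets must all be FuzzySet objects")
    if (!all(vapply(object@outputSets, is, TRUE, "FuzzySet")))
      return("outputSets must all be FuzzySet objects")
    if (!all(vapply(object@rules, is, TRUE, "FuzzyRule")))
      return("rules must all be FuzzyRule objects")
    labs <- names(object@inputSets)
    for (r in object@rules)
      if (!all(r@antecedents %in% labs))
        return("rule references an unknown input-set label")
    cons <- unique(vapply(object@rules, function(r) r@consequent, ""))
    if (!all(cons %in% names(object@outputSets)))
      return("rule consequent not among output sets")
    ctr <- sort(vapply(object@outputSets, mfCenter, 0))
    th <- object@threshold
    if (length(th) != 1L || th <= ctr[1] || th >= ctr[length(ctr)])
      return("threshold must lie strictly between the output-set centres")
    if (length(object@neighborOrder) != 8L)
      return("neighborOrder must name 8 compass positions")
    if (!all(object@neighborOrder %in% names(.compassOffsets)) ||
        anyDuplicated(object@neighborOrder))
      return("neighborOrder must be a permutation of NW,N,NE,W,E,SW,S,SE")
    TRUE
  })

#' Configuration of the fuzzy contrast-intensification stage
#'
#' Three single-input Mamdani rules (Table-style: Darker -> Darkest,
#' Grey -> Grey, Brighter -> Brightest) define a monotone intensity transfer.
#'
#' @slot inputSets named list of three input [FuzzySet-class]s.
#' @slot outputSets named list of three output [FuzzySet-class]s.
#' @slot rules named character vector mapping input label -> output label.
#' @slot universe the [OutputUniverse-class] for defuzzification.
#'
#' @exportClass ContrastConfig
setClass("ContrastConfig",
  representation(inputSets = "list", outputSets = "list", rules = "character",
                 universe = "OutputUniverse"),
  validity = function(object) {
    if (!all(vapply(object@inputSets, is, TRUE, "FuzzySet")) ||
        !all(vapply(object@outputSets, is, TRUE, "FuzzySet")))
      return("input and output sets must be FuzzySet objects")
    if (!all(names(object@rules) %in% names(object@inputSets)) ||
        !all(object@rules %in% names(object@outputSets)))
      return("rules must map input-set labels to output-set labels")
    ctr <- vapply(object@outputSets[object@rules], mfCenter, 0)
    if (is.unsorted(ctr, strictly = FALSE) && is.unsorted(rev(ctr)))
      return("output-set centres must be ordered")
    TRUE
  })

#' Realized noise injection report
#'
#' @slot density fraction of corrupted pixels.
#' @slot seed RNG seed used (NA if none was fixed).
#' @slot mse realized mean squared error against the clean image.
#' @slot psnr realized peak signal-to-noise ratio in dB (Inf when mse == 0).
#'
#' @exportClass NoiseReport
setClass("NoiseReport",
  representation(density = "numeric", seed = "numeric", mse = "numeric",
                 psnr = "numeric"),
  validity = function(object) {
    if (object@density < 0 || object@density > 1)
      return("density must be in [0, 1]")
    if (object@mse < 0) return("mse must be >= 0")
    if (object@mse > 0 && !is.finite(object@psnr))
      return("psnr must be finite when mse > 0")
    TRUE
  })

#' Synthetic test image with analytic ground truth
#'
#' @slot name generator name.
#' @slot image the [GreyImage-class].
#' @slot truth an [EdgeMap-class] marking pixels adjacent to an intensity
#'   discontinuity of the generator (both sides of each interface).
#' @slot params generation parameters (for reproducibility).
#'
#' @exportClass Fixture
setClass("Fixture",
  representation(name = "character", image = "GreyImage", truth = "EdgeMap",
                 params = "list"),
  validity = function(object) {
    if (!identical(dim(object@image), dim(object@truth)))
      return("image and truth must have the same shape")
    TRUE
  })
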