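#' Construct a trapezoidal membership function
#'
#' Degree is 0 outside `[r, u]`, rises linearly on `[r, s]`, is 1 on the
#' plateau `[s, t]` and falls linearly on `[t, u]`. Degenerate plateaus
#' (`r == s` or `t == u`) give a vertical flank and evaluate without division
#' by zero.
#'
#' @param r,s,t,u breakpoints, `r <= s <= t <= u` (grey levels).
#' @return a [TrapezoidalMF][MembershipFunction-class].
#' @examples
#' higher <- trapezoidalMF(25, 75, 255, 255)
#' memberDegree(higher, c(25, 50, 75))  # 0.0 0.5 1.0
#' @export
trapezoidalMF <- function(r, s, t, u) new("TrapezoidalMF", r = r, s = s, t = t, u = u)

#' Construct a Gaussian membership function
#'
#' `exp(-(w - m)^2 / (2 d^2))`: degree 1 exactly at `m`, strictly positive
#' everywhere.
#'
#' @param m centre (grey level).
#' @param d width (grey levels, > 0).
#' @return a [GaussianMF][MembershipFunction-class].
#' @export
gaussianMF <- function(m, d) new("GaussianMF", m = m, d = d)

#' Construct a labelled fuzzy set
#'
#' @param label linguistic label.
#' @param mf a membership function.
#' @param universe closed interval the set lives on; evaluation outside is
#'   clamped to the boundary degree.
#' @return a [FuzzySet-class].
#' @export
fuzzySet <- function(label, mf, universe = c(0, 255))
  new("FuzzySet", label = label, mf = mf, universe = as.numeric(universe))

#' @rdname memberDegree
setMethod("memberDegree", "TrapezoidalMF", function(object, w) {
  stopifnot(is.numeric(w), all(is.finite(w)))
  rise <- if (object@s > object@r) (w - object@r) / (object@s - object@r)
          else as.numeric(w >= object@s)
  fall <- if (object@u > object@t) (object@u - w) / (object@u - object@t)
          else as.numeric(w <= object@t)
  pmax(0, pmin(rise, fall, 1))
})

#' @rdname memberDegree
setMethod("memberDegree", "GaussianMF", function(object, w) {
  stopifnot(is.numeric(w), all(is.finite(w)))
  exp(-(w - object@m)^2 / (2 * object@d^2))
})

#' @rdname memberDegree
setMethod("memberDegree", "FuzzySet", function(object, w) {
  memberDegree(object@mf, pmin(pmax(w, object@universe[1]), object@universe[2]))
})

setMethod("mfCenter", "TrapezoidalMF", function(object) (object@s + object@t) / 2)
setMethod("mfCenter", "GaussianMF", function(object) object@m)
setMethod("mfCenter", "FuzzySet", function(object) mfCenter(object@mf))

setMethod("show", "TrapezoidalMF", function(object) {
  cat(sprintf("TrapezoidalMF [%g %g %g %g]\n",
              object@r, object@s, object@t, object@u))
})
setMethod("show", "GaussianMF", function(object) {
  cat(sprintf("GaussianMF (m = %g, d = %g)\n", object@m, object@d))
})
setMethod("show", "FuzzySet", function(object) {
  cat(sprintf("FuzzySet \"%s\" on [%g, %g]: ", object@label,
              object@universe[1], object@universe[2]))
  show(object@mf)
})
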