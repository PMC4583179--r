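#' Evaluate a membership degree
#'
#' Returns the degree of membership in `[0, 1]` of grey level(s) `w` in a
#' membership function or fuzzy set. For a [FuzzySet-class] the input is first
#' clamped to the set's universe.
#'
#' @param object a [MembershipFunction-class] or [FuzzySet-class].
#' @param w numeric vector of grey levels.
#' @return numeric vector of degrees in `[0, 1]`, same length as `w`.
#'
#' @examples
#' lower <- trapezoidalMF(0, 0, 25, 75)
#' memberDegree(lower, c(0, 50, 100))   # 1.0 0.5 0.0
#'
#' @export
setGeneric("memberDegree", function(object, w) standardGeneric("memberDegree"))

#' Centre of a membership function
#'
#' The crisp value at which the function peaks: `m` for a Gaussian, the
#' midpoint of the plateau `[s, t]` for a trapezoid.
#'
#' @param object a [MembershipFunction-class] or [FuzzySet-class].
#' @return a single grey level.
#' @export
setGeneric("mfCenter", function(object) standardGeneric("mfCenter"))

#' Firing strength of a rule
#'
#' Mamdani t-norm (minimum) over the rule's specified antecedents; don't-care
#' inputs do not participate.
#'
#' @param rule a [FuzzyRule-class].
#' @param deltas numeric vector of the 8 neighbourhood differences.
#' @param inputSets named list of input [FuzzySet-class]s.
#' @return a degree in `[0, 1]`.
#' @export
setGeneric("firingStrength",
           function(rule, deltas, inputSets) standardGeneric("firingStrength"))
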