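#' Construct a fuzzy rule
#'
#' @param higher integer vector of neighbour indices (1..8) constrained to be
#'   "Higher".
#' @param lower integer vector of neighbour indices constrained to be "Lower".
#' @param consequent output-set label, default "Edge".
#' @return a [FuzzyRule-class].
#' @examples
#' fuzzyRule(higher = c(1, 2), lower = 8)   # rule 1 of the default base
#' @export
fuzzyRule <- function(higher = integer(), lower = integer(),
                      consequent = "Edge") {
  ant <- c(stats::setNames(rep("Higher", length(higher)), higher),
           stats::setNames(rep("Lower", length(lower)), lower))
  new("FuzzyRule", antecedents = ant, consequent = consequent)
}

setMethod("show", "FuzzyRule", function(object) {
  a <- paste(sprintf("dP%s is %s", names(object@antecedents),
                     object@antecedents), collapse = " & ")
  cat(sprintf("FuzzyRule: IF %s THEN %s\n", a, object@consequent))
})

#' Default input fuzzy sets for the edge detector
#'
#' The two linguistic categories of a neighbourhood difference dPj on
#' `[0, 255]`: Lower = trapezoid (0, 0, 25, 75), Higher = trapezoid
#' (25, 75, 255, 255). The same pair applies to all eight inputs.
#'
#' @return named list of two [FuzzySet-class]s.
#' @export
edgeInputSets <- function() {
  list(Lower  = fuzzySet("Lower",  trapezoidalMF(0, 0, 25, 75)),
       Higher = fuzzySet("Higher", trapezoidalMF(25, 75, 255, 255)))
}

#' Default output fuzzy sets for the edge detector
#'
#' Gaussian bells on the crisp edge-score axis: NonEdge centred at 10,
#' Edge centred at 245, both with width 3.5.
#'
#' @return named list of two [FuzzySet-class]s.
#' @export
edgeOutputSets <- function() {
  list(NonEdge = fuzzySet("NonEdge", gaussianMF(10, 3.5)),
       Edge    = fuzzySet("Edge",    gaussianMF(245, 3.5)))
}

#' The 12-rule edge knowledge base
#'
#' Each rule pairs two adjacent "Higher" differences on one side of the mask
#' with one "Lower" difference on the opposite side; all other inputs are
#' don't-care. Under the row-major neighbour convention (P1=NW, P2=N, P3=NE,
#' P4=W, P5=E, P6=SW, P7=S, P8=SE) the Higher pairs (1,2), (1,4), (2,3),
#' (4,6) are directional edge templates and the Lower cell (8, 7 or 5) sits
#' across the centre. All consequents are "Edge"; a non-edge conclusion is
#' reached through the implicit else (see [inferDefuzzify()]).
#'
#' @return list of 12 [FuzzyRule-class]s.
#' @export
edgeRuleBase <- function() {
  pairs <- list(c(1, 2), c(1, 4), c(2, 3), c(4, 6))
  lowers <- c(8, 7, 5)
  rules <- vector("list", 12L)
  k <- 0L
  for (lo in lowers)
    for (hp in pairs) {
      k <- k + 1L
      rules[[k]] <- fuzzyRule(higher = hp, lower = lo)
    }
  rules
}
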