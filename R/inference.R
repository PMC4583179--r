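#' Construct a discretized output universe
#'
#' Evenly spaced sample points on `[lo, hi]` used by the discrete centroid
#' defuzzifier. The default is 512 points on `[0, 255]` (half-grey-level
#' spacing), which keeps the discretization error of the centroid below
#' 0.3 grey level in the worst case; the grid is symmetric about 127.5, so
#' exactly balanced Edge/NonEdge aggregates defuzzify to mid-grey.
#'
#' @param lo,hi bounds (grey levels).
#' @param n number of sample points (>= 2).
#' @return an [OutputUniverse-class].
#' @export
outputUniverse <- function(lo = 0, hi = 255, n = 512L) {
  n <- as.integer(n)
  new("OutputUniverse", lo = lo, hi = hi, n = n,
      points = seq(lo, hi, length.out = n))
}

setMethod("show", "OutputUniverse", function(object) {
  cat(sprintf("OutputUniverse: %d points on [%g, %g]\n",
              object@n, object@lo, object@hi))
})

#' @rdname firingStrength
setMethod("firingStrength", "FuzzyRule", function(rule, deltas, inputSets) {
  stopifnot(length(deltas) >= 8L)
  idx <- as.integer(names(rule@antecedents))
  degs <- mapply(function(j, lab) memberDegree(inputSets[[lab]], deltas[[j]]),
                 idx, rule@antecedents)
  min(degs)
})

#' Aggregate per-rule strengths onto the output sets
#'
#' Max-aggregation of rule firing strengths by consequent, plus the implicit
#' else: the knowledge base states only Edge rules, so the `elseLabel` set
#' (NonEdge) additionally receives strength `1 - max(all rule strengths)`.
#' This guarantees a non-empty aggregate and a continuous edge score.
#'
#' @param strengths numeric vector of per-rule firing strengths.
#' @param rules the list of [FuzzyRule-class]s (same order as `strengths`).
#' @param outputLabels labels of the output sets.
#' @param elseLabel output label that receives the implicit-else strength,
#'   or `NA` to disable the else rule.
#' @return named numeric vector of aggregate strengths, one per output label.
#' @export
aggregateConsequents <- function(strengths, rules,
                                 outputLabels = c("NonEdge", "Edge"),
                                 elseLabel = "NonEdge") {
  stopifnot(length(strengths) == length(rules))
  cons <- vapply(rules, function(r) r@consequent, "")
  agg <- vapply(outputLabels,
                function(lab) if (any(cons == lab)) max(strengths[cons == lab]) else 0,
                0)
  if (!is.na(elseLabel)) {
    els <- if (length(strengths)) 1 - max(strengths) else 1
    agg[elseLabel] <- max(agg[elseLabel], els)
  }
  agg
}

## Discrete Mamdani centroid: clip each output MF at its aggregate strength,
## aggregate pointwise by max, then take the weighted mean of the sample
## points. Falls back to the NonEdge (or first) set's centre when the
## aggregate is identically zero.
.mamdaniCentroid <- function(aggregates, outputSets, universe) {
  z <- universe@points
  q <- rep(0, length(z))
  for (lab in names(aggregates))
    q <- pmax(q, pmin(aggregates[[lab]], memberDegree(outputSets[[lab]], z)))
  s <- sum(q)
  if (s == 0) {
    fb <- if ("NonEdge" %in% names(outputSets)) outputSets[["NonEdge"]]
          else outputSets[[1L]]
    return(mfCenter(fb))
  }
  sum(q * z) / s
}

#' Mamdani inference with centroid defuzzification
#'
#' Implements the full consequent stage: per-rule strengths are aggregated by
#' max onto the output sets (with the implicit else on NonEdge), each output
#' MF is clipped at its aggregate strength, the clipped curves are combined
#' pointwise by max over the discretized universe, and the crisp output is
#' the centroid `sum(q_x z_x) / sum(q_x)`.
#'
#' @inheritParams aggregateConsequents
#' @param outputSets named list of output [FuzzySet-class]s.
#' @param universe an [OutputUniverse-class].
#' @param elseLabel see [aggregateConsequents()].
#' @return crisp output in `[lo, hi]` of the universe.
#' @examples
#' # rule 1 fully fired, all others silent -> crisp score near the Edge centre
#' inferDefuzzify(c(1, rep(0, 11)), edgeRuleBase(), edgeOutputSets())
#' @export
inferDefuzzify <- function(strengths, rules, outputSets,
                           universe = outputUniverse(),
                           elseLabel = "NonEdge") {
  agg <- aggregateConsequents(strengths, rules,
                              outputLabels = names(outputSets),
                              elseLabel = elseLabel)
  .mamdaniCentroid(agg, outputSets, universe)
}

## Vectorized centroid over many pixels. `aggregates` is a named list of
## equal-length strength vectors (one per output set). Chunked so that the
## (pixels x universe points) work matrix stays small. The per-chunk rowSums
## reproduce the scalar sum() accumulation order, so results agree with
## .mamdaniCentroid to machine precision.
.centroidVec <- function(aggregates, outputSets, universe, chunk = 4096L) {
  z <- universe@points
  nz <- length(z)
  npix <- length(aggregates[[1L]])
  g <- lapply(names(aggregates),
              function(lab) memberDegree(outputSets[[lab]], z))
  names(g) <- names(aggregates)
  fb <- if ("NonEdge" %in% names(outputSets)) mfCenter(outputSets[["NonEdge"]])
        else mfCenter(outputSets[[1L]])
  out <- numeric(npix)
  for (start in seq(1L, npix, by = chunk)) {
    idx <- start:min(start + chunk - 1L, npix)
    len <- length(idx)
    q <- matrix(0, len, nz)
    for (lab in names(aggregates)) {
      clip <- matrix(aggregates[[lab]][idx], len, nz)
      gmat <- matrix(g[[lab]], len, nz, byrow = TRUE)
      q <- pmax(q, pmin(clip, gmat))
    }
    den <- rowSums(q)
    num <- rowSums(q * matrix(z, len, nz, byrow = TRUE))
    out[idx] <- ifelse(den > 0, num / den, fb)
  }
  out
}
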