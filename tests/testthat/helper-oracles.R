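# Independent oracles used across the suite.

# Brute-force Mamdani centroid by dense trapezoidal quadrature, written
# against the defining integral rather than the package's discrete-sum path.
denseCentroid <- function(aggregates, outputSets, lo = 0, hi = 255,
                          n = 2560L) {
  z <- seq(lo, hi, length.out = n)
  q <- rep(0, n)
  for (lab in names(aggregates))
    q <- pmax(q, pmin(aggregates[[lab]], memberDegree(outputSets[[lab]], z)))
  trapz <- function(y) sum((y[-1] + y[-n]) / 2 * diff(z))
  den <- trapz(q)
  if (den == 0) return(NA_real_)
  trapz(q * z) / den
}

# Naive per-pixel reference detector: explicit double loop, no vectorization.
naiveDetect <- function(img, config = edgeDetectorConfig()) {
  m <- nrow(img); n <- ncol(img)
  flags <- matrix(FALSE, m, n)
  for (r in 2:(m - 1))
    for (cl in 2:(n - 1)) {
      d <- extractDeltas(img, r, cl, config@neighborOrder)
      flags[r, cl] <- edgeScore(d, config) >= config@threshold - 1e-9
    }
  edgeMap(flags)
}

randomGrey <- function(m, n, seed) {
  set.seed(seed)
  matrix(sample(0:255, m * n, replace = TRUE), m, n)
}
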