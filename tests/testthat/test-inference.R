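cfg <- edgeDetectorConfig()

test_that("firing strength is the min over specified antecedents only", {
  rule1 <- cfg@rules[[1]]   # dP1 Higher & dP2 Higher & dP8 Lower
  sets <- cfg@inputSets
  d <- c(255, 255, 0, 0, 0, 0, 0, 0)
  expect_equal(firingStrength(rule1, d, sets), 1)
  # a zero membership anywhere in the antecedents kills the rule
  expect_equal(firingStrength(rule1, c(0, 255, 0, 0, 0, 0, 0, 0), sets), 0)
  expect_equal(firingStrength(rule1, c(255, 255, 0, 0, 0, 0, 0, 255), sets), 0)
  # partial membership propagates through the min
  expect_equal(firingStrength(rule1, c(50, 255, 0, 0, 0, 0, 0, 0), sets), 0.5)
  # don't-care inputs do not participate: dP3..dP7 are free
  expect_equal(firingStrength(rule1, c(255, 255, 9, 99, 199, 7, 131, 0), sets), 1)
})

test_that("firing strength is monotone in the antecedent directions", {
  rule1 <- cfg@rules[[1]]
  sets <- cfg@inputSets
  set.seed(11)
  for (i in 1:30) {
    d <- runif(8, 0, 255)
    s0 <- firingStrength(rule1, d, sets)
    dHi <- d; dHi[1] <- min(255, d[1] + runif(1, 0, 80))
    expect_gte(firingStrength(rule1, dHi, sets), s0)   # Higher antecedent up
    dLo <- d; dLo[8] <- min(255, d[8] + runif(1, 0, 80))
    expect_lte(firingStrength(rule1, dLo, sets), s0)   # Lower antecedent up
  }
})

test_that("the implicit else routes residual strength to NonEdge", {
  agg <- aggregateConsequents(rep(0, 12), cfg@rules)
  expect_equal(unname(agg["NonEdge"]), 1)
  expect_equal(unname(agg["Edge"]), 0)
  agg <- aggregateConsequents(c(0.7, rep(0.2, 11)), cfg@rules)
  expect_equal(unname(agg["Edge"]), 0.7)
  expect_equal(unname(agg["NonEdge"]), 0.3)
})

test_that("pure consequents defuzzify to the output centres", {
  one <- c(1, rep(0, 11))
  cEdge <- inferDefuzzify(one, cfg@rules, cfg@outputSets, cfg@universe)
  oEdge <- denseCentroid(c(Edge = 1, NonEdge = 0), cfg@outputSets)
  expect_lt(abs(cEdge - 245), 1)
  expect_lt(abs(cEdge - oEdge), 0.5)
  cNon <- inferDefuzzify(rep(0, 12), cfg@rules, cfg@outputSets, cfg@universe)
  oNon <- denseCentroid(c(Edge = 0, NonEdge = 1), cfg@outputSets)
  expect_lt(abs(cNon - 10), 1)
  expect_lt(abs(cNon - oNon), 0.5)
})

test_that("balanced strengths land on the axis of symmetry", {
  # the output Gaussians share d and sit symmetrically (10 from 0, 245
  # from 255), so equal clips aggregate symmetrically about 127.5
  v <- fuzzedge:::.mamdaniCentroid(c(Edge = 0.5, NonEdge = 0.5),
                                   cfg@outputSets, cfg@universe)
  expect_lt(abs(v - 127.5), 0.5)
})

test_that("the discrete centroid tracks a 10x denser quadrature oracle", {
  set.seed(99)
  for (i in 1:100) {
    sE <- runif(1); sN <- runif(1)
    if (sE == 0 && sN == 0) sN <- 0.5
    got <- fuzzedge:::.mamdaniCentroid(c(Edge = sE, NonEdge = sN),
                                       cfg@outputSets, cfg@universe)
    want <- denseCentroid(c(Edge = sE, NonEdge = sN), cfg@outputSets)
    expect_lt(abs(got - want), 0.5)
  }
})

test_that("the crisp output is monotone in the Edge strength", {
  sE <- seq(0, 1, by = 0.02)
  v <- vapply(sE, function(s)
    fuzzedge:::.mamdaniCentroid(c(Edge = s, NonEdge = 0.4),
                                cfg@outputSets, cfg@universe), 0)
  expect_true(all(diff(v) >= -1e-9))
})

test_that("an all-zero aggregate falls back to the NonEdge centre", {
  v <- fuzzedge:::.mamdaniCentroid(c(Edge = 0, NonEdge = 0),
                                   cfg@outputSets, cfg@universe)
  expect_equal(v, 10)
})

test_that("vectorized and scalar centroids agree", {
  set.seed(5)
  sE <- runif(50); sN <- runif(50)
  vec <- fuzzedge:::.centroidVec(list(NonEdge = sN, Edge = sE),
                                 cfg@outputSets, cfg@universe, chunk = 7L)
  sca <- mapply(function(e, nn)
    fuzzedge:::.mamdaniCentroid(c(Edge = e, NonEdge = nn),
                                cfg@outputSets, cfg@universe), sE, sN)
  expect_equal(vec, sca, tolerance = 1e-12)
})
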