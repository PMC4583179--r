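cfg <- edgeDetectorConfig()

test_that("extractDeltas returns |Pj - P| under the row-major convention", {
  u <- matrix(100, 3, 3)
  expect_equal(unname(extractDeltas(u, 2, 2)), rep(0, 8))
  v <- matrix(255, 3, 3); v[2, 2] <- 0
  expect_equal(unname(extractDeltas(v, 2, 2)), rep(255, 8))
  w <- matrix(100, 3, 3); w[1, 1] <- 30          # NW neighbour = index 1
  expect_equal(unname(extractDeltas(w, 2, 2)), c(70, rep(0, 7)))
  expect_error(extractDeltas(u, 1, 2), "interior")
  expect_error(extractDeltas(u, 2, 3), "interior")
})

test_that("edge scores hit the centres for canonical neighbourhoods", {
  # no contrast anywhere: no rule can fire, else pushes to NonEdge
  expect_lt(abs(edgeScore(rep(0, 8), cfg) - 10), 1)
  # rule 1 pattern at full strength
  expect_lt(abs(edgeScore(c(255, 255, 0, 0, 0, 0, 0, 0), cfg) - 245), 1)
  # contrast in all eight directions (isolated impulse): every rule's Lower
  # antecedent is dead, so the point is classified non-edge
  expect_lt(abs(edgeScore(rep(255, 8), cfg) - 10), 1)
})

test_that("a uniform image yields no edges", {
  for (lev in c(0, 128, 255))
    expect_equal(edgeCount(detectEdges(makeUniform(32, 32, lev))), 0)
})

test_that("a hard vertical step yields one thin bright-side line", {
  em <- detectEdges(makeStep(32, 32))
  flags <- which(em@.Data, arr.ind = TRUE)
  cols <- unique(flags[, 2])
  expect_lte(length(cols), 2)                 # width <= 2
  expect_true(all(abs(cols - 16.5) <= 1.5))   # adjacent to the step column
  expect_setequal(unique(flags[, 1]), 2:31)   # spans all interior rows
  expect_equal(componentCount(em), 1)
})

test_that("an isolated impulse is rejected everywhere", {
  img <- matrix(0, 16, 16); img[8, 8] <- 255
  em <- detectEdges(img, cfg)
  expect_equal(edgeCount(em), 0)
  # and the brute-force per-pixel oracle agrees pixel for pixel
  expect_identical(em@.Data, naiveDetect(img, cfg)@.Data)
})

test_that("detection is invariant under a global intensity shift", {
  img <- randomGrey(20, 20, seed = 31) %/% 2   # range 0..127 leaves headroom
  for (k in c(30, 100, 128))
    expect_identical(detectEdges(img + k, cfg)@.Data,
                     detectEdges(img, cfg)@.Data)
})

test_that("mirroring the image mirrors the edge map under convention relabeling", {
  # The 12-rule base is directionally asymmetric (its Higher pairs favour the
  # NW/W quadrant), so a left-right mirror commutes with detection only after
  # the neighbour convention is mirrored too: NW<->NE, W<->E, SW<->SE.
  img <- randomGrey(18, 24, seed = 7)
  mirrorOrder <- c(NW = "NE", N = "N", NE = "NW", W = "E", E = "W",
                   SW = "SE", S = "S", SE = "SW")[cfg@neighborOrder]
  cfgM <- edgeDetectorConfig(neighborOrder = unname(mirrorOrder))
  a <- detectEdges(img, cfg)@.Data
  b <- detectEdges(img[, ncol(img):1], cfgM)@.Data
  expect_identical(b[, ncol(b):1], a)
  expect_equal(sum(a), sum(b))
})

test_that("the vectorized detector equals the naive per-pixel oracle", {
  for (seed in c(1, 2, 3)) {
    img <- randomGrey(16, 16, seed)
    expect_identical(detectEdges(img, cfg)@.Data, naiveDetect(img, cfg)@.Data)
  }
})

test_that("raising the threshold never adds edge pixels", {
  img <- randomGrey(24, 24, seed = 13)
  maps <- lapply(c(40, 100, 127.5, 180, 240), function(th)
    detectEdges(img, edgeDetectorConfig(threshold = th))@.Data)
  for (i in seq_len(length(maps) - 1))
    expect_true(all(maps[[i]] | !maps[[i + 1]]))  # map[i+1] subset of map[i]
})

test_that("images smaller than the mask are refused", {
  expect_error(detectEdges(matrix(0, 2, 2)), "3x3")
  expect_error(detectEdges(matrix(0, 3, 2)), "3x3")
})

test_that("the detector config validates its threshold and neighbours", {
  expect_error(edgeDetectorConfig(threshold = 5), "strictly between")
  expect_error(edgeDetectorConfig(threshold = 250), "strictly between")
  expect_error(edgeDetectorConfig(neighborOrder = rep("N", 8)), "permutation")
})

test_that("scores are NA on the border and finite inside", {
  sc <- edgeScores(randomGrey(8, 9, seed = 4), cfg)
  expect_true(all(is.na(sc[c(1, 8), ])) && all(is.na(sc[, c(1, 9)])))
  inner <- sc[2:7, 2:8]
  expect_true(all(is.finite(inner)))
  expect_true(all(inner >= 0 & inner <= 255))
})
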