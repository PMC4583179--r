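test_that("8-connected labelling merges diagonal touches, 4-connected does not", {
  m <- matrix(FALSE, 7, 7)
  m[2, 2] <- m[3, 3] <- m[5, 5] <- TRUE
  expect_equal(componentCount(m, 8), 2)
  expect_equal(componentCount(m, 4), 3)
  ring <- matrix(FALSE, 6, 6)
  ring[2:5, 2:5] <- TRUE; ring[3:4, 3:4] <- FALSE
  expect_equal(componentCount(ring, 8), 1)
  expect_equal(max(labelComponents(matrix(FALSE, 4, 4))), 0)
})

test_that("false edge pixels are those flagged outside the reference", {
  ref <- edgeMap(matrix(FALSE, 10, 10))
  allOn <- matrix(TRUE, 10, 10)
  expect_equal(falseEdgeCount(allOn, ref), 64)      # (10-2)^2 interior pixels
  expect_equal(falseEdgeCount(ref, ref), 0)
  sub <- matrix(FALSE, 10, 10); sub[4, 4] <- TRUE
  full <- matrix(FALSE, 10, 10); full[4, 3:6] <- TRUE
  expect_equal(falseEdgeCount(sub, full), 0)        # subset of the reference
  expect_equal(falseEdgeCount(full, sub), 3)
  expect_error(falseEdgeCount(matrix(FALSE, 4, 4), matrix(FALSE, 5, 5)),
               "same shape")
})

test_that("detected pixels partition into hits and false edges", {
  set.seed(17)
  for (i in 1:10) {
    d <- edgeMap(matrix(runif(400) < 0.3, 20, 20))
    r <- edgeMap(matrix(runif(400) < 0.3, 20, 20))
    hits <- sum(d@.Data & r@.Data)
    expect_equal(falseEdgeCount(d, r) + hits, edgeCount(d))
  }
})

test_that("a one-pixel tolerance band forgives adjacent flags", {
  ref <- matrix(FALSE, 12, 12); ref[6, 3:10] <- TRUE
  det <- matrix(FALSE, 12, 12); det[7, 3:10] <- TRUE   # shifted one row
  expect_equal(falseEdgeCount(det, ref), 8)
  expect_equal(falseEdgeCount(det, ref, tolerance = 1), 0)
})

test_that("confusion metrics reproduce hand-built tables", {
  truth <- matrix(FALSE, 12, 12); truth[4, 2:11] <- TRUE
  perfect <- confusionMetrics(truth, truth)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  interior <- matrix(FALSE, 12, 12); interior[2:11, 2:11] <- TRUE
  compl <- confusionMetrics(!truth & interior, truth)
  expect_equal(compl$sensitivity, 0)                  # complement finds nothing
  expect_lt(compl$specificity, 100)
  # 100 true edge pixels, 89 found, 400 of the 10000 non-edge pixels
  # falsely flagged -> sensitivity 89%, specificity 96%
  tr <- matrix(FALSE, 101, 100)
  tr[10, 2:51] <- TRUE; tr[12, 2:51] <- TRUE          # 100 truth pixels
  det <- matrix(FALSE, 101, 100)
  det[10, 2:45] <- TRUE; det[12, 2:46] <- TRUE        # 89 of them found
  det[30:37, 2:51] <- TRUE                            # 400 false positives
  cm <- confusionMetrics(det, tr)
  expect_equal(cm$tp, 89)
  expect_equal(cm$fp, 400)
  expect_equal(cm$sensitivity, 89)
  expect_equal(cm$specificity, 96)
})

test_that("sensitivity and specificity survive simultaneous mirroring", {
  set.seed(23)
  d <- matrix(runif(18 * 14) < 0.2, 18, 14)
  t <- matrix(runif(18 * 14) < 0.2, 18, 14)
  a <- confusionMetrics(edgeMap(d), edgeMap(t))
  b <- confusionMetrics(edgeMap(d[, 14:1]), edgeMap(t[, 14:1]))
  expect_equal(a$sensitivity, b$sensitivity)
  expect_equal(a$specificity, b$specificity)
})

test_that("runComparison reports per detector and is seed-deterministic", {
  fx <- makeRainbow(width = 80, height = 60, bandHeight = 8)
  empty <- runComparison(fx, targetDb = 25, detectors = character(), seed = 1)
  expect_equal(nrow(empty), 0)
  rep1 <- runComparison(fx, targetDb = 25,
                        detectors = c("fuzzy", "sobel"), seed = 4)
  rep2 <- runComparison(fx, targetDb = 25,
                        detectors = c("fuzzy", "sobel"), seed = 4)
  expect_identical(rep1, rep2)
  expect_setequal(rep1$detector, c("fuzzy", "sobel"))
  expect_true(all(rep1$falseEdges >= 0))
  expect_s4_class(attr(rep1, "noise"), "NoiseReport")
  expect_lt(abs(attr(rep1, "noise")@psnr - 25), 0.25)
  expect_error(runComparison(fx, detectors = "kirsch", seed = 1), "unknown")
})
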