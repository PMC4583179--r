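test_that("trapezoidal degrees follow the piecewise-linear closed form", {
  lower <- trapezoidalMF(0, 0, 25, 75)
  higher <- trapezoidalMF(25, 75, 255, 255)
  expect_equal(memberDegree(lower, 0), 1)            # degenerate left plateau
  expect_equal(memberDegree(lower, 50), 0.5)         # midpoint of fall 25->75
  expect_equal(memberDegree(lower, 25), 1)
  expect_equal(memberDegree(lower, 75), 0)
  expect_equal(memberDegree(higher, 25), 0)
  expect_equal(memberDegree(higher, 50), 0.5)
  expect_equal(memberDegree(higher, 255), 1)
  # vectorized evaluation; below r the raw MF is 0 even with a degenerate
  # left plateau (clamping to the universe happens at the FuzzySet level)
  expect_equal(memberDegree(lower, c(-10, 0, 50, 100)), c(0, 1, 0.5, 0))
})

test_that("Gaussian degrees follow exp(-(w-m)^2 / 2d^2)", {
  g <- gaussianMF(245, 3.5)
  expect_identical(memberDegree(g, 245), 1)          # exactly 1 at the centre
  expect_equal(memberDegree(g, 248.5), exp(-0.5), tolerance = 1e-14)
  # positive off-centre (far tails underflow to 0 in double precision)
  expect_true(all(memberDegree(g, seq(200, 255)) > 0))
})

test_that("invalid membership parameters are rejected at construction", {
  expect_error(trapezoidalMF(10, 5, 25, 75), "r <= s <= t <= u")
  expect_error(trapezoidalMF(0, 0, 80, 75), "r <= s <= t <= u")
  expect_error(gaussianMF(100, 0), "d must")
  expect_error(gaussianMF(100, -2), "d must")
  # degenerate plateaus are legal and evaluate without NaN
  sq <- trapezoidalMF(10, 10, 10, 10)
  expect_identical(memberDegree(sq, 10), 1)
  expect_identical(memberDegree(sq, 9.999), 0)
})

test_that("fuzzy sets clamp evaluation to their universe", {
  s <- fuzzySet("Higher", trapezoidalMF(25, 75, 255, 255), c(0, 255))
  expect_equal(memberDegree(s, 1e6), memberDegree(s, 255))
  expect_equal(memberDegree(s, -1e6), memberDegree(s, 0))
})

test_that("degrees are bounded in [0,1] over random valid parameters", {
  set.seed(42)
  w <- runif(200, -1000, 1000)
  for (i in 1:25) {
    p <- sort(runif(4, -50, 300))
    tz <- trapezoidalMF(p[1], p[2], p[3], p[4])
    dg <- memberDegree(tz, w)
    expect_true(all(dg >= 0 & dg <= 1))
    g <- gaussianMF(runif(1, 0, 255), runif(1, 0.5, 50))
    dg <- memberDegree(g, w)
    expect_true(all(dg >= 0 & dg <= 1))   # far tails may underflow to 0
  }
})

test_that("mfCenter reports the peak location", {
  expect_equal(mfCenter(gaussianMF(245, 3.5)), 245)
  expect_equal(mfCenter(trapezoidalMF(0, 0, 25, 75)), 12.5)
  expect_equal(mfCenter(fuzzySet("x", gaussianMF(10, 3.5))), 10)
})
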