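test_that("salt-and-pepper corruption follows its binomial contract", {
  img <- makeUniform(64, 64, 128)@image
  expect_identical(addSaltPepper(img, 0, seed = 1)@.Data, img@.Data)
  all <- addSaltPepper(img, 1, seed = 1)@.Data
  expect_true(all(all %in% c(0, 255)))
  # corrupted-pixel count within 3 sigma of the binomial mean at p = 0.1
  big <- makeUniform(512, 512, 128)@image
  noisy <- addSaltPepper(big, 0.1, seed = 2)
  k <- sum(noisy@.Data != big@.Data)
  n <- 512 * 512
  expect_lt(abs(k - n * 0.1), 3 * sqrt(n * 0.1 * 0.9))
  # same seed, same pattern; caller's RNG stream untouched
  set.seed(77); before <- runif(1)
  set.seed(77)
  a <- addSaltPepper(img, 0.3, seed = 5)
  expect_identical(runif(1), before)
  expect_identical(a@.Data, addSaltPepper(img, 0.3, seed = 5)@.Data)
})

test_that("empirical MSE under salt-and-pepper matches the closed form", {
  # uniform mid-grey 128: E[sq diff | corrupted] = (128^2 + 127^2)/2
  img <- makeUniform(512, 512, 128)@image
  noisy <- addSaltPepper(img, 0.1, seed = 3)
  expected <- 0.1 * (128^2 + 127^2) / 2
  expect_lt(abs(mse(img, noisy) - expected) / expected, 0.02)
})

test_that("mse matches hand values and validates shape", {
  a <- matrix(0, 512, 512)
  b <- a; b[100, 200] <- 255
  expect_equal(mse(a, a), 0)
  expect_equal(mse(a, b), 255^2 / (512 * 512))
  expect_equal(mse(matrix(0, 8, 8), matrix(255, 8, 8)), 65025)
  expect_equal(mse(a, b), mse(b, a))                       # symmetry
  expect_error(mse(matrix(0, 4, 4), matrix(0, 4, 5)), "same shape")
})

test_that("psnr follows 10 log10(255^2 / MSE)", {
  z <- matrix(0, 8, 8)
  expect_equal(psnr(z, matrix(255, 8, 8)), 0)               # MSE = Qp^2
  a <- matrix(0, 512, 512); b <- a; b[1, 2] <- 255
  expect_equal(psnr(a, b), 10 * log10(65025 / (255^2 / 262144)))
  expect_equal(psnr(a, b), 54.185, tolerance = 1e-4)
  expect_error(psnr(a, a), "undefined")
  # strictly decreasing in MSE
  m <- c(1, 10, 100, 1000)
  v <- 10 * log10(255^2 / m)
  expect_true(all(diff(v) < 0))
})

test_that("density calibration realizes the target PSNR within tolerance", {
  img <- makeUniform(512, 512, 128)@image
  cal <- calibrateDensity(img, targetDb = 25, seed = 11)
  expect_lt(abs(cal$report@psnr - 25), 0.25)
  expect_equal(psnr(img, cal$image), cal$report@psnr)       # report is honest
  small <- makeSmoothPhantom(270, 290)@image
  cal24 <- calibrateDensity(small, targetDb = 24, seed = 12)
  expect_lt(abs(cal24$report@psnr - 24), 0.25)
  expect_equal(cal24$report@seed, 12)
})

test_that("an infinite tolerance accepts the first probe", {
  img <- makeUniform(32, 32, 128)@image
  cal <- calibrateDensity(img, targetDb = 25, tolDb = Inf, seed = 1)
  expect_equal(cal$density, 0.5)
})

test_that("unreachable targets are reported as non-bracketable", {
  img <- makeUniform(64, 64, 128)@image
  expect_error(calibrateDensity(img, targetDb = 1, seed = 1), "not bracketable")
})
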