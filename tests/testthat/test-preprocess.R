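test_that("zero-variance noise is the identity and draws are seeded", {
  ph <- generatePhantom(64, seed = 2)
  img <- grayImage(ph)
  expect_identical(addGaussianNoise(img, 0, 7)@.Data, img@.Data)
  a <- addGaussianNoise(img, 0.01, seed = 11)
  b <- addGaussianNoise(img, 0.01, seed = 11)
  expect_identical(a@.Data, b@.Data)
  expect_false(identical(a@.Data, addGaussianNoise(img, 0.01, seed = 12)@.Data))
  expect_error(addGaussianNoise(img, -0.1), ">= 0")
})

test_that("injected noise has the requested variance", {
  img <- GrayImage(matrix(0.5, 256, 256))
  out <- addGaussianNoise(img, 0.02, seed = 3)
  # chi-square bounds at n = 65536 give about +/- 1% around 0.02
  expect_gt(var(as.vector(out@.Data - 0.5)), 0.018)
  expect_lt(var(as.vector(out@.Data - 0.5)), 0.022)
})

test_that("Wiener filter is the identity on constant images", {
  img <- GrayImage(matrix(0.4, 16, 16))
  expect_equal(wienerDenoise(img, 3)@.Data, img@.Data, tolerance = 1e-10)
  expect_error(wienerDenoise(img, 4), "odd")
})

test_that("Wiener filter reduces residual variance at all studied noise levels", {
  img <- GrayImage(matrix(0.5, 128, 128))
  for (v in c(0.005, 0.01, 0.02)) {
    noisy <- addGaussianNoise(img, v, seed = 7)
    den <- wienerDenoise(noisy, 3)
    expect_lt(var(as.vector(den@.Data - 0.5)), v)
  }
})

test_that("Wiener filter preserves a clean step edge away from the transition band", {
  m <- cbind(matrix(0.2, 16, 8), matrix(0.8, 16, 8))
  out <- wienerDenoise(GrayImage(m), 3)@.Data
  away <- c(1:7, 10:16)  # columns more than 1 px from the 8|9 edge
  expect_lt(max(abs(out[, away] - m[, away])), 0.05)
})

test_that("opening matches the brute-force footprint-scan oracle", {
  elem <- structuringElement(2)
  # single isolated pixel vanishes
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_false(any(morphOpen(BinaryMask(single), elem)@.Data))
  # filled square: corners round by at most 4 px^2 each
  sq <- matrix(FALSE, 28, 28); sq[5:24, 5:24] <- TRUE
  op <- morphOpen(BinaryMask(sq), elem)@.Data
  expect_identical(op, bruteOpen(sq, elem@footprint))
  expect_true(all(op[!sq] == FALSE))
  expect_lte(sum(sq) - sum(op), 4 * 4)
  # random masks, both shapes
  for (s in 1:5) {
    m <- randomMask(15, 17, p = 0.6, seed = s)
    for (shape in c("disk", "square")) {
      el <- structuringElement(1 + s %% 2, shape)
      expect_identical(morphOpen(BinaryMask(m), el)@.Data,
                       bruteOpen(m, el@footprint))
    }
  }
})

test_that("opening is anti-extensive, increasing and idempotent", {
  elem <- structuringElement(2)
  for (s in 1:20) {
    m <- randomMask(20, 20, p = 0.6, seed = 100 + s)
    op <- morphOpen(BinaryMask(m), elem)@.Data
    expect_true(all(op <= m))                          # anti-extensive
    expect_identical(morphOpen(BinaryMask(op), elem)@.Data, op)  # idempotent
    m2 <- m | randomMask(20, 20, p = 0.2, seed = 200 + s)
    op2 <- morphOpen(BinaryMask(m2), elem)@.Data
    expect_true(all(op <= op2))                        # increasing
  }
})

test_that("hole filling matches the flood-fill oracle and its laws", {
  # annulus -> filled disk
  off <- seq(-10, 10)
  rr <- sqrt(outer(off^2, off^2, "+"))
  ring <- rr <= 9 & rr >= 6
  expect_identical(fillHoles(BinaryMask(ring))@.Data, rr <= 9)
  # two nested rings -> fully filled outer disk
  nested <- (rr <= 9 & rr >= 7) | (rr <= 4 & rr >= 2.5)
  filled <- fillHoles(BinaryMask(nested))@.Data
  expect_identical(filled, bruteFillHoles(nested))
  expect_identical(filled, rr <= 9)
  # no holes -> identity; extensive + idempotent on random masks
  for (s in 1:20) {
    m <- randomMask(18, 18, p = 0.4, seed = 300 + s)
    f <- fillHoles(BinaryMask(m))@.Data
    expect_identical(f, bruteFillHoles(m))
    expect_true(all(m <= f))
    expect_identical(fillHoles(BinaryMask(f))@.Data, f)
  }
})

test_that("skull stripping removes the skull ring and keeps the parenchyma", {
  ph <- generatePhantom(256, noiseVar = 0, seed = 4)
  den <- wienerDenoise(grayImage(ph), 3)
  res <- skullStrip(den, structuringElement(5))
  lab <- labelMap(ph)@.Data
  got <- res$mask@.Data
  expect_equal(sum(got & lab == 1L), 0)           # no skull pixels
  expect_equal(sum(got & lab == 0L), 0)           # no background pixels
  truth <- brainMask(ph)@.Data
  expect_gte(sum(got & truth) / sum(truth), 0.99) # >= 99% of brain kept
  # masked image is zero outside the mask
  expect_true(all(res$image@.Data[!got] == 0))
})

test_that("opening leaves a large filled disk unchanged", {
  off <- seq(-15, 15)
  disk <- sqrt(outer(off^2, off^2, "+")) <= 12
  elem <- structuringElement(3)
  expect_identical(morphOpen(BinaryMask(disk), elem)@.Data, disk)
})

test_that("an all-zero image yields a no-head error", {
  img <- GrayImage(matrix(0, 64, 64))
  expect_error(skullStrip(img), "no head detected")
})
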