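test_that("Gaussian kernel has its defining properties", {
  expect_equal(gaussianKernel(0, 1, 0.5), exp(-1))
  set.seed(1)
  a <- runif(20); b <- runif(20)
  expect_equal(gaussianKernel(a, a, 0.3), rep(1, 20))   # K(x, x) = 1
  expect_equal(gaussianKernel(a, b, 0.3), gaussianKernel(b, a, 0.3))
  expect_true(all(gaussianKernel(a, b, 0.3) > 0 & gaussianKernel(a, b, 0.3) <= 1))
  expect_error(gaussianKernel(0, 1, 0), "sigma2")
})

test_that("K-means++ picks the farthest value deterministically after the first draw", {
  x <- c(0, 0, 0, 10, 10, 10, 5)
  for (s in 1:10) {
    ctr <- kmeansppInit(x, 2, seed = s)
    # oracle: brute-force farthest point from whichever first center was drawn
    d2 <- (sort(unique(x)) - ctr[1])^2
    expect_equal(ctr[2], sort(unique(x))[which.max(d2)])
  }
  # forced outcome: two distinct values, k = 2
  for (s in 1:5) expect_setequal(kmeansppInit(c(0, 1, 0, 1), 2, seed = s), c(0, 1))
  # k = 1: a single seeded pick, reproducible
  expect_identical(kmeansppInit(x, 1, seed = 3), kmeansppInit(x, 1, seed = 3))
  expect_error(kmeansppInit(c(1, 1, 1), 2), "degenerate")
})

test_that("Lloyd refinement reaches the analytic fixed point", {
  v <- kmeansRefine(c(0, 0.1, 0.9, 1.0), c(0, 1))
  expect_equal(sort(v), c(0.05, 0.95))
  # init already at the fixed point stays put
  expect_equal(kmeansRefine(c(0, 0.1, 0.9, 1.0), c(0.05, 0.95)), c(0.05, 0.95))
})

test_that("K-means++ plus Lloyd attains the exhaustive brute-force optimum", {
  x <- c(0.05, 0.10, 0.12, 0.15, 0.45, 0.50, 0.52, 0.55, 0.85, 0.90, 0.92, 0.95)
  # enumerate all 3^12 assignments and find the minimal within-cluster SS
  G <- as.matrix(expand.grid(rep(list(1:3), 12)))
  total <- 0
  for (c in 1:3) {
    M <- (G == c) * 1
    n <- rowSums(M)
    s <- as.vector(M %*% x)
    ss <- as.vector(M %*% x^2)
    w <- ss - ifelse(n > 0, s^2 / pmax(n, 1), 0)
    w[n == 0] <- 0
    total <- total + w
  }
  best <- G[which.min(total), ]
  bestCenters <- sort(tapply(x, best, mean))
  for (s in 1:5) {
    v <- kmeansRefine(x, kmeansppInit(x, 3, seed = s))
    expect_equal(sort(v), as.vector(bestCenters))
  }
})

test_that("GKFCM membership matches the closed form and its conventions", {
  # hand-evaluated closed form at x = 0.4, centroids {0.2, 0.8}
  u <- gkfcmMembership(0.4, c(0.2, 0.8), sigma2 = 0.1, fuzzyIndex = 2)
  d1 <- 1 - exp(-(0.4 - 0.2)^2 / 0.2)
  d2 <- 1 - exp(-(0.4 - 0.8)^2 / 0.2)
  expect_equal(u[1, 1] / u[1, 2], d2 / d1)
  expect_equal(sum(u), 1)
  # equidistant pixel splits evenly
  expect_equal(as.vector(gkfcmMembership(0.5, c(0.2, 0.8), 0.1)), c(0.5, 0.5))
  # pixel at a centroid is crisp
  u <- gkfcmMembership(0.2, c(0.2, 0.8, 0.5), 0.1)
  expect_equal(as.vector(u), c(1, 0, 0))
  # lowest index wins on simultaneous exact matches (shared update core)
  d0 <- matrix(c(0, 0.5, 0), 1)
  expect_equal(as.vector(BrainTumorKFCM:::membershipFromDist(d0, 2)), c(1, 0, 0))
  expect_error(gkfcmMembership(0.5, c(0.3, 0.3), 0.1), "degenerate")
})

test_that("GKFCM centroid update matches a term-by-term oracle", {
  set.seed(42)
  x <- runif(20)
  vPrev <- c(0.2, 0.5, 0.8)
  u <- gkfcmMembership(x, vPrev, 0.1, 2)
  got <- gkfcmCentroids(x, u, vPrev, 0.1, 2)
  for (i in 1:3) {
    num <- den <- 0
    for (j in 1:20) {
      kj <- exp(-(x[j] - vPrev[i])^2 / (2 * 0.1))
      num <- num + u[j, i]^2 * kj * x[j]
      den <- den + u[j, i]^2 * kj
    }
    expect_equal(got[i], num / den)
  }
})

test_that("crisp memberships with a flat kernel reduce to plain means", {
  x <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  u <- cbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  v <- gkfcmCentroids(x, u, c(0.2, 0.8), sigma2 = 1e12, fuzzyIndex = 2)
  expect_equal(v, c(0.2, 0.8), tolerance = 1e-9)
  # single pixel per cluster: centroid moves onto the pixel
  v1 <- gkfcmCentroids(c(0.3, 0.6), diag(2), c(0.1, 0.9), 0.1, 2)
  expect_equal(v1, c(0.3, 0.6))
})

test_that("gkfcmFit recovers two well-separated blobs exactly", {
  set.seed(8)
  x <- c(rnorm(100, 0.1, 0.01), rnorm(100, 0.9, 0.01))
  fit <- gkfcmFit(x, segConfig(k = 2, seed = 8))
  expect_true(converged(fit))
  v <- centroids(fit)
  expect_equal(sort(v), c(mean(x[1:100]), mean(x[101:200])), tolerance = 0.02)
  lab <- labels(fit)
  expect_equal(length(unique(lab[1:100])), 1L)
  expect_equal(length(unique(lab[101:200])), 1L)
  expect_false(lab[1] == lab[101])
})

test_that("a very large epsilon stops after exactly one iteration", {
  set.seed(3)
  x <- runif(100)
  fit <- gkfcmFit(x, segConfig(k = 3, epsilon = 1e6, seed = 3))
  expect_equal(nIter(fit), 1L)
  expect_length(objectiveTrace(fit), 2L)  # J at init + one iteration
})

test_that("repeated runs under one seed are bit-identical", {
  set.seed(10)
  x <- runif(400)
  cfg <- segConfig(k = 4, seed = 5)
  ref <- gkfcmFit(x, cfg)
  for (r in 1:9) {
    fit <- gkfcmFit(x, cfg)
    expect_identical(labels(fit), labels(ref))
    expect_identical(centroids(fit), centroids(ref))
    expect_identical(membership(fit), membership(ref))
  }
})

test_that("pixel order never changes the label map", {
  set.seed(11)
  x <- runif(300)
  cfg <- segConfig(k = 4, seed = 2)
  ref <- gkfcmFit(x, cfg)
  for (s in 1:3) {
    perm <- sample(length(x))
    fit <- gkfcmFit(x[perm], cfg)
    expect_identical(labels(fit), labels(ref)[perm])
    expect_identical(centroids(fit), centroids(ref))
  }
})

test_that("membership rows stay stochastic throughout the iteration", {
  for (s in 1:5) {
    set.seed(s)
    x <- runif(200)
    cfg <- segConfig(k = 4, seed = s)
    v <- kmeansRefine(x, kmeansppInit(x, 4, s))
    for (it in 1:15) {
      u <- gkfcmMembership(x, v, cfg@sigma2, cfg@fuzzyIndex)
      expect_lt(max(abs(rowSums(u) - 1)), 1e-9)
      expect_true(all(u >= 0 & u <= 1))
      v <- gkfcmCentroids(x, u, v, cfg@sigma2, cfg@fuzzyIndex)
    }
  }
})

test_that("the objective trace is nonincreasing", {
  for (s in 1:5) {
    set.seed(20 + s)
    x <- c(rnorm(150, 0.3, 0.05), rnorm(150, 0.7, 0.05))
    fit <- gkfcmFit(x, segConfig(k = 3, seed = s, epsilon = 1e-9))
    J <- objectiveTrace(fit)
    expect_true(all(diff(J) <= 1e-12 * pmax(abs(J[-length(J)]), 1)))
  }
})

test_that("classical FCM behaves as its closed-form fixed points dictate", {
  # two-point problem converges to centroids {0, 1}
  fit <- fcmFit(c(0, 1), segConfig(k = 2, seed = 1))
  expect_equal(sort(centroids(fit)), c(0, 1), tolerance = 1e-6)
  # symmetric blobs give memberships symmetric under blob swap
  x <- c(0.2, 0.25, 0.75, 0.8)
  fit <- fcmFit(x, segConfig(k = 2, seed = 1))
  u <- membership(fit)
  lo <- order(centroids(fit))
  expect_equal(u[1, lo], rev(u[4, lo]))
  expect_equal(u[2, lo], rev(u[3, lo]))
})

test_that("GKFCM collapses to FCM in the flat-kernel limit", {
  set.seed(13)
  x <- runif(200)
  # the kernel objective is ~sigma2 times smaller than the Euclidean one,
  # so both fits get a tolerance far below either scale and iterate to
  # their actual fixed points before being compared
  cfgG <- segConfig(k = 3, sigma2 = 1e6, epsilon = 1e-20, maxIter = 300, seed = 13)
  cfgF <- segConfig(k = 3, epsilon = 1e-20, maxIter = 300, seed = 13)
  uG <- membership(gkfcmFit(x, cfgG))
  uF <- membership(fcmFit(x, cfgF))
  expect_lt(max(abs(uG - uF)), 1e-4)
})

test_that("hard K-means baseline returns crisp labels at the Lloyd solution", {
  set.seed(14)
  x <- c(rnorm(50, 0.2, 0.02), rnorm(50, 0.8, 0.02))
  fit <- kmeansFit(x, segConfig(k = 2, seed = 14))
  u <- membership(fit)
  expect_true(all(u %in% c(0, 1)))
  expect_equal(rowSums(u), rep(1, 100))
  expect_equal(sort(centroids(fit)),
               sort(as.vector(tapply(x, labels(fit), mean))), tolerance = 1e-9)
})
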