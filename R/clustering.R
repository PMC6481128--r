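# Stage 2: the K++GKFCM optimizer and its baselines.
#
# Clustering operates on the scalar intensities of the in-mask pixels.
# The objective is J = 2 * sum_i sum_j u_ij^n (1 - K(x_j, v_i)) with the
# Gaussian kernel K(x, y) = exp(-(x - y)^2 / (2 sigma^2)), minimized
# under the row-stochastic membership constraint by alternating the
# closed-form membership update and the kernel-weighted centroid
# fixed-point update. The centroid step is a majorize-minimize step
# (1 - exp(-t) is concave in t = (x - v)^2, so the kernel-weighted mean
# minimizes a linear majorizer at the previous centroid), hence J is
# nonincreasing across iterations.

#' Gaussian kernel on the intensity line
#'
#' `K(x, y) = exp(-(x - y)^2 / (2 sigma2))`; symmetric, in (0, 1], and
#' equal to 1 exactly when `x == y`.
#'
#' @param x,y numeric intensities (vectorized).
#' @param sigma2 kernel width sigma^2 > 0.
#' @return kernel values in (0, 1\].
#' @examples
#' gaussianKernel(0, 1, 0.5)  # exp(-1)
#' @export
gaussianKernel <- function(x, y, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  exp(-(x - y)^2 / (2 * sigma2))
}

#' Deterministic K-means++ centroid initialization
#'
#' Only the first center is random: it is drawn with the seeded RNG from
#' the sorted unique intensity values (drawing by value rather than by
#' pixel position makes the result invariant to pixel order). Every
#' further center is chosen deterministically as the value maximizing
#' `D(x)^2 / sum D(x)^2`, where `D(x)` is the distance to the nearest
#' already-chosen center — the farthest-point rule; ties go to the
#' smallest value. This deterministic selection is what stabilizes the
#' downstream fuzzy clustering: repeated runs with one seed always start
#' from the same, well-spread centroids.
#'
#' @param x numeric vector of pixel intensities.
#' @param k number of centers; `x` must contain at least `k` distinct
#'   values.
#' @param seed integer seed for the first draw.
#' @return numeric vector of k initial centers.
#' @export
kmeansppInit <- function(x, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  uv <- sort(unique(as.numeric(x)))
  if (length(uv) < k)
    stop("degenerate input: fewer than k distinct intensity values")
  centers <- uv[withSeed(seed, sample.int(length(uv), 1L))]
  d2 <- (uv - centers[1])^2
  while (length(centers) < k) {
    nxt <- uv[which.max(d2)]   # which.max -> first (smallest) on ties
    centers <- c(centers, nxt)
    d2 <- pmin(d2, (uv - nxt)^2)
  }
  centers
}

#' Lloyd refinement of initial centers
#'
#' Standard K-means iterations on scalar intensities: assign each pixel
#' to its nearest center (ties to the lowest index), recompute the means,
#' repeat until the assignment is stable or `maxIter` is reached. A
#' cluster left empty keeps its previous center.
#'
#' @param x numeric vector of pixel intensities.
#' @param centers numeric vector of distinct initial centers.
#' @param maxIter iteration cap.
#' @return numeric vector of refined centers (same length as `centers`).
#' @export
kmeansRefine <- function(x, centers, maxIter = 100L) {
  # reductions run over value-sorted pixels so the result (and every
  # float rounding in it) is independent of pixel order
  x <- sort(as.numeric(x))
  if (anyDuplicated(centers)) stop("initial centers must be distinct")
  v <- centers
  assign <- integer(length(x))
  for (it in seq_len(maxIter)) {
    newAssign <- max.col(-abs(outer(x, v, "-")), ties.method = "first")
    if (identical(newAssign, assign)) break
    assign <- newAssign
    for (i in seq_along(v)) {
      xi <- x[assign == i]
      if (length(xi)) v[i] <- mean(xi)
    }
  }
  v
}

# membership update shared by GKFCM (dist = 1 - K) and FCM (dist = d^2).
# u_ij = dist_ij^(-1/(n-1)) / sum_k dist_ik^(-1/(n-1)); a pixel lying
# exactly on a centroid (dist 0) gets crisp membership in that cluster
# (lowest index on multiple exact matches).
membershipFromDist <- function(dist, n) {
  p <- 1 / (n - 1)
  w <- dist^(-p)
  u <- w / rowSums(w)
  bad <- which(rowSums(dist == 0) > 0L | !is.finite(rowSums(w)))
  if (length(bad)) {
    pick <- apply(dist[bad, , drop = FALSE], 1, which.min)
    u[bad, ] <- 0
    u[cbind(bad, pick)] <- 1
  }
  u
}

#' GKFCM membership update
#'
#' Closed-form minimizer of the kernel objective over the memberships for
#' fixed centroids:
#' `u_ij = (1 - K(x_j, v_i))^(-1/(n-1)) / sum_k (1 - K(x_j, v_k))^(-1/(n-1))`.
#' Rows sum to 1. A pixel exactly at a centroid takes crisp membership 1
#' in that cluster (lowest index if it matches several).
#'
#' @param x numeric vector of N pixel intensities.
#' @param centroids numeric vector of k distinct centroids.
#' @param sigma2 Gaussian kernel width > 0.
#' @param fuzzyIndex fuzzifier n > 1.
#' @return N x k membership matrix.
#' @export
gkfcmMembership <- function(x, centroids, sigma2, fuzzyIndex = 2) {
  if (anyDuplicated(centroids)) stop("degenerate centroids: duplicates")
  d <- 1 - gaussianKernel(outer(as.numeric(x), centroids, "-"), 0, sigma2)
  membershipFromDist(d, fuzzyIndex)
}

#' GKFCM centroid update
#'
#' Kernel-weighted fixed-point step derived from the stationarity of the
#' kernel objective:
#' `v_i = sum_j u_ij^n K(x_j, v_i) x_j / sum_j u_ij^n K(x_j, v_i)`,
#' with the kernel evaluated at the previous centroids. An all-zero
#' denominator keeps the previous centroid.
#'
#' @param x numeric vector of N pixel intensities.
#' @param u N x k membership matrix (rows sum to 1).
#' @param centroidsPrev numeric vector of k previous centroids.
#' @param sigma2 Gaussian kernel width > 0.
#' @param fuzzyIndex fuzzifier n > 1.
#' @return numeric vector of k updated centroids.
#' @export
gkfcmCentroids <- function(x, u, centroidsPrev, sigma2, fuzzyIndex = 2) {
  x <- as.numeric(x)
  K <- gaussianKernel(outer(x, centroidsPrev, "-"), 0, sigma2)
  w <- u^fuzzyIndex * K
  den <- colSums(w)
  num <- colSums(w * x)
  ifelse(den > 0, num / den, centroidsPrev)
}

objectiveGK <- function(x, u, v, sigma2, n) {
  d <- 1 - gaussianKernel(outer(as.numeric(x), v, "-"), 0, sigma2)
  2 * sum(u^n * d)
}

makeClusterResult <- function(x, u, v, trace, it, converged, method) {
  new("ClusterResult", centroids = v, membership = u,
      labels = max.col(u, ties.method = "first") - 1L,
      objective = trace, nIter = as.integer(it),
      converged = converged, method = method)
}

# Fit `fun` on value-sorted pixels and un-permute the per-pixel slots, so
# every reduction happens in one canonical order and the label map is
# bitwise invariant to pixel order.
fitSorted <- function(x, fun) {
  ord <- order(x)
  res <- fun(x[ord])
  u <- res@membership
  u[ord, ] <- res@membership
  lab <- res@labels
  lab[ord] <- res@labels
  initialize(res, membership = u, labels = lab)
}

#' Fit the K++GKFCM model
#'
#' The full clustering stage: centroids are initialized by deterministic
#' K-means++ ([kmeansppInit()]) and refined by K-means
#' ([kmeansRefine()]); the Gaussian-kernel fuzzy C-means updates
#' ([gkfcmMembership()], [gkfcmCentroids()]) are then alternated, the
#' objective J recorded each iteration, until `|J(i) - J(i-1)| <=
#' epsilon` or `maxIter`. The first element of the objective trace is J
#' at the initial centroids.
#'
#' @param x numeric vector of in-mask pixel intensities (at least `k`
#'   distinct values).
#' @param config a [SegConfig-class]; `k`, `fuzzyIndex`, `sigma2`,
#'   `epsilon`, `maxIter`, and `seed` are used.
#' @return a [ClusterResult-class]; centroids keep the initialization
#'   order (use [centroids()] and sort if a canonical order is needed).
#' @examples
#' x <- c(rnorm(100, 0.2, 0.01), rnorm(100, 0.8, 0.01))
#' fit <- gkfcmFit(x, segConfig(k = 2))
#' sort(centroids(fit))
#' @export
gkfcmFit <- function(x, config = segConfig()) {
  fitSorted(as.numeric(x), function(xs) gkfcmFitCore(xs, config))
}

gkfcmFitCore <- function(x, config) {
  n <- config@fuzzyIndex; s2 <- config@sigma2
  v <- kmeansRefine(x, kmeansppInit(x, config@k, config@seed), config@maxIter)
  v <- dedupeCentroids(v, x)
  u <- gkfcmMembership(x, v, s2, n)
  trace <- objectiveGK(x, u, v, s2, n)
  converged <- FALSE
  it <- 0L
  while (it < config@maxIter) {
    it <- it + 1L
    u <- gkfcmMembership(x, v, s2, n)
    v <- gkfcmCentroids(x, u, v, s2, n)
    v <- dedupeCentroids(v, x)
    trace <- c(trace, objectiveGK(x, u, v, s2, n))
    if (abs(trace[it + 1L] - trace[it]) <= config@epsilon) {
      converged <- TRUE
      break
    }
  }
  makeClusterResult(x, u, v, trace, it, converged, "kgkfcm")
}

# Guard against centroid collapse (duplicate centroids would make the
# membership update singular): nudge exact duplicates apart by one ulp of
# the data range. In practice K-means++ spreading prevents this.
dedupeCentroids <- function(v, x) {
  while (anyDuplicated(v)) {
    i <- anyDuplicated(v)
    v[i] <- v[i] + (max(x) - min(x) + 1) * .Machine$double.eps * i
  }
  v
}

#' Fit classical fuzzy C-means (baseline)
#'
#' Standard FCM on scalar intensities with squared Euclidean distances:
#' `u_ij = d_ij^(-2/(n-1)) / sum_k d_kj^(-2/(n-1))` and centroid
#' `v_i = sum u_ij^n x_j / sum u_ij^n`; objective
#' `J = sum_i sum_j u_ij^n (x_j - v_i)^2`. Initialization, stopping rule
#' and the result container match [gkfcmFit()] so the two are directly
#' comparable.
#'
#' @inheritParams gkfcmFit
#' @return a [ClusterResult-class].
#' @export
fcmFit <- function(x, config = segConfig()) {
  fitSorted(as.numeric(x), function(xs) fcmFitCore(xs, config))
}

fcmFitCore <- function(x, config) {
  n <- config@fuzzyIndex
  obj <- function(u, v) sum(u^n * outer(x, v, "-")^2)
  memb <- function(v) membershipFromDist(outer(x, v, "-")^2, n)
  v <- kmeansRefine(x, kmeansppInit(x, config@k, config@seed), config@maxIter)
  v <- dedupeCentroids(v, x)
  u <- memb(v)
  trace <- obj(u, v)
  converged <- FALSE
  it <- 0L
  while (it < config@maxIter) {
    it <- it + 1L
    u <- memb(v)
    w <- u^n
    den <- colSums(w)
    v <- ifelse(den > 0, colSums(w * x) / den, v)
    v <- dedupeCentroids(v, x)
    trace <- c(trace, obj(u, v))
    if (abs(trace[it + 1L] - trace[it]) <= config@epsilon) {
      converged <- TRUE
      break
    }
  }
  makeClusterResult(x, u, v, trace, it, converged, "fcm")
}

#' Fit hard K-means (baseline)
#'
#' K-means++ initialization followed by Lloyd refinement; returned as a
#' [ClusterResult-class] with crisp 0/1 memberships and the within-
#' cluster sum of squares as the objective.
#'
#' @inheritParams gkfcmFit
#' @return a [ClusterResult-class].
#' @export
kmeansFit <- function(x, config = segConfig()) {
  fitSorted(as.numeric(x), function(xs) kmeansFitCore(xs, config))
}

kmeansFitCore <- function(x, config) {
  v <- kmeansRefine(x, kmeansppInit(x, config@k, config@seed), config@maxIter)
  assign <- max.col(-abs(outer(x, v, "-")), ties.method = "first")
  u <- matrix(0, length(x), length(v))
  u[cbind(seq_along(x), assign)] <- 1
  wcss <- sum((x - v[assign])^2)
  makeClusterResult(x, u, v, wcss, 1L, TRUE, "kmeans")
}

#' Assemble a full-grid label map from a clustering of in-mask pixels
#'
#' @param fit a [ClusterResult-class] fitted on `img[mask]` intensities
#'   taken in column-major order.
#' @param mask the [BinaryMask-class] that selected those pixels.
#' @return a [LabelMap-class]: cluster ids inside the mask, -1 outside.
#' @export
labelsToMap <- function(fit, mask) {
  m <- asMaskMatrix(mask)
  lab <- array(-1L, dim(m))
  lab[m] <- fit@labels
  LabelMap(lab)
}
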