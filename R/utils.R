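# Internal helpers shared across modules.

# min-max normalization to [0,1]; constant input maps to all zeros
minmax01 <- function(m) {
  rng <- range(m)
  if (rng[1] == rng[2]) return(array(0, dim(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

# clip to [0,1] preserving matrix dims (pmin/pmax would drop them)
clip01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

# Run code with a fixed RNG seed, restoring the caller's RNG state after.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# box-filter local mean via EBImage FFT convolution, replicated borders
boxMean <- function(m, window) {
  kern <- matrix(1 / (window * window), window, window)
  EBImage::filter2(m, kern, boundary = "replicate")
}

# integer-valued box sum of a 0/1 matrix, outside-image = 0
boxSum0 <- function(m, window) {
  kern <- matrix(1, window, window)
  round(EBImage::filter2(m, kern, boundary = 0))
}

asMaskMatrix <- function(mask) {
  if (is(mask, "BinaryMask")) mask@.Data else {
    stopifnot(is.matrix(mask))
    mask != 0
  }
}

asImageMatrix <- function(img) {
  if (is(img, "GrayImage")) img@.Data else {
    stopifnot(is.matrix(img), is.numeric(img))
    img
  }
}

oddWindowCheck <- function(window) {
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  as.integer(window)
}
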