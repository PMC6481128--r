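# Independent brute-force oracles used to check the package's fast paths.

# random logical matrix
randomMask <- function(nr, nc, p = 0.5, seed = 1) {
  set.seed(seed)
  matrix(runif(nr * nc) < p, nr, nc)
}

# footprint-scan erosion: pixel survives iff every footprint offset lands
# on an in-image foreground pixel (outside-image counts as background)
bruteErode <- function(m, fp) {
  r <- (nrow(fp) - 1L) / 2L
  offs <- which(fp == 1, arr.ind = TRUE) - (r + 1L)
  out <- m & FALSE
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ii <- i + offs[, 1]; jj <- j + offs[, 2]
    inb <- ii >= 1 & ii <= nrow(m) & jj >= 1 & jj <= ncol(m)
    out[i, j] <- all(inb) && all(m[cbind(ii, jj)])
  }
  out
}

bruteDilate <- function(m, fp) {
  r <- (nrow(fp) - 1L) / 2L
  offs <- which(fp == 1, arr.ind = TRUE) - (r + 1L)
  out <- m & FALSE
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ii <- i + offs[, 1]; jj <- j + offs[, 2]
    inb <- ii >= 1 & ii <= nrow(m) & jj >= 1 & jj <= ncol(m)
    out[i, j] <- any(m[cbind(ii[inb], jj[inb])])
  }
  out
}

bruteOpen <- function(m, fp) bruteDilate(bruteErode(m, fp), fp)

# hole filling oracle: iteratively spread border-reachable background
# (4-connected background, the complement of 8-connected foreground)
bruteFillHoles <- function(m) {
  reach <- !m
  border <- matrix(FALSE, nrow(m), ncol(m))
  border[c(1, nrow(m)), ] <- TRUE; border[, c(1, ncol(m))] <- TRUE
  cur <- reach & border
  repeat {
    grown <- cur
    grown[-1, ] <- grown[-1, ] | cur[-nrow(m), ]
    grown[-nrow(m), ] <- grown[-nrow(m), ] | cur[-1, ]
    grown[, -1] <- grown[, -1] | cur[, -ncol(m)]
    grown[, -ncol(m)] <- grown[, -ncol(m)] | cur[, -1]
    grown <- grown & reach
    if (identical(grown, cur)) break
    cur <- grown
  }
  m | !cur
}

# per-pixel confusion tally + formula re-evaluation
bruteConfusion <- function(p, t) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(p)) {
    if (p[i] && t[i]) tp <- tp + 1L
    else if (!p[i] && !t[i]) tn <- tn + 1L
    else if (p[i] && !t[i]) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

phantomClassMeans <- c(0.25, 0.45, 0.65, 0.90)  # CSF, GM, WM, tumor
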