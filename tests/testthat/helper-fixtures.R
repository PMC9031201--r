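# Shared fixtures, built in code.

# isotropic Gaussian peak A * exp(-r^2 / (2 sigma^2)) on a zero background
gaussianPeakImage <- function(n = 101, cx = 51, cy = 51, A = 100,
                              sigma = 10, bits = 8L) {
  g <- outer(seq_len(n), seq_len(n), function(y, x)
    A * exp(-(((x - cx)^2 + (y - cy)^2)) / (2 * sigma^2)))
  GrayImage(pmin(g, 2^bits - 1), bits)
}

twoPeakImage <- function(n = 101) {
  pk <- function(cx, cy, A, s) outer(seq_len(n), seq_len(n), function(y, x)
    A * exp(-(((x - cx)^2 + (y - cy)^2)) / (2 * s^2)))
  GrayImage(pmin(pk(25, 25, 100, 7) + pk(76, 76, 90, 7), 255), 8L)
}

# axis-aligned square contour centred at (cx, cy) with half-side s
squareContour <- function(level, cx, cy, s) {
  IsoContour(level, cbind(c(cx - s, cx + s, cx + s, cx - s),
                          c(cy - s, cy - s, cy + s, cy + s)))
}

# regular polygon approximating a disc of radius r
discContour <- function(level, cx, cy, r, nv = 720L) {
  th <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  IsoContour(level, cbind(cx + r * cos(th), cy + r * sin(th)))
}

# small textured phantom with one sharp round mass, for fast detector tests
smallMassPhantom <- function(seed = 11L, densityClass = "B", shape = 160L) {
  composePhantom(PhantomSpec(
    shape = c(shape, shape), densityClass = densityClass,
    lesions = list(list(lesion_type = "round_oval_clear_border",
                        center = c(shape * 0.45, shape * 0.5),
                        size_px = shape * 0.22, contrast = 0.8)),
    noiseSigma = 1, textureStrength = 1, seed = seed))
}

emptyAnn <- function() NestedContours:::.emptyAnnotations()

# Independent oracle for chain linking: full containment matrix over all
# contour pairs, then the same greedy rule executed naively. Returns chains
# as integer index vectors.
# brute force: containment matrix over all contour pairs, then the same
# greedy rule executed naively
bruteForceChains <- function(contourList, k) {
  n <- length(contourList)
  if (n == 0L) return(list())
  lv <- vapply(contourList, level, numeric(1L))
  ar <- vapply(contourList, area, numeric(1L))
  M <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j)
      M[i, j] <- containsContour(contourList[[i]], contourList[[j]])
  ulev <- sort(unique(lv))
  chains <- list(); tips <- integer(0L); done <- list()
  for (jj in seq_along(ulev)) {
    cs <- which(abs(lv - ulev[jj]) < 1e-9)
    consecutive <- jj > 1L && abs(ulev[jj] - ulev[jj - 1L] - k) < k * 1e-6
    parent <- rep(NA_integer_, length(cs))
    if (consecutive && length(tips)) {
      for (ci in seq_along(cs)) {
        holds <- which(M[tips, cs[ci]])
        if (length(holds))
          parent[ci] <- holds[which.min(ar[tips[holds]])]
      }
    }
    newChains <- list(); newTips <- integer(0L)
    for (t in seq_along(tips)) {
      kids <- cs[which(parent == t)]
      if (!length(kids)) { done <- c(done, chains[t]); next }
      cenT <- centroid(contourList[[tips[t]]])
      sh <- vapply(kids, function(i)
        sqrt(sum((centroid(contourList[[i]]) - cenT)^2)), numeric(1L))
      best <- kids[order(-ar[kids], sh)][1L]
      newChains <- c(newChains, list(c(chains[[t]], best)))
      newTips <- c(newTips, best)
      for (r in setdiff(kids, best)) {
        newChains <- c(newChains, list(r)); newTips <- c(newTips, r)
      }
    }
    for (i in cs[is.na(parent)]) {
      newChains <- c(newChains, list(i)); newTips <- c(newTips, i)
    }
    chains <- newChains; tips <- newTips
  }
  c(done, chains)
}
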