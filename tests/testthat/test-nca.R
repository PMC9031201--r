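test_that("level contours of a Gaussian peak match the analytic radii", {
  im <- gaussianPeakImage()
  cs <- buildLevelContours(im, k = 10)
  expect_length(cs, 9L)
  expect_equal(vapply(cs, level, numeric(1L)), seq(10, 90, by = 10))
  # r(l) = sigma * sqrt(2 ln(A / l)) for A exp(-r^2 / (2 sigma^2))
  for (c in cs) {
    v <- vertices(c)
    r <- sqrt((v[, 1L] - 51)^2 + (v[, 2L] - 51)^2)
    # sub-pixel marching squares: ~2% discretization error at the smallest
    # (highest-level) radius, well under 1% elsewhere
    expect_equal(mean(r), 10 * sqrt(2 * log(100 / level(c))),
                 tolerance = 0.025)
  }
  # radii decrease with level
  radii <- vapply(cs, function(c) sqrt(area(c) / pi), numeric(1L))
  expect_true(all(diff(radii) < 0))
})

test_that("contour extraction edge cases", {
  expect_length(buildLevelContours(GrayImage(matrix(9, 16, 16), 8L)), 0L)
  # two well-separated peaks: two contours at every low level
  cs <- buildLevelContours(twoPeakImage(), k = 20)
  lv <- vapply(cs, level, numeric(1L))
  expect_true(all(table(lv[lv <= 60]) == 2L))
  expect_error(buildLevelContours(gaussianPeakImage(), k = -1), "positive")
})

test_that("containsContour is a correct geometric predicate", {
  expect_true(containsContour(squareContour(1, 0, 0, 5),
                              squareContour(2, 0, 0, 2)))
  expect_false(containsContour(squareContour(1, 0, 0, 5),
                               squareContour(2, 20, 20, 2)))
  # overlapping but non-nested L-shaped pair
  L1 <- IsoContour(1, cbind(c(0, 10, 10, 4, 4, 0), c(0, 0, 4, 4, 10, 10)))
  L2 <- IsoContour(2, cbind(c(2, 12, 12, 6, 6, 2), c(2, 2, 6, 6, 12, 12)))
  expect_false(containsContour(L1, L2))
  expect_false(containsContour(L2, L1))
  # vertices on the outer boundary still count as contained
  expect_true(containsContour(squareContour(1, 0, 0, 5),
                              squareContour(2, 0, 0, 5)))
})

test_that("step dissimilarity follows its closed form", {
  d10 <- discContour(1, 0, 0, 10)
  d8 <- discContour(2, 0, 0, 8)
  expect_equal(stepDissimilarity(d10, d10), 0)
  # concentric discs radius 10 and 8: |1 - 64/100| = 0.36
  expect_equal(stepDissimilarity(d10, d8), 0.36, tolerance = 1e-3)
  # same-area disc shifted by its radius: shift / sqrt(area/pi) = r / r = 1
  sh <- discContour(2, 5, 0, 5)
  expect_equal(stepDissimilarity(discContour(1, 0, 0, 5), sh), 1,
               tolerance = 1e-3)
  expect_gte(stepDissimilarity(d10, discContour(2, 1, 1, 7)), 0)
})

test_that("nested chains link Gaussian contours into a single deep chain", {
  cs <- buildLevelContours(gaussianPeakImage(), k = 10)
  nests <- linkNestedChains(cs, NCAParams(k = 10))
  expect_length(nests, 1L)
  expect_equal(depth(nests[[1L]]), 9L)
  expect_length(dissimilarityTrace(nests[[1L]]), 8L)
  # nesting soundness on every returned chain
  for (nest in nests) {
    cc <- contours(nest)
    for (i in seq_len(length(cc) - 1L))
      expect_true(containsContour(cc[[i]], cc[[i + 1L]]))
  }
  expect_length(linkNestedChains(list(), NCAParams()), 0L)
  # two separated peaks give two chains
  cs2 <- buildLevelContours(twoPeakImage(), k = 10)
  expect_length(linkNestedChains(cs2, NCAParams(k = 10)), 2L)
})

test_that("the discard rule keeps similar runs and cuts dissimilar steps", {
  cs <- buildLevelContours(gaussianPeakImage(), k = 10)
  nests <- linkNestedChains(cs, NCAParams(k = 10))
  generous <- NCAParams(k = 10, tauArea = 2, tauShift = 2)
  kept <- pruneChains(nests, generous)
  expect_length(kept, 1L)
  expect_equal(depth(kept[[1L]]), 9L)   # chain kept intact under generous tau

  # a forced 10x area jump cuts the chain at that step
  chain <- ContourNest(list(discContour(10, 0, 0, 40),
                            discContour(20, 0, 0, 12),
                            discContour(30, 0, 0, 11),
                            discContour(40, 0, 0, 10)))
  runs <- pruneChains(list(chain), NCAParams(k = 10, minDepth = 3L,
                                             minArea = 1))
  expect_length(runs, 1L)
  expect_equal(depth(runs[[1L]]), 3L)   # the dissimilar outer disc dropped
  expect_equal(area(contours(runs[[1L]])[[1L]]), pi * 12^2, tolerance = 0.01)
  # with minDepth above the surviving run length, nothing survives
  expect_length(pruneChains(list(chain), NCAParams(k = 10, minDepth = 4L,
                                                   minArea = 1)), 0L)
  expect_length(pruneChains(list(), NCAParams()), 0L)
})

test_that("detectLesions finds seeded masses and nothing on flat images", {
  ph <- smallMassPhantom(seed = 11L)
  cands <- detectLesions(ph$image, NCAParams())
  expect_gte(length(cands), 1L)
  ctr <- c(mean(ph$annotations$x_min + ph$annotations$x_max) / 2,
           mean(ph$annotations$y_min + ph$annotations$y_max) / 2)
  containing <- vapply(cands, function(c) {
    b <- boundingBox(c)
    b[1L] <= ctr[1L] && b[3L] >= ctr[1L] && b[2L] <= ctr[2L] && b[4L] >= ctr[2L]
  }, logical(1L))
  expect_true(any(containing))

  expect_length(detectLesions(GrayImage(matrix(40, 64, 64), 8L), NCAParams()),
                0L)

  # two disjoint masses give two candidates with disjoint boxes
  c2 <- detectLesions(twoPeakImage(), NCAParams())
  expect_length(c2, 2L)
  b1 <- boundingBox(c2[[1L]]); b2 <- boundingBox(c2[[2L]])
  expect_true(b1[3L] <= b2[1L] || b2[3L] <= b1[1L] ||
              b1[4L] <= b2[2L] || b2[4L] <= b1[2L])
  # scores sorted descending
  sc <- vapply(c2, score, numeric(1L))
  expect_true(all(diff(sc) <= 0))
})

test_that("detection is deterministic and affine-intensity invariant", {
  ph <- smallMassPhantom(seed = 23L)
  a <- detectLesions(ph$image, NCAParams())
  b <- detectLesions(ph$image, NCAParams())
  expect_identical(lapply(a, boundingBox), lapply(b, boundingBox))
  expect_identical(vapply(a, score, numeric(1L)), vapply(b, score, numeric(1L)))

  # a * image + b with a > 0: identical candidate geometry (levels are
  # placed relative to the image's own brightness range)
  scaled <- GrayImage(pixels(ph$image) * 0.5 + 30, 8L)
  d <- detectLesions(scaled, NCAParams())
  expect_identical(lapply(a, boundingBox), lapply(d, boundingBox))
  expect_identical(vapply(a, depth, integer(1L)),
                   vapply(d, depth, integer(1L)))
})

test_that("chain linking matches a brute-force containment construction", {
  sig <- function(chain, contourList)
    paste(vapply(chain, function(i)
      sprintf("%.6g:%.6g", level(contourList[[i]]), area(contourList[[i]])),
      character(1L)), collapse = "|")

  set.seed(99)
  for (case in 1:5) {
    m <- matrix(0, 24, 24)
    nb <- sample(1:3, 1L)
    for (b in seq_len(nb)) {
      cx <- sample(6:18, 1L); cy <- sample(6:18, 1L)
      m <- m + 90 * exp(-(outer((1:24 - cy)^2, (1:24 - cx)^2, `+`)) /
                          (2 * sample(2:4, 1L)^2))
    }
    m <- round(pmin(m, 255) / 64) * 64   # at most 4 intensity levels
    if (max(m) == min(m)) next
    im <- GrayImage(m, 8L)
    k <- (max(m) - min(m)) / 4
    cs <- buildLevelContours(im, k = k)
    got <- linkNestedChains(cs, NCAParams(k = k))
    want <- bruteForceChains(cs, k)
    gotSig <- sort(vapply(got, function(nst) paste(vapply(contours(nst),
      function(c) sprintf("%.6g:%.6g", level(c), area(c)), character(1L)),
      collapse = "|"), character(1L)))
    wantSig <- sort(vapply(want, sig, character(1L), contourList = cs))
    expect_identical(gotSig, wantSig)
  }
})

test_that("raising minDepth never increases the number of candidates", {
  ph <- smallMassPhantom(seed = 31L, densityClass = "C")
  counts <- vapply(2:6, function(md)
    length(detectLesions(ph$image, NCAParams(minDepth = md))), integer(1L))
  expect_true(all(diff(counts) <= 0))
})
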