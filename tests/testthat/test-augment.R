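test_that("eightfold augmentation yields 8 in-bounds, seed-stable samples", {
  ph <- smallMassPhantom(seed = 5L, shape = 96L)
  out <- eightfoldAugment(ph$image, ph$annotations, seed = 42L)
  expect_length(out, 8L)
  for (s in out) {
    expect_identical(dim(pixels(s)), dim(pixels(ph$image)))
    ann <- annotations(s)
    if (nrow(ann)) {
      expect_true(all(ann$x_min >= 0 & ann$y_min >= 0))
      expect_true(all(ann$x_max <= 96 & ann$y_max <= 96))
      expect_true(all(ann$x_min < ann$x_max & ann$y_min < ann$y_max))
    }
  }
  # bit-identical under the same seed
  again <- eightfoldAugment(ph$image, ph$annotations, seed = 42L)
  for (i in 1:8) {
    expect_identical(pixels(out[[i]]), pixels(again[[i]]))
    expect_identical(annotations(out[[i]]), annotations(again[[i]]))
  }
  # different seed changes the draws
  other <- eightfoldAugment(ph$image, ph$annotations, seed = 43L)
  expect_false(identical(pixels(out[[1L]]), pixels(other[[1L]])))
})

test_that("box transform follows the affine corner-mapping convention", {
  ann <- data.frame(x_min = 10, y_min = 10, x_max = 20, y_max = 30,
                    lesion_type = "star_like")
  # identity draw leaves boxes unchanged
  Mid <- NestedContours:::.makeAffine(0, FALSE, FALSE, 0, 0, 100, 100)
  expect_equal(as.numeric(
    NestedContours:::.transformBoxes(ann, Mid, 100, 100)[1, 1:4]),
    c(10, 10, 20, 30))
  # 90-degree clockwise rotation about the centre of a 100x100 image:
  # corners (10,10),(20,10),(10,30),(20,30) map to (90,10),(90,20),
  # (70,10),(70,20), so the re-axis-aligned box is (70,10,90,20)
  M90 <- NestedContours:::.makeAffine(90, FALSE, FALSE, 0, 0, 100, 100)
  expect_equal(as.numeric(
    NestedContours:::.transformBoxes(ann, M90, 100, 100)[1, 1:4]),
    c(70, 10, 90, 20), tolerance = 1e-9)
  # transforming image and annotation together keeps the lesion centroid
  # inside the transformed box
  ph <- smallMassPhantom(seed = 9L, shape = 96L)
  set.seed(1)
  for (i in 1:5) {
    M <- NestedContours:::.makeAffine(runif(1, 0, 360), runif(1) < 0.5,
                                      runif(1) < 0.5, runif(1, -9, 9),
                                      runif(1, -9, 9), 96, 96)
    a0 <- ph$annotations
    ctr <- c((a0$x_min + a0$x_max) / 2, (a0$y_min + a0$y_max) / 2)
    newCtr <- NestedContours:::.affinePoints(M, matrix(ctr, 1L))
    tb <- NestedContours:::.transformBoxes(a0, M, 96, 96)
    if (nrow(tb)) {
      expect_gte(newCtr[1], tb$x_min[1] - 1e-9)
      expect_lte(newCtr[1], tb$x_max[1] + 1e-9)
      expect_gte(newCtr[2], tb$y_min[1] - 1e-9)
      expect_lte(newCtr[2], tb$y_max[1] + 1e-9)
    }
  }
})

test_that("mosaic mixes four images with conserved pixels and annotations", {
  mk <- function(val, seed) {
    img <- GrayImage(matrix(val, 64, 64), 8L)
    ann <- data.frame(x_min = 28, y_min = 28, x_max = 36, y_max = 36,
                      lesion_type = "round_oval_clear_border")
    new("AugmentedSample", image = img, annotations = ann,
        provenance = "fixture", seed = as.integer(seed))
  }
  samples <- lapply(1:4, function(i) mk(c(40, 80, 120, 160)[i], i))
  mo <- mosaicAugment(samples, seed = 3L, outShape = c(64L, 64L))
  # every output pixel originates from exactly one input image
  expect_true(all(pixels(mo) %in% c(40, 80, 120, 160)))
  # four centred lesions survive (central crops do not clip them)
  expect_equal(nrow(annotations(mo)), 4L)
  expect_true(all(annotations(mo)$x_max - annotations(mo)$x_min > 0))

  # annotation-free inputs give an annotation-free mosaic
  bare <- lapply(samples, function(s) {
    s@annotations <- emptyAnn(); s
  })
  expect_equal(nrow(annotations(mosaicAugment(bare, seed = 3L,
                                              outShape = c(64L, 64L)))), 0L)
  expect_error(mosaicAugment(samples[1:3], seed = 1L), "exactly 4")
  # reproducibility
  mo2 <- mosaicAugment(samples, seed = 3L, outShape = c(64L, 64L))
  expect_identical(pixels(mo), pixels(mo2))
  expect_identical(annotations(mo), annotations(mo2))
})
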