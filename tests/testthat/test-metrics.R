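test_that("iou is exact, symmetric and bounded", {
  a <- c(0, 0, 2, 2); b <- c(1, 1, 3, 3)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(5, 5, 6, 6)), 0)
  expect_equal(iou(a, b), 1 / 7)
  expect_equal(iou(b, a), 1 / 7)
  set.seed(5)
  for (i in 1:25) {
    p <- sort(runif(4)); q <- sort(runif(4))
    bx <- c(p[1], p[2], p[3], p[4]); by <- c(q[1], q[2], q[3], q[4])
    v <- iou(bx, by)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, iou(by, bx))
    expect_equal(iou(bx, bx), 1)
  }
})

test_that("matching honours the IoU >= 0.5 rule with greedy 1-1 assignment", {
  gt <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                   lesion_type = "star_like")
  det06 <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 14.5,
                      score = 1)   # IoU ~ 0.69
  m <- matchDetections(det06, gt)
  expect_equal(c(m$counts@tp, m$counts@fp, m$counts@fn), c(1L, 0L, 0L))

  det04 <- data.frame(x_min = 0, y_min = 6, x_max = 10, y_max = 16,
                      score = 1)   # IoU = 4/16 < 0.5
  m2 <- matchDetections(det04, gt)
  expect_equal(c(m2$counts@tp, m2$counts@fp, m2$counts@fn), c(0L, 1L, 1L))

  # two detections over one ground truth: greedy one-to-one
  dets <- data.frame(x_min = c(0, 1), y_min = c(0, 1), x_max = c(10, 10),
                     y_max = c(10, 10), score = c(0.9, 0.8))
  m3 <- matchDetections(dets, gt)
  expect_equal(c(m3$counts@tp, m3$counts@fp, m3$counts@fn), c(1L, 1L, 0L))
  expect_equal(m3$matches$det, 1L)   # the higher-scored one matched
  # tp + fn equals the number of ground truths
  expect_equal(m3$counts@tp + m3$counts@fn, nrow(gt))
})

test_that("precision and recall are exact rationals with flagged undefined", {
  pr <- precisionRecall(ConfusionCounts(60, 10, 40))
  expect_equal(pr[["precision"]], 60 / 70)
  expect_equal(pr[["recall"]], 0.6)
  pr2 <- precisionRecall(ConfusionCounts(93, 63, 7))
  expect_equal(pr2[["precision"]], 93 / 156)
  expect_equal(pr2[["recall"]], 0.93)
  pr3 <- precisionRecall(ConfusionCounts(0, 0, 5))
  expect_true(is.na(pr3[["precision"]]))
  expect_equal(pr3[["recall"]], 0)
})

test_that("f1 and f-beta follow the printed formulas", {
  expect_equal(f1Score(0.85, 0.60), 2 * 0.85 * 0.6 / 1.45)
  for (x in c(0.2, 0.5, 0.93)) expect_equal(f1Score(x, x), x)
  expect_equal(f1Score(0, 0), 0)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(1, 0.05, 1); r <- runif(1, 0.05, 1)
    f <- f1Score(p, r)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
    # beta = 1 reduces f-beta to f1
    expect_equal(fBetaScore(p, r, 1), f)
  }
  # denominator is beta * p + r, exactly as printed
  expect_equal(fBetaScore(0.85, 0.60, 10), 101 * 0.85 * 0.6 / (8.5 + 0.6))
  expect_equal(floor(fBetaScore(0.85, 0.60, 10) * 100) / 100, 5.66)
  expect_equal(floor(fBetaScore(0.59, 0.93, 100) * 100) / 100, 91.56)
})

test_that("11-point interpolated AP and mAP", {
  expect_equal(averagePrecision11(
    data.frame(recall = seq(0, 1, 0.1), precision = 1)), 1)
  expect_equal(averagePrecision11(
    data.frame(recall = seq(0, 1, 0.25), precision = 0.5)), 0.5)
  two <- data.frame(recall = c(0.5, 1), precision = c(1, 0.2))
  expect_equal(averagePrecision11(two), (6 * 1 + 5 * 0.2) / 11)
  # invariant to point order
  expect_equal(averagePrecision11(two[2:1, ]), averagePrecision11(two))
  expect_error(averagePrecision11(data.frame(recall = numeric(0),
                                             precision = numeric(0))),
               "empty")
  expect_equal(meanAveragePrecision(c(c1 = 0.8)), 0.8)
  expect_equal(meanAveragePrecision(c(0.96, 0.90)), 0.93)
  expect_equal(meanAveragePrecision(c(1, 0)), 0.5)
  expect_error(meanAveragePrecision(numeric(0)), "empty")
})

test_that("per-type aggregation conserves totals and rejects bad labels", {
  tab <- data.frame(lesion_type = LESION_TYPES,
                    tp = c(15L, 24L, 8L, 6L, 5L, 2L),
                    fp = c(0L, 7L, 3L, 0L, 0L, 0L),
                    fn = c(1L, 6L, 0L, 22L, 11L, 0L))
  rep <- aggregateByType(tab)
  total <- rep@perType[rep@perType$lesion_type == "Total", ]
  expect_equal(c(total$tp, total$fp, total$fn), c(60L, 10L, 40L))
  # totals equal column sums of the per-type rows (conservation)
  body <- rep@perType[rep@perType$lesion_type != "Total", ]
  expect_equal(colSums(body[, c("tp", "fp", "fn")]),
               unlist(total[, c("tp", "fp", "fn")]))

  expect_error(aggregateByType(data.frame(lesion_type = "weird", tp = 1,
                                          fp = 0, fn = 0)), "unknown")
  empty <- aggregateByType(data.frame(lesion_type = character(0),
                                      tp = integer(0), fp = integer(0),
                                      fn = integer(0)))
  expect_equal(empty@counts@tp + empty@counts@fp + empty@counts@fn, 0L)
})

test_that("two-proportion chi-square comparison (no continuity correction)", {
  p <- compareMarkingRates(c(14, 30), c(7, 30))
  expect_gt(p, 0.055); expect_lt(p, 0.062)
  # cross-check against the closed-form Pearson statistic
  stat <- 60 * (14 * 23 - 16 * 7)^2 / (30 * 30 * 21 * 39)
  expect_equal(p, stats::pchisq(stat, 1L, lower.tail = FALSE))
  expect_equal(compareMarkingRates(c(12, 30), c(12, 30)), 1)
  expect_lt(compareMarkingRates(c(16, 16), c(0, 16)), 0.001)
  expect_error(compareMarkingRates(c(0, 16), c(0, 16)), "margin")
})
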