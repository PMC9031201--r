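# Detection evaluation: IoU box matching, precision/recall, F1 and F-beta,
# 11-point interpolated average precision, per-lesion-type aggregation, and
# a two-proportion chi-square comparison.

#' Intersection over union of two boxes
#'
#' IoU = S(A intersect B) / S(A union B); 0 for disjoint boxes, 1 for
#' perfect overlap. Boxes are c(xmin, ymin, xmax, ymax), 0-based half-open.
#'
#' @param a,b numeric boxes.
#' @return real in [0, 1]; symmetric in its arguments.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  stopifnot(length(a) == 4L, length(b) == 4L,
            a[1L] < a[3L], a[2L] < a[4L], b[1L] < b[3L], b[2L] < b[4L])
  iw <- min(a[3L], b[3L]) - max(a[1L], b[1L])
  ih <- min(a[4L], b[4L]) - max(a[2L], b[2L])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3L] - a[1L]) * (a[4L] - a[2L]) +
           (b[3L] - b[1L]) * (b[4L] - b[2L]) - inter)
}

.boxMatrix <- function(df) {
  as.matrix(df[, c("x_min", "y_min", "x_max", "y_max"), drop = FALSE])
}

#' Match detections to ground truths
#'
#' A bounding box is defined correctly if IoU >= the threshold (default
#' 0.5). Detections are processed in descending score order; each is
#' matched greedily to the still-unmatched ground truth with the highest
#' IoU at or above the threshold. Matched pairs count as TP, unmatched
#' detections as FP, unmatched ground truths as FN, so tp + fn equals the
#' number of ground truths.
#'
#' @param detections data.frame with columns x_min, y_min, x_max, y_max and
#'   optionally score (unscored detections are taken in input order).
#' @param groundTruth data.frame with box columns and optionally
#'   lesion_type.
#' @param iouThreshold real in (0, 1], default 0.5.
#' @return list with \code{counts} (\linkS4class{ConfusionCounts}),
#'   \code{matches} (data.frame det, gt, iou), and \code{gtMatched}
#'   (logical per ground truth).
#' @export
matchDetections <- function(detections, groundTruth, iouThreshold = 0.5) {
  stopifnot(iouThreshold > 0, iouThreshold <= 1)
  nd <- nrow(detections); ng <- nrow(groundTruth)
  if (is.null(nd)) nd <- 0L
  if (is.null(ng)) ng <- 0L
  matches <- data.frame(det = integer(0L), gt = integer(0L), iou = numeric(0L))
  gtMatched <- rep(FALSE, ng)
  if (nd > 0L && ng > 0L) {
    db <- .boxMatrix(detections); gb <- .boxMatrix(groundTruth)
    ord <- if ("score" %in% names(detections))
      order(-detections$score) else seq_len(nd)
    for (i in ord) {
      ious <- vapply(seq_len(ng), function(j)
        if (gtMatched[j]) -1 else iou(db[i, ], gb[j, ]), numeric(1L))
      j <- which.max(ious)
      if (ious[j] >= iouThreshold) {
        gtMatched[j] <- TRUE
        matches <- rbind(matches,
                         data.frame(det = i, gt = j, iou = ious[j]))
      }
    }
  }
  tp <- nrow(matches)
  list(counts = ConfusionCounts(tp = tp, fp = nd - tp, fn = ng - tp),
       matches = matches, gtMatched = gtMatched)
}

#' Precision and recall from confusion counts
#'
#' Exact rational values; any report-level rounding is applied separately.
#' A zero denominator yields NA (undefined is flagged, never silently 0).
#'
#' @param counts a \linkS4class{ConfusionCounts}.
#' @return named numeric c(precision, recall).
#' @export
precisionRecall <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  p <- if (counts@tp + counts@fp > 0L)
    counts@tp / (counts@tp + counts@fp) else NA_real_
  r <- if (counts@tp + counts@fn > 0L)
    counts@tp / (counts@tp + counts@fn) else NA_real_
  c(precision = p, recall = r)
}

#' F1 score (harmonic mean of precision and recall)
#'
#' @param p,r precision and recall in [0, 1].
#' @return 2 p r / (p + r); 0 when both are 0.
#' @export
f1Score <- function(p, r) {
  if (is.na(p) || is.na(r)) return(NA_real_)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' F-beta score, recall weighted beta times over precision
#'
#' Computed exactly as printed in the source formulation:
#' \code{(1 + beta^2) * p * r / (beta * p + r)} -- note the denominator uses
#' beta, not beta squared. At beta = 1 it coincides with F1. Values exceed 1
#' for large beta by construction of this form.
#'
#' @param p,r precision and recall.
#' @param beta positive weight.
#' @return the score; 0 when the denominator is 0.
#' @export
fBetaScore <- function(p, r, beta) {
  stopifnot(beta > 0)
  if (is.na(p) || is.na(r)) return(NA_real_)
  den <- beta * p + r
  if (den == 0) return(0)
  (1 + beta^2) * p * r / den
}

# two-decimal truncation; +1e-9 guards IEEE artefacts (0.6*100 -> 59.999...)
.trunc2 <- function(x) floor(x * 100 + 1e-9) / 100

.round2dp <- function(x, mode) {
  if (is.na(x)) return(NA_real_)
  switch(mode,
         truncate_2dp = .trunc2(x),
         round_2dp = round(x, 2L),
         stop("unknown rounding mode: ", mode))
}

#' 11-point interpolated average precision
#'
#' AP is the mean of the interpolated precision at the eleven evenly spaced
#' recall points 0, 0.1, ..., 1.0, where the interpolated precision at
#' recall r is the maximum precision attained at any recall >= r (0 when no
#' curve point reaches r).
#'
#' @param curve data.frame or matrix with columns recall, precision, each in
#'   [0, 1]. Point order is irrelevant.
#' @return AP in [0, 1].
#' @examples
#' averagePrecision11(data.frame(recall = c(0.5, 1), precision = c(1, 0.2)))
#' @export
averagePrecision11 <- function(curve) {
  curve <- as.data.frame(curve)
  if (nrow(curve) == 0L) stop("empty precision-recall curve")
  stopifnot(all(c("recall", "precision") %in% names(curve)),
            all(curve$recall >= 0 & curve$recall <= 1),
            all(curve$precision >= 0 & curve$precision <= 1))
  pts <- seq(0, 1, by = 0.1)
  pint <- vapply(pts, function(r) {
    sel <- curve$recall >= r - 1e-9
    if (any(sel)) max(curve$precision[sel]) else 0
  }, numeric(1L))
  mean(pint)
}

#' Mean average precision over classes
#'
#' @param perClass named numeric vector of per-class AP values.
#' @return arithmetic mean; equals the single AP for one class.
#' @export
meanAveragePrecision <- function(perClass) {
  if (length(perClass) == 0L) stop("empty per-class AP map")
  mean(perClass)
}

#' Aggregate per-type confusion counts into a metric report
#'
#' Takes a per-type count table (columns lesion_type, tp, fp, fn; one row
#' per type, as tallied by \code{\link{evaluateImageSet}} or entered
#' directly). Totals are the column sums of the per-type counts; precision/recall are derived from the totals, then
#' rounded under \code{roundingMode}, and F1/F-beta are computed from the
#' rounded values (the form in which such tables are conventionally
#' printed).
#'
#' @param perType data.frame of per-type counts.
#' @param betas numeric vector of beta values for F-beta.
#' @param roundingMode "truncate_2dp" (default) or "round_2dp".
#' @return A \linkS4class{MetricReport}; its \code{perType} table carries
#'   the six type rows plus a Total row.
#' @examples
#' tab <- data.frame(lesion_type = LESION_TYPES,
#'                   tp = c(15, 24, 8, 6, 5, 2), fp = c(0, 7, 3, 0, 0, 0),
#'                   fn = c(1, 6, 0, 22, 11, 0))
#' aggregateByType(tab)
#' @export
aggregateByType <- function(perType, betas = c(1, 10, 50, 100),
                            roundingMode = "truncate_2dp") {
  perType <- as.data.frame(perType)
  stopifnot(all(c("lesion_type", "tp", "fp", "fn") %in% names(perType)))
  bad <- setdiff(perType$lesion_type, LESION_TYPES)
  if (length(bad))
    stop("unknown lesion_type label(s): ", paste(bad, collapse = ", "))
  agg <- if (nrow(perType) == 0L)
    perType[, c("lesion_type", "tp", "fp", "fn"), drop = FALSE]
  else
    stats::aggregate(cbind(tp, fp, fn) ~ lesion_type, perType, sum)
  agg <- agg[match(intersect(LESION_TYPES, agg$lesion_type),
                   agg$lesion_type), , drop = FALSE]
  total <- data.frame(lesion_type = "Total", tp = sum(agg$tp),
                      fp = sum(agg$fp), fn = sum(agg$fn))
  counts <- ConfusionCounts(total$tp, total$fp, total$fn)
  pr <- precisionRecall(counts)
  p2 <- .round2dp(pr[["precision"]], roundingMode)
  r2 <- .round2dp(pr[["recall"]], roundingMode)
  fb <- vapply(betas, function(b)
    .round2dp(fBetaScore(p2, r2, b), roundingMode), numeric(1L))
  names(fb) <- as.character(betas)
  new("MetricReport", counts = counts, precision = p2, recall = r2,
      f1 = .round2dp(f1Score(p2, r2), roundingMode), fBeta = fb,
      perType = rbind(agg, total), roundingMode = roundingMode)
}

#' Compare two marking rates (chi-square on the 2x2 table)
#'
#' Two-sided Pearson chi-square test without continuity correction on the
#' 2x2 success/failure table of two detectors' marking rates.
#'
#' @param a,b integer c(successes, trials).
#' @return two-sided p value.
#' @examples
#' compareMarkingRates(c(14, 30), c(7, 30))
#' @export
compareMarkingRates <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L,
            a[1L] >= 0, b[1L] >= 0, a[1L] <= a[2L], b[1L] <= b[2L])
  tab <- matrix(c(a[1L], a[2L] - a[1L], b[1L], b[2L] - b[1L]), nrow = 2L)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table: a zero margin")
  if (a[1L] * b[2L] == b[1L] * a[2L] &&
      a[1L] / a[2L] == b[1L] / b[2L]) {
    # identical proportions: statistic 0 exactly
    return(1)
  }
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}
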