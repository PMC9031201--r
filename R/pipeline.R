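# Run configuration and the detect -> match -> aggregate pipeline.

.CONFIG_KEYS <- c("nca", "preprocess", "iou_threshold", "betas",
                  "rounding_mode", "seed", "paths")

# only keys present in the config override the NCAParams() defaults
.ncaParamsFromList <- function(l) {
  l <- l %||% list()
  args <- list(k = l$k, minDepth = l$min_depth, tauArea = l$tau_area,
               tauShift = l$tau_shift, minArea = l$min_area,
               maxArea = l$max_area)
  do.call(NCAParams, Filter(Negate(is.null), args))
}

#' Read a run configuration from a JSON file
#'
#' The config is a single JSON object with keys \code{nca} (k, min_depth,
#' tau_area, tau_shift, min_area, max_area), \code{preprocess}
#' (low_fraction, high_fraction, clip_limit_1, clip_limit_2, tile_grid),
#' \code{iou_threshold}, \code{betas}, \code{rounding_mode}, \code{seed}
#' and \code{paths}. Unknown keys are rejected.
#'
#' @param path JSON config path.
#' @return validated config list with \code{ncaParams} resolved.
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  normalizeRunConfig(cfg)
}

#' Validate and complete a run configuration
#'
#' @param cfg named list (possibly partial).
#' @return config list with defaults filled in and parameter objects built.
#' @export
normalizeRunConfig <- function(cfg = list()) {
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- list(
    nca = cfg$nca %||% list(),
    preprocess = cfg$preprocess,
    iou_threshold = cfg$iou_threshold %||% 0.5,
    betas = cfg$betas %||% c(1, 10, 50, 100),
    rounding_mode = cfg$rounding_mode %||% "truncate_2dp",
    seed = cfg$seed %||% 1L,
    paths = cfg$paths %||% list())
  out$ncaParams <- .ncaParamsFromList(out$nca)
  stopifnot(out$iou_threshold > 0, out$iou_threshold <= 1)
  out
}

#' Evaluate detections over a set of images
#'
#' For each image the detections are matched to its ground truths
#' (\code{\link{matchDetections}}); TP and FN are attributed to the matched
#' ground truth's lesion type, while FP on lesion-free images (and
#' detections unmatched on positive images) are attributed to the image's
#' dominant annotation type or counted as type-less false positives.
#'
#' @param detectionsList list (per image) of detection data.frames.
#' @param annotationsList list (per image) of ground-truth data.frames
#'   (zero-row for lesion-free images).
#' @param iouThreshold IoU matching threshold (0.5).
#' @return list: \code{perType} count data.frame (an FP on an image without
#'   annotations is tallied under the row with lesion_type of its image if
#'   known, otherwise spread into a separate accounting column),
#'   \code{counts} overall \linkS4class{ConfusionCounts}, and
#'   \code{perImage} match results.
#' @export
evaluateImageSet <- function(detectionsList, annotationsList,
                             iouThreshold = 0.5) {
  stopifnot(length(detectionsList) == length(annotationsList))
  tallies <- stats::setNames(
    data.frame(lesion_type = LESION_TYPES, tp = 0L, fp = 0L, fn = 0L),
    c("lesion_type", "tp", "fp", "fn"))
  fpUntyped <- 0L
  perImage <- vector("list", length(detectionsList))
  for (i in seq_along(detectionsList)) {
    det <- detectionsList[[i]]; gt <- annotationsList[[i]]
    m <- matchDetections(det, gt, iouThreshold)
    perImage[[i]] <- m
    if (nrow(gt)) {
      for (j in seq_len(nrow(gt))) {
        ty <- gt$lesion_type[j]
        row <- match(ty, tallies$lesion_type)
        if (is.na(row)) stop("unknown lesion_type: ", ty)
        if (m$gtMatched[j]) tallies$tp[row] <- tallies$tp[row] + 1L
        else tallies$fn[row] <- tallies$fn[row] + 1L
      }
      nFp <- m$counts@fp
      # false positives on a positive image count against its lesion type
      row <- match(gt$lesion_type[1L], tallies$lesion_type)
      tallies$fp[row] <- tallies$fp[row] + nFp
    } else {
      fpUntyped <- fpUntyped + m$counts@fp
    }
  }
  counts <- ConfusionCounts(sum(tallies$tp), sum(tallies$fp) + fpUntyped,
                            sum(tallies$fn))
  list(perType = tallies, fpOnNegatives = fpUntyped, counts = counts,
       perImage = perImage)
}

#' Run the full detection + evaluation pipeline
#'
#' For every image: NCA detection, IoU matching against its ground truth,
#' per-type aggregation, and report emission (per-type table in the shape
#' of a TP/FP rate table and a metric table with precision/recall/F1 and
#' F-beta rows). With an output directory the per-image detections, the
#' JSON report and CSV tables are written; the report embeds the exact
#' configuration and seed that produced it.
#'
#' @param images list of \linkS4class{GrayImage}.
#' @param annotationsList list of ground-truth data.frames (one per image).
#' @param config run configuration (see \code{\link{normalizeRunConfig}}).
#' @param outDir optional output directory.
#' @param verbose log progress to stderr.
#' @return A \linkS4class{MetricReport} with attributes \code{evaluation}
#'   (per-image detail) and \code{config}.
#' @export
runPipeline <- function(images, annotationsList, config = list(),
                        outDir = NULL, verbose = FALSE) {
  config <- if (is.list(config) && !is.null(config$ncaParams)) config
            else normalizeRunConfig(config)
  detections <- vector("list", length(images))
  allCands <- vector("list", length(images))
  for (i in seq_along(images)) {
    if (verbose) message("detect [", i, "/", length(images), "]")
    cands <- detectLesions(images[[i]], config$ncaParams)
    allCands[[i]] <- cands
    detections[[i]] <- detectionTable(cands)
  }
  ev <- evaluateImageSet(detections, annotationsList, config$iou_threshold)
  report <- aggregateByType(ev$perType, betas = config$betas,
                            roundingMode = config$rounding_mode)
  # fold the FP tally from lesion-free images into the overall counts
  total <- ConfusionCounts(report@counts@tp,
                           report@counts@fp + ev$fpOnNegatives,
                           report@counts@fn)
  pr <- precisionRecall(total)
  p2 <- .round2dp(pr[["precision"]], config$rounding_mode)
  r2 <- .round2dp(pr[["recall"]], config$rounding_mode)
  fb <- vapply(config$betas, function(b)
    .round2dp(fBetaScore(p2, r2, b), config$rounding_mode), numeric(1L))
  names(fb) <- as.character(config$betas)
  report <- new("MetricReport", counts = total, precision = p2, recall = r2,
                f1 = .round2dp(f1Score(p2, r2), config$rounding_mode),
                fBeta = fb, perType = report@perType,
                roundingMode = config$rounding_mode)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(allCands))
      writeDetections(allCands[[i]],
                      file.path(outDir, sprintf("detections_%03d.json", i)))
    utils::write.csv(report@perType,
                     file.path(outDir, "per_type_table.csv"),
                     row.names = FALSE)
    metricTab <- data.frame(
      metric = c("precision", "recall", "f1",
                 paste0("f_beta_", names(report@fBeta))),
      value = c(report@precision, report@recall, report@f1, report@fBeta))
    utils::write.csv(metricTab, file.path(outDir, "metric_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(config = config[setdiff(names(config), "ncaParams")],
           counts = list(tp = total@tp, fp = total@fp, fn = total@fn),
           fp_on_negatives = ev$fpOnNegatives,
           precision = report@precision, recall = report@recall,
           f1 = report@f1, f_beta = as.list(report@fBeta),
           per_type = report@perType),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  attr(report, "evaluation") <- ev
  attr(report, "config") <- config
  report
}
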