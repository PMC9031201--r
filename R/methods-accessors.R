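# Accessor and show methods.

#' @rdname GrayImage-class
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' @rdname GrayImage-class
#' @export
setMethod("bitDepth", "GrayImage", function(x) x@bitDepth)

#' @rdname maxIntensity
#' @export
setMethod("maxIntensity", "GrayImage", function(x) 2^x@bitDepth - 1)

#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @export
setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GrayImage %dx%d (HxW), %d-bit, intensity range [%.7g, %.7g]\n",
              d[1L], d[2L], object@bitDepth,
              min(object@pixels), max(object@pixels)))
})

#' @rdname IsoContour-class
#' @export
setMethod("level", "IsoContour", function(x) x@level)

#' @rdname IsoContour-class
#' @export
setMethod("vertices", "IsoContour", function(x) x@vertices)

#' @rdname IsoContour-class
#' @export
setMethod("area", "IsoContour", function(x) x@area)

#' @rdname IsoContour-class
#' @export
setMethod("centroid", "IsoContour", function(x) x@centroid)

#' @rdname IsoContour-class
#' @export
setMethod("perimeter", "IsoContour", function(x) x@perimeter)

#' @rdname boundingBox
#' @export
setMethod("boundingBox", "IsoContour", function(x) x@bbox)

#' @export
setMethod("show", "IsoContour", function(object) {
  cat(sprintf(
    "IsoContour level %.7g: %d vertices, area %.2f px^2, centroid (%.2f, %.2f)\n",
    object@level, nrow(object@vertices), object@area,
    object@centroid[1L], object@centroid[2L]))
})

#' @rdname ContourNest-class
#' @export
setMethod("contours", "ContourNest", function(x) x@contours)

#' @rdname ContourNest-class
#' @export
setMethod("depth", "ContourNest", function(x) length(x@contours))

#' @rdname ContourNest-class
#' @export
setMethod("dissimilarityTrace", "ContourNest",
          function(x) x@dissimilarityTrace)

#' @export
setMethod("show", "ContourNest", function(object) {
  lv <- vapply(object@contours, level, numeric(1L))
  cat(sprintf("ContourNest depth %d, levels %.7g..%.7g, outer area %.1f px^2\n",
              length(object@contours), lv[1L], lv[length(lv)],
              area(object@contours[[1L]])))
})

#' @rdname LesionCandidate-class
#' @param x a \linkS4class{LesionCandidate}.
#' @export
setMethod("depth", "LesionCandidate", function(x) x@depth)

#' @rdname LesionCandidate-class
#' @export
setMethod("score", "LesionCandidate", function(x) x@score)

#' @rdname boundingBox
#' @export
setMethod("boundingBox", "LesionCandidate", function(x) x@box)

#' @rdname LesionCandidate-class
#' @export
setMethod("contours", "LesionCandidate", function(x) list(x@contour))

#' @export
setMethod("show", "LesionCandidate", function(object) {
  cat(sprintf(
    "LesionCandidate box [%g, %g, %g, %g), depth %d, score %.3f\n",
    object@box[1L], object@box[2L], object@box[3L], object@box[4L],
    object@depth, object@score))
})

#' @export
setMethod("show", "NCAParams", function(object) {
  cat(sprintf(
    "NCAParams: k=%s, minDepth=%d, tauArea=%.3g, tauShift=%.3g, area [%g, %s] px^2\n",
    if (is.na(object@k)) "range/32" else format(object@k), object@minDepth,
    object@tauArea, object@tauShift, object@minArea,
    if (is.na(object@maxArea)) "25% of image" else format(object@maxArea)))
})

#' @export
setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d FN=%d\n",
              object@tp, object@fp, object@fn))
})

#' @export
setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport (%s): TP=%d FP=%d FN=%d\n", object@roundingMode,
              object@counts@tp, object@counts@fp, object@counts@fn))
  cat(sprintf("  precision %s  recall %s  F1 %s\n",
              format(object@precision), format(object@recall),
              format(object@f1)))
  if (length(object@fBeta))
    cat("  F-beta:", paste(sprintf("beta=%s: %s", names(object@fBeta),
                                   format(object@fBeta)), collapse = ", "),
        "\n")
})

#' @export
setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec %dx%d, ACR %s, %d lesion(s), noise sigma %.3g, texture %.3g, seed %d\n",
    object@shape[1L], object@shape[2L], object@densityClass,
    length(object@lesions), object@noiseSigma, object@textureStrength,
    object@seed))
})
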