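# Training-set augmentation: the eightfold rotation/mirror/shift expansion
# and the four-image mosaic mix, both with annotation-consistent geometry.
# One affine matrix drives both the raster warp and the box transform, so
# image and annotations can never drift apart.

#' AugmentedSample: an image with its transformed annotations
#'
#' @slot image a \linkS4class{GrayImage}.
#' @slot annotations data.frame of boxes (x_min, y_min, x_max, y_max, plus
#'   any label columns), all within image bounds.
#' @slot provenance character; source id and transform description.
#' @slot seed integer seed that produced the sample.
#' @export
setClass("AugmentedSample",
  representation(image = "GrayImage", annotations = "data.frame",
                 provenance = "character", seed = "integer"),
  validity = function(object) {
    ann <- object@annotations
    if (nrow(ann)) {
      d <- dim(object@image@pixels)
      if (any(ann$x_min < 0) || any(ann$y_min < 0) ||
          any(ann$x_max > d[2L]) || any(ann$y_max > d[1L]))
        return("annotation boxes must lie within image bounds")
      if (any(ann$x_min >= ann$x_max) || any(ann$y_min >= ann$y_max))
        return("annotation boxes must have positive area")
    }
    TRUE
  }
)

#' @rdname AugmentedSample-class
#' @param x an \linkS4class{AugmentedSample}.
#' @export
setMethod("pixels", "AugmentedSample", function(x) x@image@pixels)

#' Annotations of a sample
#' @param x an \linkS4class{AugmentedSample}.
#' @export
annotations <- function(x) x@annotations

#' @export
setMethod("show", "AugmentedSample", function(object) {
  cat(sprintf("AugmentedSample (%s): %d annotation(s), seed %d\n",
              object@provenance, nrow(object@annotations), object@seed))
})

.emptyAnnotations <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
             y_max = numeric(0), lesion_type = character(0))
}

# Forward affine map p' = A %*% (p - centre) + centre + t, encoded as a
# list(A = 2x2, t = length-2). Applied identically to raster and boxes.
.affineIdentity <- function() list(A = diag(2), t = c(0, 0), centre = c(0, 0))

.makeAffine <- function(angleDeg, mirrorH, mirrorV, dx, dy, width, height) {
  th <- angleDeg * pi / 180
  # clockwise rotation in y-down pixel coordinates
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L, byrow = TRUE)
  S <- diag(c(if (mirrorH) -1 else 1, if (mirrorV) -1 else 1))
  list(A = R %*% S, t = c(dx, dy), centre = c(width / 2, height / 2))
}

.affinePoints <- function(M, pts) {
  # pts: n x 2
  sweep(t(M$A %*% t(sweep(pts, 2L, M$centre))), 2L,
        M$centre + M$t, `+`)
}

# inverse-mapped nearest-neighbour warp; exposed corners fill with 0
# (mammography background is black)
.warpImage <- function(image, M) {
  px <- image@pixels
  h <- nrow(px); w <- ncol(px)
  X <- rep(0:(w - 1L), each = h)
  Y <- rep(0:(h - 1L), times = w)
  Ainv <- solve(M$A)
  src <- t(Ainv %*% rbind(X - M$centre[1L] - M$t[1L],
                          Y - M$centre[2L] - M$t[2L]))
  sx <- round(src[, 1L] + M$centre[1L])
  sy <- round(src[, 2L] + M$centre[2L])
  ok <- sx >= 0 & sx < w & sy >= 0 & sy < h
  out <- numeric(h * w)
  out[ok] <- px[cbind(sy[ok] + 1L, sx[ok] + 1L)]
  GrayImage(matrix(out, h, w), image@bitDepth)
}

.transformBoxes <- function(ann, M, width, height) {
  if (!nrow(ann)) return(ann)
  out <- ann
  for (i in seq_len(nrow(ann))) {
    cx <- c(ann$x_min[i], ann$x_max[i], ann$x_min[i], ann$x_max[i])
    cy <- c(ann$y_min[i], ann$y_min[i], ann$y_max[i], ann$y_max[i])
    p <- .affinePoints(M, cbind(cx, cy))
    out$x_min[i] <- max(min(p[, 1L]), 0)
    out$y_min[i] <- max(min(p[, 2L]), 0)
    out$x_max[i] <- min(max(p[, 1L]), width)
    out$y_max[i] <- min(max(p[, 2L]), height)
  }
  out[out$x_max - out$x_min > 0 & out$y_max - out$y_min > 0, , drop = FALSE]
}

#' Eightfold augmentation: rotation, mirroring and shift
#'
#' Produces exactly eight variants of the input, each applying an
#' independently drawn rotation (angle uniform in [0, 360) degrees,
#' clockwise about the image centre), horizontal and vertical mirroring
#' (each with probability 1/2) and a translation uniform within +/-
#' \code{shiftFrac} of each dimension. Annotation boxes are transformed by
#' the same affine map, re-axis-aligned (bounding box of the transformed
#' corners) and clipped; boxes clipped to zero area are dropped. Exposed
#' corners are filled with intensity 0. Deterministic given the seed.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param ann data.frame of annotation boxes (may be empty).
#' @param seed integer.
#' @param shiftFrac maximum shift as a fraction of each dimension (0.1).
#' @param sourceId provenance label of the input.
#' @return list of 8 \linkS4class{AugmentedSample}.
#' @export
eightfoldAugment <- function(image, ann = .emptyAnnotations(), seed = 1L,
                             shiftFrac = 0.1, sourceId = "sample") {
  stopifnot(is(image, "GrayImage"))
  h <- nrow(image@pixels); w <- ncol(image@pixels)
  set.seed(as.integer(seed))
  lapply(seq_len(8L), function(i) {
    angle <- stats::runif(1L, 0, 360)
    mh <- stats::runif(1L) < 0.5
    mv <- stats::runif(1L) < 0.5
    dx <- stats::runif(1L, -shiftFrac, shiftFrac) * w
    dy <- stats::runif(1L, -shiftFrac, shiftFrac) * h
    M <- .makeAffine(angle, mh, mv, dx, dy, w, h)
    new("AugmentedSample",
        image = .warpImage(image, M),
        annotations = .transformBoxes(ann, M, w, h),
        provenance = sprintf(
          "%s | rot %.1fdeg%s%s shift (%.1f, %.1f)", sourceId, angle,
          if (mh) " mirrorH" else "", if (mv) " mirrorV" else "", dx, dy),
        seed = as.integer(seed))
  })
}

# nearest-neighbour index map for scaling a length-n axis to length m
.scaleIdx <- function(m, n) pmin(floor(((seq_len(m) - 0.5) * n) / m), n - 1L) + 1L

#' Mosaic augmentation: mix four images into one
#'
#' A mosaic centre is drawn uniformly within the central half of the output
#' shape; each input is scaled to the output shape (nearest neighbour, so
#' every output pixel originates from exactly one input) and its central
#' crop fills one quadrant. Annotations are remapped through the same
#' scale-and-crop, clipped to their quadrant, and dropped when more than
#' \code{dropFrac} of their scaled area is lost.
#'
#' @param samples list of exactly 4 \linkS4class{AugmentedSample} (or lists
#'   with \code{image} and \code{annotations}).
#' @param seed integer.
#' @param outShape integer c(height, width) of the mosaic.
#' @param dropFrac area-loss fraction above which a clipped box is dropped
#'   (default 0.8).
#' @return one \linkS4class{AugmentedSample}.
#' @export
mosaicAugment <- function(samples, seed = 1L, outShape = c(512L, 512L),
                          dropFrac = 0.8) {
  if (length(samples) != 4L)
    stop("mosaic requires exactly 4 input samples, got ", length(samples))
  getIm <- function(s) if (is(s, "AugmentedSample")) s@image else s$image
  getAnn <- function(s) if (is(s, "AugmentedSample")) s@annotations else
    s$annotations
  H <- as.integer(outShape[1L]); W <- as.integer(outShape[2L])
  set.seed(as.integer(seed))
  cxr <- stats::runif(1L, 0.25, 0.75); cyr <- stats::runif(1L, 0.25, 0.75)
  cx <- round(W * cxr); cy <- round(H * cyr)
  # quadrant rectangles [x0, x1) x [y0, y1), row-major TL TR BL BR
  quads <- list(c(0L, 0L, cx, cy), c(cx, 0L, W, cy),
                c(0L, cy, cx, H), c(cx, cy, W, H))
  outPx <- matrix(0, H, W)
  outAnn <- NULL
  bd <- getIm(samples[[1L]])@bitDepth
  for (q in seq_len(4L)) {
    im <- getIm(samples[[q]]); ann <- getAnn(samples[[q]])
    qx0 <- quads[[q]][1L]; qy0 <- quads[[q]][2L]
    qw <- quads[[q]][3L] - qx0; qh <- quads[[q]][4L] - qy0
    if (qw < 1L || qh < 1L) next
    ih <- nrow(im@pixels); iw <- ncol(im@pixels)
    scaled <- im@pixels[.scaleIdx(H, ih), .scaleIdx(W, iw), drop = FALSE]
    crx0 <- (W - qw) %/% 2L; cry0 <- (H - qh) %/% 2L   # central crop origin
    outPx[(qy0 + 1L):(qy0 + qh), (qx0 + 1L):(qx0 + qw)] <-
      scaled[(cry0 + 1L):(cry0 + qh), (crx0 + 1L):(crx0 + qw)]
    if (nrow(ann)) {
      sx <- W / iw; sy <- H / ih
      a <- ann
      a$x_min <- ann$x_min * sx - crx0 + qx0
      a$x_max <- ann$x_max * sx - crx0 + qx0
      a$y_min <- ann$y_min * sy - cry0 + qy0
      a$y_max <- ann$y_max * sy - cry0 + qy0
      fullArea <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
      a$x_min <- pmax(a$x_min, qx0); a$x_max <- pmin(a$x_max, qx0 + qw)
      a$y_min <- pmax(a$y_min, qy0); a$y_max <- pmin(a$y_max, qy0 + qh)
      clippedArea <- pmax(a$x_max - a$x_min, 0) * pmax(a$y_max - a$y_min, 0)
      keep <- clippedArea > (1 - dropFrac) * fullArea & clippedArea > 0
      if (any(keep)) outAnn <- rbind(outAnn, a[keep, , drop = FALSE])
    }
  }
  if (is.null(outAnn)) outAnn <- .emptyAnnotations()
  new("AugmentedSample", image = GrayImage(outPx, bd),
      annotations = outAnn,
      provenance = sprintf("mosaic centre (%d, %d)", cx, cy),
      seed = as.integer(seed))
}
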