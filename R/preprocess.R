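# Three-step image enhancement: truncation normalization, CLAHE at two clip
# limits, and synthesis of the 3-channel image. The nested-contours detector
# itself runs on the raw image; this conditioning is offered for detectors
# that benefit from a standardized intensity distribution.

#' Truncation normalization
#'
#' Selects an effective minimum and maximum intensity as percentiles of the
#' non-zero (breast) pixels, cuts off intensities beyond them and linearly
#' rescales to the full output range. This guarantees the breast region a
#' sufficient intensity spread regardless of exposure.
#'
#' @param image a \linkS4class{GrayImage} with positive dynamic range.
#' @param params a \linkS4class{PreprocessParams}; \code{lowFraction} and
#'   \code{highFraction} give the percentile positions of the effective
#'   bounds (type-1 quantiles of the non-zero pixels; with both 0 the bounds
#'   are the plain min/max).
#' @return A \linkS4class{GrayImage} of the same dimensions spanning
#'   \code{[0, 2^bitDepth - 1]}.
#' @examples
#' im <- GrayImage(matrix(rep(0:255, each = 4), 32, 32), 8L)
#' tn <- truncationNormalize(im, PreprocessParams())
#' @export
truncationNormalize <- function(image, params = PreprocessParams()) {
  stopifnot(is(image, "GrayImage"), is(params, "PreprocessParams"))
  px <- image@pixels
  roi <- px[px > 0]
  if (length(roi) == 0L) roi <- as.vector(px)
  if (max(px) <= min(px))
    stop("degenerate image: no dynamic range to normalize")
  # fraction 0 means no truncation on that side: the bound is the global
  # extreme (the non-zero ROI restriction only shapes the percentiles)
  lo <- if (params@lowFraction == 0) min(px) else
    stats::quantile(roi, params@lowFraction, type = 1L, names = FALSE)
  hi <- if (params@highFraction == 0) max(px) else
    stats::quantile(roi, 1 - params@highFraction, type = 1L, names = FALSE)
  if (hi <= lo)
    stop("effective intensity bounds collapsed; decrease the fractions")
  out <- (pmin(pmax(px, lo), hi) - lo) / (hi - lo) * (2^image@bitDepth - 1)
  GrayImage(out, image@bitDepth)
}

# Per-tile clipped-histogram equalization LUT. Classic mapping
# (cdf - cdfmin)/(N - cdfmin); a tile whose pixels fall in a single bin maps
# identically (no contrast to redistribute).
.claheTileLut <- function(counts, clipLimit, nBins, outMax) {
  n <- sum(counts)
  if (sum(counts > 0) <= 1L) {     # single-bin tile: no contrast, identity
    return(seq(0, outMax, length.out = nBins))
  }
  clip <- max(1, clipLimit * n / nBins)
  excess <- sum(pmax(counts - clip, 0))
  counts <- pmin(counts, clip) + excess / nBins
  cdf <- cumsum(counts)
  cdfmin <- cdf[which(cdf > 0)[1L]]
  if (n - cdfmin <= 0) return(seq(0, outMax, length.out = nBins))
  pmin(pmax((cdf - cdfmin) / (n - cdfmin) * outMax, 0), outMax)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tiles the image, equalizes each tile with its histogram clipped at
#' \code{clipLimit} times the uniform bin height (the excess being
#' redistributed evenly), and blends neighbouring tile mappings bilinearly by
#' pixel position. A 1 x 1 grid with a very large clip limit reduces to plain
#' global histogram equalization; a constant image is returned unchanged.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param clipLimit positive contrast clip limit.
#' @param tileGrid integer c(rows, cols), default 8 x 8.
#' @param nBins number of histogram bins (256).
#' @return A \linkS4class{GrayImage} of identical dimensions and range.
#' @export
claheEnhance <- function(image, clipLimit = 2, tileGrid = c(8L, 8L),
                         nBins = 256L) {
  stopifnot(is(image, "GrayImage"))
  if (!is.numeric(clipLimit) || length(clipLimit) != 1L || clipLimit <= 0)
    stop("clipLimit must be a positive number")
  tileGrid <- as.integer(tileGrid)
  if (length(tileGrid) != 2L || any(tileGrid < 1L))
    stop("tileGrid must be two positive integers")
  px <- image@pixels
  h <- nrow(px); w <- ncol(px)
  outMax <- 2^image@bitDepth - 1
  ty <- min(tileGrid[1L], h); tx <- min(tileGrid[2L], w)

  # bin index per pixel over the full representable range
  bin <- pmin(floor(px / (outMax + 1) * nBins) + 1L, nBins)

  # tile boundaries (as equal as possible) and per-tile LUTs
  rowTile <- if (ty == 1L) rep(1L, h) else
    as.integer(cut(seq_len(h), breaks = ty, labels = FALSE))
  colTile <- if (tx == 1L) rep(1L, w) else
    as.integer(cut(seq_len(w), breaks = tx, labels = FALSE))
  luts <- array(0, dim = c(nBins, ty, tx))
  for (i in seq_len(ty)) for (j in seq_len(tx)) {
    counts <- tabulate(bin[rowTile == i, colTile == j, drop = FALSE], nBins)
    luts[, i, j] <- .claheTileLut(counts, clipLimit, nBins, outMax)
  }

  # tile centers for bilinear blending
  cy <- vapply(seq_len(ty), function(i) mean(range(which(rowTile == i))),
               numeric(1L))
  cx <- vapply(seq_len(tx), function(j) mean(range(which(colTile == j))),
               numeric(1L))
  iy <- findInterval(seq_len(h), cy)            # lower tile index (0..ty)
  ix <- findInterval(seq_len(w), cx)
  iy0 <- pmax(iy, 1L); iy1 <- pmin(iy + 1L, ty)
  ix0 <- pmax(ix, 1L); ix1 <- pmin(ix + 1L, tx)
  wy <- ifelse(iy1 > iy0, (seq_len(h) - cy[iy0]) / (cy[iy1] - cy[iy0]), 0)
  wx <- ifelse(ix1 > ix0, (seq_len(w) - cx[ix0]) / (cx[ix1] - cx[ix0]), 0)
  wy <- pmin(pmax(wy, 0), 1); wx <- pmin(pmax(wx, 0), 1)

  # blend the four surrounding tile LUTs, vectorized over the whole image
  B <- as.vector(bin)
  Ry0 <- rep(iy0, times = w); Ry1 <- rep(iy1, times = w)
  Cx0 <- rep(ix0, each = h);  Cx1 <- rep(ix1, each = h)
  Wy <- rep(wy, times = w);   Wx <- rep(wx, each = h)
  v00 <- luts[cbind(B, Ry0, Cx0)]
  v10 <- luts[cbind(B, Ry1, Cx0)]
  v01 <- luts[cbind(B, Ry0, Cx1)]
  v11 <- luts[cbind(B, Ry1, Cx1)]
  out <- (1 - Wy) * (1 - Wx) * v00 + Wy * (1 - Wx) * v10 +
         (1 - Wy) * Wx * v01 + Wy * Wx * v11
  GrayImage(matrix(out, h, w), image@bitDepth)
}

#' Synthesize the 3-channel enhanced image
#'
#' Channel 1 is the truncation-normalized image; channels 2 and 3 are its
#' CLAHE enhancements at the two configured clip limits.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param params a \linkS4class{PreprocessParams}.
#' @return A \linkS4class{ThreeChannelImage}.
#' @export
synthesizeThreeChannel <- function(image, params = PreprocessParams()) {
  stopifnot(is(image, "GrayImage"), is(params, "PreprocessParams"))
  ch1 <- truncationNormalize(image, params)
  ch2 <- claheEnhance(ch1, params@clipLimit1, params@tileGrid)
  ch3 <- claheEnhance(ch1, params@clipLimit2, params@tileGrid)
  new("ThreeChannelImage", chTrunc = ch1, chClahe1 = ch2, chClahe2 = ch3)
}
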