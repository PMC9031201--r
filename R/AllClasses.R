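#' @import methods
NULL

#' The six mammographic lesion appearance types
#'
#' Closed set of lesion-type labels used throughout the package: star-like
#' (spiculated) lesions, masses with unclear border, round- or oval-shaped
#' masses with clear border, asymmetric densities, changes invisible on the
#' dense parenchymal background, and partly visualized (edge-clipped) masses.
#'
#' @export
LESION_TYPES <- c(
  "star_like",
  "mass_unclear_border",
  "round_oval_clear_border",
  "asymmetric_density",
  "invisible_dense_background",
  "partly_visualized"
)

#' ACR breast-density classes
#' @export
DENSITY_CLASSES <- c("A", "B", "C", "D")

# ---------------------------------------------------------------- GrayImage

#' GrayImage: a 2-D grayscale intensity raster
#'
#' The unit of all processing: a numeric matrix of intensities (rows = y,
#' columns = x) together with its bit depth (8 or 16). All intensities must
#' lie within \code{[0, 2^bitDepth - 1]}.
#'
#' @slot pixels numeric matrix of intensities, \code{pixels[y + 1, x + 1]}
#'   addressing the pixel at 0-based coordinate (x, y).
#' @slot bitDepth integer, 8 or 16.
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", bitDepth = "integer"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1x1")
    if (length(object@bitDepth) != 1L || !object@bitDepth %in% c(8L, 16L))
      return("bitDepth must be 8 or 16")
    if (anyNA(p) || any(!is.finite(p))) return("pixels must be finite")
    mx <- 2^object@bitDepth - 1
    if (min(p) < 0 || max(p) > mx)
      return(sprintf("intensities must lie in [0, %d]", mx))
    TRUE
  }
)

#' Construct a GrayImage
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param bitDepth 8 or 16.
#' @return A \linkS4class{GrayImage}.
#' @examples
#' im <- GrayImage(matrix(0:255, 16, 16), 8L)
#' @export
GrayImage <- function(pixels, bitDepth = 8L) {
  new("GrayImage", pixels = as.matrix(pixels), bitDepth = as.integer(bitDepth))
}

# ---------------------------------------------------------------- contours

#' IsoContour: one closed iso-intensity polygon
#'
#' A closed simple polygon traced at a single intensity level, with sub-pixel
#' vertex coordinates in the image's 0-based (x, y) frame. Area, centroid,
#' perimeter and the axis-aligned bounding box are computed at construction.
#'
#' @slot level intensity value of the level set.
#' @slot vertices n x 2 matrix of (x, y) vertices; implicitly closed (the last
#'   vertex connects back to the first).
#' @slot area polygon area in pixels squared (shoelace formula).
#' @slot centroid polygon centroid (x, y).
#' @slot perimeter closed-polygon perimeter in pixels.
#' @slot bbox c(xmin, ymin, xmax, ymax) of the vertices.
#' @export
setClass("IsoContour",
  representation(level = "numeric", vertices = "matrix", area = "numeric",
                 centroid = "numeric", perimeter = "numeric", bbox = "numeric"),
  validity = function(object) {
    v <- object@vertices
    if (ncol(v) != 2L) return("vertices must be an n x 2 matrix")
    if (nrow(v) < 3L) return("a polygon needs at least 3 vertices")
    if (anyNA(v)) return("vertices must be finite")
    if (length(object@level) != 1L) return("level must be a scalar")
    if (object@area <= 0) return("contour area must be positive")
    TRUE
  }
)

.polyArea <- function(v) {
  # shoelace; vertices implicitly closed
  x <- v[, 1L]; y <- v[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  abs(sum(x * y2 - x2 * y)) / 2
}

.polyCentroid <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

.polyPerimeter <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(sqrt((x2 - x)^2 + (y2 - y)^2))
}

#' Construct an IsoContour
#'
#' @param level intensity level.
#' @param vertices n x 2 matrix of (x, y) coordinates; a duplicated closing
#'   vertex is removed.
#' @return An \linkS4class{IsoContour}.
#' @export
IsoContour <- function(level, vertices) {
  vertices <- as.matrix(vertices)
  n <- nrow(vertices)
  if (n > 1L && all(vertices[1L, ] == vertices[n, ]))
    vertices <- vertices[-n, , drop = FALSE]
  new("IsoContour",
      level = as.numeric(level), vertices = vertices,
      area = .polyArea(vertices), centroid = .polyCentroid(vertices),
      perimeter = .polyPerimeter(vertices),
      bbox = c(min(vertices[, 1L]), min(vertices[, 2L]),
               max(vertices[, 1L]), max(vertices[, 2L])))
}

#' ContourNest: an ordered chain of nested iso-contours
#'
#' Contours are ordered by strictly increasing level; each contour
#' geometrically contains the next (brighter, inner) one. The dissimilarity
#' trace holds the per-step dissimilarity between consecutive contours.
#'
#' @slot contours list of \linkS4class{IsoContour}, outermost (lowest level)
#'   first.
#' @slot dissimilarityTrace numeric vector of length \code{depth - 1}.
#' @export
setClass("ContourNest",
  representation(contours = "list", dissimilarityTrace = "numeric"),
  validity = function(object) {
    cs <- object@contours
    if (length(cs) < 1L) return("a nest needs at least one contour")
    if (!all(vapply(cs, is, logical(1L), class2 = "IsoContour")))
      return("contours must be IsoContour objects")
    lv <- vapply(cs, function(c) c@level, numeric(1L))
    if (length(lv) > 1L && any(diff(lv) <= 0))
      return("levels must be strictly increasing")
    if (length(object@dissimilarityTrace) != length(cs) - 1L)
      return("dissimilarityTrace must have depth - 1 entries")
    for (i in seq_len(length(cs) - 1L))
      if (!containsContour(cs[[i]], cs[[i + 1L]]))
        return(sprintf("contour %d does not contain contour %d", i, i + 1L))
    TRUE
  }
)

#' Construct a ContourNest
#'
#' The dissimilarity trace is computed with \code{\link{stepDissimilarity}}
#' unless supplied.
#'
#' @param contours list of \linkS4class{IsoContour}, lowest level first.
#' @param dissimilarityTrace optional precomputed trace.
#' @return A \linkS4class{ContourNest}.
#' @export
ContourNest <- function(contours, dissimilarityTrace = NULL) {
  if (is.null(dissimilarityTrace)) {
    n <- length(contours)
    dissimilarityTrace <- if (n < 2L) numeric(0L) else
      vapply(seq_len(n - 1L), function(i)
        stepDissimilarity(contours[[i]], contours[[i + 1L]]), numeric(1L))
  }
  new("ContourNest", contours = contours,
      dissimilarityTrace = as.numeric(dissimilarityTrace))
}

# ---------------------------------------------------------------- parameters

#' NCAParams: tuning parameters of the nested contours algorithm
#'
#' @slot k gradation step in intensity units; \code{NA} means
#'   (image max - image min) / 32, i.e. levels are placed relative to the
#'   image's own brightness range.
#' @slot minDepth minimum chain length for a surviving mass candidate.
#' @slot tauArea maximum allowed successive area-ratio deviation
#'   \code{|1 - area(next)/area(prev)|}.
#' @slot tauShift maximum allowed centroid shift normalized by the equivalent
#'   radius \code{sqrt(area(prev)/pi)}.
#' @slot minArea,maxArea pixel-squared bounds on the representative contour;
#'   \code{maxArea = NA} means 25\% of the image area.
#' @slot polarity only \code{"bright_on_dark"} (masses are radiopaque).
#' @export
setClass("NCAParams",
  representation(k = "numeric", minDepth = "integer", tauArea = "numeric",
                 tauShift = "numeric", minArea = "numeric", maxArea = "numeric",
                 polarity = "character"),
  validity = function(object) {
    if (!is.na(object@k) && object@k <= 0) return("k must be positive")
    if (object@minDepth < 2L) return("minDepth must be >= 2")
    if (object@tauArea <= 0 || object@tauShift <= 0)
      return("dissimilarity thresholds must be positive")
    if (!is.na(object@maxArea) && object@minArea >= object@maxArea)
      return("minArea must be smaller than maxArea")
    if (!identical(object@polarity, "bright_on_dark"))
      return("polarity must be 'bright_on_dark'")
    TRUE
  }
)

#' Construct NCAParams
#'
#' @param k gradation step; \code{NA} (default) places 32 steps across the
#'   image's brightness range.
#' @param minDepth minimum accepted chain depth.
#' @param tauArea,tauShift discard-rule thresholds (see
#'   \code{\link{stepDissimilarity}}).
#' @param minArea,maxArea candidate area bounds in pixels squared;
#'   \code{maxArea = NA} resolves to 25\% of the image area.
#' @param polarity fixed to \code{"bright_on_dark"}.
#' @return An \linkS4class{NCAParams}.
#' @examples
#' NCAParams(minDepth = 4L)
#' @export
NCAParams <- function(k = NA_real_, minDepth = 3L, tauArea = 0.35,
                      tauShift = 0.2, minArea = 25, maxArea = NA_real_,
                      polarity = "bright_on_dark") {
  new("NCAParams", k = as.numeric(k), minDepth = as.integer(minDepth),
      tauArea = tauArea, tauShift = tauShift, minArea = minArea,
      maxArea = as.numeric(maxArea), polarity = polarity)
}

#' LesionCandidate: one detected mass
#'
#' @slot contour representative \linkS4class{IsoContour} (the outermost
#'   retained contour of the chain).
#' @slot box integer-valued c(xmin, ymin, xmax, ymax), 0-based half-open.
#' @slot depth nest depth of the surviving chain.
#' @slot score depth-weighted circularity,
#'   \code{depth * 4 * pi * area / perimeter^2}.
#' @export
setClass("LesionCandidate",
  representation(contour = "IsoContour", box = "numeric", depth = "integer",
                 score = "numeric"),
  validity = function(object) {
    b <- object@box
    if (length(b) != 4L) return("box must be c(xmin, ymin, xmax, ymax)")
    if (b[1L] >= b[3L] || b[2L] >= b[4L]) return("box must have positive extent")
    if (object@depth < 1L) return("depth must be positive")
    if (object@score < 0) return("score must be non-negative")
    TRUE
  }
)

#' PreprocessParams: parameters of the three-step image enhancement
#'
#' @slot lowFraction,highFraction percentile fractions in [0, 1) defining the
#'   effective minimum/maximum intensity over the non-zero (breast) pixels.
#' @slot clipLimit1,clipLimit2 CLAHE contrast clip limits of the two enhanced
#'   channels (multiples of the uniform per-tile bin height).
#' @slot tileGrid integer c(rows, cols) CLAHE tile grid.
#' @export
setClass("PreprocessParams",
  representation(lowFraction = "numeric", highFraction = "numeric",
                 clipLimit1 = "numeric", clipLimit2 = "numeric",
                 tileGrid = "integer"),
  validity = function(object) {
    if (object@lowFraction < 0 || object@lowFraction >= 1 ||
        object@highFraction < 0 || object@highFraction >= 1)
      return("fractions must lie in [0, 1)")
    if (object@lowFraction >= 1 - object@highFraction)
      return("lowFraction must be below 1 - highFraction")
    if (object@clipLimit1 <= 0 || object@clipLimit2 <= 0)
      return("clip limits must be positive")
    if (object@clipLimit1 == object@clipLimit2)
      return("the two clip limits must differ")
    if (length(object@tileGrid) != 2L || any(object@tileGrid < 1L))
      return("tileGrid must be two positive integers")
    TRUE
  }
)

#' Construct PreprocessParams
#'
#' @param lowFraction,highFraction robust-range percentile fractions
#'   (defaults 0.01).
#' @param clipLimit1,clipLimit2 CLAHE clip limits of channels 2 and 3
#'   (defaults 1 and 2, read literally from the pre-processing recipe).
#' @param tileGrid CLAHE tile grid, default 8 x 8.
#' @return A \linkS4class{PreprocessParams}.
#' @export
PreprocessParams <- function(lowFraction = 0.01, highFraction = 0.01,
                             clipLimit1 = 1, clipLimit2 = 2,
                             tileGrid = c(8L, 8L)) {
  new("PreprocessParams", lowFraction = lowFraction, highFraction = highFraction,
      clipLimit1 = clipLimit1, clipLimit2 = clipLimit2,
      tileGrid = as.integer(tileGrid))
}

#' ThreeChannelImage: truncation-normalized image plus two CLAHE channels
#'
#' @slot chTrunc truncation-normalized channel.
#' @slot chClahe1 CLAHE of chTrunc at clip limit 1.
#' @slot chClahe2 CLAHE of chTrunc at clip limit 2.
#' @export
setClass("ThreeChannelImage",
  representation(chTrunc = "GrayImage", chClahe1 = "GrayImage",
                 chClahe2 = "GrayImage"),
  validity = function(object) {
    d <- dim(object@chTrunc@pixels)
    if (!identical(d, dim(object@chClahe1@pixels)) ||
        !identical(d, dim(object@chClahe2@pixels)))
      return("all three channels must share dimensions")
    TRUE
  }
)

# ---------------------------------------------------------------- metrics

#' ConfusionCounts: TP/FP/FN tallies of a detection run
#'
#' There is no true-negative cell: in a detection task every image region not
#' marked and not annotated is an uncounted background.
#'
#' @slot tp,fp,fn non-negative integer counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", fn = "integer"),
  validity = function(object) {
    if (object@tp < 0L || object@fp < 0L || object@fn < 0L)
      return("counts must be non-negative")
    TRUE
  }
)

#' Construct ConfusionCounts
#' @param tp,fp,fn non-negative integer counts.
#' @export
ConfusionCounts <- function(tp = 0L, fp = 0L, fn = 0L) {
  new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn))
}

#' MetricReport: derived detection scores with their source counts
#'
#' @slot counts overall \linkS4class{ConfusionCounts}.
#' @slot precision,recall,f1 reals in [0, 1] under the declared rounding mode
#'   (\code{NA} when undefined).
#' @slot fBeta named numeric, F-beta score per requested beta.
#' @slot perType data.frame with one row per lesion type plus a Total row
#'   (columns lesion_type, tp, fp, fn).
#' @slot roundingMode \code{"truncate_2dp"} or \code{"round_2dp"}.
#' @export
setClass("MetricReport",
  representation(counts = "ConfusionCounts", precision = "numeric",
                 recall = "numeric", f1 = "numeric", fBeta = "numeric",
                 perType = "data.frame", roundingMode = "character"),
  validity = function(object) {
    if (!object@roundingMode %in% c("truncate_2dp", "round_2dp"))
      return("roundingMode must be 'truncate_2dp' or 'round_2dp'")
    TRUE
  }
)

# ---------------------------------------------------------------- phantoms

#' PhantomSpec: declarative recipe for one synthetic mammography phantom
#'
#' @slot shape integer c(height, width) in pixels.
#' @slot densityClass ACR density class "A".."D".
#' @slot lesions list of lesion descriptors, each a list with fields
#'   \code{lesion_type}, \code{center} (x, y), \code{size_px},
#'   \code{contrast} in (0, 1], optional \code{n_spicula}.
#' @slot noiseSigma additive Gaussian noise standard deviation (intensity
#'   units).
#' @slot textureStrength non-negative multiplier of the parenchyma texture
#'   amplitude.
#' @slot seed integer; fixes the phantom completely.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", densityClass = "character",
                 lesions = "list", noiseSigma = "numeric",
                 textureStrength = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@shape) != 2L || any(object@shape < 8L))
      return("shape must be two integers >= 8")
    if (!object@densityClass %in% DENSITY_CLASSES)
      return("densityClass must be one of A, B, C, D")
    for (les in object@lesions) {
      if (!is.list(les) || is.null(les$lesion_type))
        return("each lesion needs a lesion_type")
      if (!les$lesion_type %in% LESION_TYPES)
        return(sprintf("unknown lesion_type '%s'", les$lesion_type))
      if (!is.null(les$contrast) &&
          (les$contrast <= 0 || les$contrast > 1))
        return("lesion contrast must lie in (0, 1]")
    }
    if (object@noiseSigma < 0) return("noiseSigma must be non-negative")
    if (object@textureStrength < 0)
      return("textureStrength must be non-negative")
    TRUE
  }
)

#' Construct a PhantomSpec
#'
#' @param shape c(height, width) in pixels.
#' @param densityClass "A", "B", "C" or "D".
#' @param lesions list of lesion descriptors (see \linkS4class{PhantomSpec}).
#' @param noiseSigma additive Gaussian noise sigma.
#' @param textureStrength texture amplitude multiplier.
#' @param seed integer seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(shape = c(512L, 512L), densityClass = "B",
                        lesions = list(), noiseSigma = 2,
                        textureStrength = 1, seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape), densityClass = densityClass,
      lesions = lesions, noiseSigma = noiseSigma,
      textureStrength = textureStrength, seed = as.integer(seed))
}
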