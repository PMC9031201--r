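# Seeded mammography-like phantoms. Stylized, not photorealistic: their job
# is to exercise the nesting logic of the detector across the clinically
# motivated difficulty spectrum (spiculated, unclear-border, clear-border,
# asymmetric, invisible-on-dense-background and edge-clipped lesions) over
# four ACR density backgrounds, with exact ground truth.

# per-class background parameters (8-bit intensities): base parenchyma mean
# and band-limited texture amplitude both increase from fatty (A) to dense (D)
.densityMean <- c(A = 60, B = 90, C = 120, D = 150)
.densityTexAmp <- c(A = 4, B = 10, C = 16, D = 24)

.gblur <- function(m, sigma) {
  as.matrix(EBImage::imageData(EBImage::gblur(m, sigma = sigma)))
}

.breastMask <- function(h, w) {
  # half-ellipse anchored at the chest wall (left image edge)
  x <- matrix(rep(0:(w - 1L), each = h), h, w)
  y <- matrix(rep(0:(h - 1L), times = w), h, w)
  (x / (0.85 * w))^2 + ((y - h / 2) / (0.48 * h))^2 <= 1
}

#' Generate a parenchyma background of a given ACR density class
#'
#' Base intensity and texture amplitude increase from class A (fatty: low
#' mean, weak texture) to D (dense: high mean, strong low-frequency
#' texture). The breast-shaped support is a half-ellipse against the left
#' (chest-wall) edge; intensity is zero outside it.
#'
#' @param densityClass "A", "B", "C" or "D".
#' @param shape integer c(height, width).
#' @param textureStrength non-negative texture multiplier; 0 gives a
#'   spatially constant breast region.
#' @param seed integer; the background is fully determined by it.
#' @return A \linkS4class{GrayImage} (8-bit).
#' @export
genBackground <- function(densityClass, shape = c(512L, 512L),
                          textureStrength = 1, seed = 1L) {
  if (!densityClass %in% DENSITY_CLASSES)
    stop("unknown density class: ", densityClass)
  h <- as.integer(shape[1L]); w <- as.integer(shape[2L])
  set.seed(as.integer(seed))
  mask <- .breastMask(h, w)
  bg <- matrix(.densityMean[[densityClass]], h, w)
  amp <- .densityTexAmp[[densityClass]] * textureStrength
  if (amp > 0) {
    t1 <- .gblur(matrix(stats::rnorm(h * w), h, w), sigma = 6)
    t1 <- t1 / stats::sd(t1) * amp
    tex <- t1
    if (densityClass %in% c("C", "D")) {
      # dense classes get an extra low-frequency structural component
      t2 <- .gblur(matrix(stats::rnorm(h * w), h, w), sigma = 20)
      tex <- tex + t2 / stats::sd(t2) * (0.5 * amp)
    }
    bg <- bg + tex
  }
  bg[!mask] <- 0
  GrayImage(pmin(pmax(bg, 0), 255), 8L)
}

#' Generate one lesion intensity patch with its truth mask
#'
#' Returns a square patch with peak intensity 1 plus the logical truth mask
#' (patch at or above 10\% of its peak: the lesion's visible extent, down
#' to where it fades into the background). The
#' appearance follows the lesion type: \code{star_like} is a dense Gaussian
#' core with \code{nSpicula} thin radial ridges; \code{mass_unclear_border}
#' a wide Gaussian; \code{round_oval_clear_border} a flat ellipse with a
#' sharp sigmoid edge; \code{asymmetric_density} an anisotropic two-lobed
#' blob; \code{invisible_dense_background} shares the unclear-border shape
#' (its near-invisibility comes from the low contrast its composer assigns,
#' at most 20\% of the background texture amplitude);
#' \code{partly_visualized} shares the clear-border shape (its
#' edge-clipping comes from placement near the image border).
#'
#' @param lesionType one of \code{LESION_TYPES}.
#' @param sizePx nominal lesion diameter in pixels.
#' @param nSpicula number of radial spicula for star-like lesions.
#' @param seed integer controlling the random orientation/phase.
#' @return list(patch = matrix in [0, 1], mask = logical matrix).
#' @export
genLesion <- function(lesionType, sizePx = 48, nSpicula = 8L, seed = 1L) {
  if (!lesionType %in% LESION_TYPES)
    stop("unknown lesion type: ", lesionType)
  set.seed(as.integer(seed))
  R <- sizePx / 2
  n <- 2L * as.integer(ceiling(1.8 * sizePx / 2)) + 1L
  cc <- (n - 1) / 2
  x <- matrix(rep(seq_len(n) - 1 - cc, each = n), n, n)
  y <- matrix(rep(seq_len(n) - 1 - cc, times = n), n, n)
  r <- sqrt(x^2 + y^2)
  phi <- stats::runif(1L, 0, 2 * pi)
  rot <- function(sx, sy) {         # rotated anisotropic radius
    xr <- x * cos(phi) + y * sin(phi)
    yr <- -x * sin(phi) + y * cos(phi)
    sqrt((xr / sx)^2 + (yr / sy)^2)
  }
  patch <- switch(lesionType,
    star_like = {
      # dense core with thin radial spicula of defined length (sharp
      # radial cut-off at one lesion radius)
      theta <- atan2(y, x)
      core <- exp(-(r / (0.5 * R))^2)
      arms <- pmax(cos(nSpicula * (theta - phi)), 0)^6 /
        (1 + exp((r / R - 1) / 0.05))
      pmax(core, 0.3 * arms)
    },
    mass_unclear_border = exp(-(r / (0.75 * R))^2),
    round_oval_clear_border = 1 / (1 + exp((rot(R, 0.75 * R) - 1) / 0.04)),
    asymmetric_density = {
      d1 <- rot(R, 0.4 * R)
      xo <- x - 0.5 * R * cos(phi); yo <- y - 0.5 * R * sin(phi)
      xr <- xo * cos(phi) + yo * sin(phi)
      yr <- -xo * sin(phi) + yo * cos(phi)
      d2 <- sqrt((xr / (0.5 * R))^2 + (yr / (0.55 * R))^2)
      pmax(exp(-d1^2), 0.6 * exp(-d2^2))
    },
    invisible_dense_background = exp(-(r / (0.75 * R))^2),
    partly_visualized = 1 / (1 + exp((rot(R, 0.75 * R) - 1) / 0.04))
  )
  patch <- patch / max(patch)
  list(patch = patch, mask = patch >= 0.1)
}

#' Compose a phantom from its declarative spec
#'
#' Renders the background, additively blends each lesion (peak amplitude =
#' contrast times the headroom above the local background median), adds
#' Gaussian noise, clamps to the 8-bit range, and derives annotations as
#' the tight axis-aligned boxes of the clipped truth masks.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list(image = \linkS4class{GrayImage}, annotations = data.frame
#'   with columns x_min, y_min, x_max, y_max, lesion_type, density_class).
#' @export
composePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  h <- spec@shape[1L]; w <- spec@shape[2L]
  bg <- genBackground(spec@densityClass, spec@shape, spec@textureStrength,
                      spec@seed)
  px <- bg@pixels
  ann <- .emptyAnnotations()
  ann$density_class <- character(0)
  for (i in seq_along(spec@lesions)) {
    les <- spec@lesions[[i]]
    g <- genLesion(les$lesion_type, les$size_px,
                   nSpicula = les$n_spicula %||% 8L,
                   seed = (spec@seed + 7919L * i) %% 2147483647L)
    n <- nrow(g$patch)
    cc <- (n - 1) / 2
    x0 <- round(les$center[1L] - cc); y0 <- round(les$center[2L] - cc)
    # overlap of the patch with the image
    pxr <- max(1L, 1L - x0):min(n, w - x0)
    pyr <- max(1L, 1L - y0):min(n, h - y0)
    if (!length(pxr) || !length(pyr) || min(pxr) > max(pxr) ||
        min(pyr) > max(pyr)) {
      warning("lesion ", i, " falls entirely outside the image; dropped")
      next
    }
    ixr <- (pxr + x0); iyr <- (pyr + y0)      # 1-based image columns/rows
    sub <- px[iyr, ixr, drop = FALSE]
    amp <- les$contrast * max(255 - stats::median(sub), 0)
    px[iyr, ixr] <- sub + amp * g$patch[pyr, pxr, drop = FALSE]
    m <- g$mask[pyr, pxr, drop = FALSE]
    if (!any(m)) {
      warning("lesion ", i, " truth mask clipped to zero area; dropped")
      next
    }
    cols <- range(which(apply(m, 2L, any)))
    rows <- range(which(apply(m, 1L, any)))
    ann <- rbind(ann, data.frame(
      x_min = ixr[cols[1L]] - 1, y_min = iyr[rows[1L]] - 1,
      x_max = ixr[cols[2L]], y_max = iyr[rows[2L]],
      lesion_type = les$lesion_type, density_class = spec@densityClass))
  }
  if (spec@noiseSigma > 0) {
    set.seed((spec@seed + 999331L) %% 2147483647L)
    px <- px + matrix(stats::rnorm(h * w, sd = spec@noiseSigma), h, w)
  }
  list(image = GrayImage(pmin(pmax(px, 0), 255), 8L), annotations = ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default contrasts of the visible lesion types (fraction of the headroom
# above the local background); the invisible type instead receives an
# absolute amplitude of 20% of its background's texture amplitude
.typeContrast <- c(star_like = 0.8, mass_unclear_border = 0.5,
                   round_oval_clear_border = 0.8, asymmetric_density = 0.4,
                   partly_visualized = 0.8)

#' Generate a seeded synthetic test set
#'
#' Emits \code{nPositive} single-lesion phantoms whose lesion-type and ACR
#' density compositions follow the given count distributions (defaults: 16
#' star-like / 30 unclear border / 8 clear border / 28 asymmetric / 16
#' invisible / 2 partly visualized, and densities 27 A / 33 B / 31 C / 9 D),
#' plus \code{nNegative} lesion-free phantoms. Fully reproducible from the
#' seed.
#'
#' @param nPositive,nNegative image counts.
#' @param typeDistribution integer counts per \code{LESION_TYPES}, summing
#'   to \code{nPositive}.
#' @param densityDistribution integer counts per \code{DENSITY_CLASSES},
#'   summing to \code{nPositive}.
#' @param seed integer master seed.
#' @param shape phantom shape c(height, width), default 512 x 512.
#' @param dir optional output directory: PNG images plus a manifest JSON
#'   with annotations and spec echoes are written there.
#' @param render if FALSE, only the \linkS4class{PhantomSpec}s and manifest
#'   are returned (images composed lazily by the caller).
#' @return list with \code{specs} (list of \linkS4class{PhantomSpec}),
#'   \code{samples} (when rendered: list of composePhantom results),
#'   \code{manifest} (data.frame: id, positive, density_class,
#'   lesion_type).
#' @export
genTestSet <- function(nPositive = 100L, nNegative = 100L,
                       typeDistribution = c(16L, 30L, 8L, 28L, 16L, 2L),
                       densityDistribution = c(27L, 33L, 31L, 9L),
                       seed = 1L, shape = c(512L, 512L), dir = NULL,
                       render = TRUE) {
  if (sum(typeDistribution) != nPositive)
    stop("typeDistribution must sum to nPositive")
  if (sum(densityDistribution) != nPositive)
    stop("densityDistribution must sum to nPositive")
  set.seed(as.integer(seed))
  types <- rep(LESION_TYPES, typeDistribution)
  dens <- sample(rep(DENSITY_CLASSES, densityDistribution))
  h <- shape[1L]; w <- shape[2L]
  specs <- vector("list", nPositive + nNegative)
  for (i in seq_len(nPositive)) {
    ty <- types[i]; dc <- dens[i]
    size <- stats::runif(1L, 0.08, 0.14) * min(h, w)
    if (ty == "partly_visualized") {
      centre <- c(0.3 * size, stats::runif(1L, 0.35, 0.65) * h)
    } else {
      centre <- c(stats::runif(1L, 0.15, 0.55) * w,
                  stats::runif(1L, 0.3, 0.7) * h)
    }
    contrast <- if (ty == "invisible_dense_background") {
      texAmp <- .densityTexAmp[[dc]]
      min(1, 0.2 * texAmp / max(255 - .densityMean[[dc]], 1))
    } else .typeContrast[[ty]]
    specs[[i]] <- PhantomSpec(
      shape = shape, densityClass = dc,
      lesions = list(list(lesion_type = ty, center = centre,
                          size_px = size, contrast = contrast,
                          n_spicula = 8L)),
      noiseSigma = 2, textureStrength = 1,
      seed = (seed + 104729L * i) %% 2147483647L)
  }
  densNeg <- sample(rep(DENSITY_CLASSES, densityDistribution),
                    nNegative, replace = TRUE)
  for (i in seq_len(nNegative)) {
    specs[[nPositive + i]] <- PhantomSpec(
      shape = shape, densityClass = densNeg[i], lesions = list(),
      noiseSigma = 2, textureStrength = 1,
      seed = (seed + 104729L * (nPositive + i)) %% 2147483647L)
  }
  manifest <- data.frame(
    id = sprintf("phantom_%03d", seq_along(specs)),
    positive = rep(c(TRUE, FALSE), c(nPositive, nNegative)),
    density_class = c(dens, densNeg),
    lesion_type = c(types, rep(NA_character_, nNegative)))
  out <- list(specs = specs, manifest = manifest)
  if (render || !is.null(dir)) {
    out$samples <- lapply(specs, composePhantom)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      files <- file.path(dir, paste0(manifest$id, ".png"))
      for (i in seq_along(out$samples))
        saveImage(out$samples[[i]]$image, files[i])
      manifestJson <- list(
        seed = seed, shape = shape,
        images = lapply(seq_along(out$samples), function(i) list(
          id = manifest$id[i], file = basename(files[i]),
          positive = manifest$positive[i],
          density_class = manifest$density_class[i],
          annotations = .annotationsToList(out$samples[[i]]$annotations))))
      jsonlite::write_json(manifestJson, file.path(dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      out$dir <- dir
    }
  }
  out
}
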