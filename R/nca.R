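# The nested contours algorithm (NCA).
#
# Masses are radiopaque: on a mammogram they appear as bright, roughly
# compact regions whose iso-intensity contours, traced at successively
# higher brightness levels, shrink gradually and stay concentric. The NCA
# exploits exactly this: level sets are built over the entire brightness
# range of the raw image at a constant gradation step k, nested contours are
# linked into chains from the lowest level upward, and a chain is cut where
# a contour stops resembling the one found at the previous gradation step
# (abrupt area change or centroid drift). Chains that stay similar for at
# least minDepth steps are the mass candidates. No pre-processing is
# required; the detector is driven by the source image alone.

#' Build iso-intensity contours over the whole brightness range
#'
#' Level sets are traced (marching squares with sub-pixel linear
#' interpolation, via \code{\link[grDevices]{contourLines}}) at thresholds
#' \code{min + k, min + 2k, ...} strictly below the image maximum, where
#' min/max are taken over the image itself, so the level placement is
#' relative to the image's own brightness range. Contours touching the image
#' border are closed along the border, keeping partly visualized
#' (edge-clipped) masses detectable.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param k gradation step in intensity units; \code{NA} (default) uses
#'   (max - min) / 32.
#' @return List of \linkS4class{IsoContour}, sorted by increasing level.
#'   Empty for a degenerate (constant) image.
#' @examples
#' g <- outer(1:64, 1:64, function(y, x)
#'   100 * exp(-((x - 32)^2 + (y - 32)^2) / (2 * 8^2)))
#' cs <- buildLevelContours(GrayImage(g, 8L), k = 10)
#' @export
buildLevelContours <- function(image, k = NA_real_) {
  lapply(.traceContours(image, k), function(r) {
    con <- new("IsoContour", level = r$level, vertices = r$v, area = r$area,
               centroid = r$centroid, perimeter = r$perimeter, bbox = r$bbox)
    con
  })
}

# plain-list contour records (level, v, area, centroid, perimeter, bbox);
# the hot path works on these and materializes IsoContour objects only at
# the API boundary
.traceContours <- function(image, k = NA_real_) {
  stopifnot(is(image, "GrayImage"))
  px <- image@pixels
  mn <- min(px); mx <- max(px)
  if (mx <= mn) return(list())
  if (is.na(k)) k <- (mx - mn) / 32
  if (k <= 0) stop("gradation step k must be positive")
  nlev <- floor((mx - mn) / k - 1e-9)
  if (nlev < 1L) return(list())
  levels <- mn + k * seq_len(nlev)

  nr <- nrow(px); nc <- ncol(px)
  # pad with a below-minimum frame: every level curve closes, border-touching
  # regions are closed along the border after clamping
  zp <- matrix(mn - k, nr + 2L, nc + 2L)
  zp[2L:(nr + 1L), 2L:(nc + 1L)] <- px
  ys <- (0L:(nr + 1L)) - 1      # pixel-center coords of padded rows (y)
  xs <- (0L:(nc + 1L)) - 1
  cl <- grDevices::contourLines(ys, xs, zp, levels = levels)

  out <- vector("list", length(cl))
  nOut <- 0L
  for (cc in cl) {
    # contourLines' first axis follows rows (our y), second follows cols (x)
    vx <- pmin(pmax(cc$y, 0), nc - 1L)
    vy <- pmin(pmax(cc$x, 0), nr - 1L)
    keep <- c(TRUE, diff(vx) != 0 | diff(vy) != 0)   # clamping duplicates
    n <- sum(keep)
    if (n > 1L && vx[keep][1L] == vx[keep][n] && vy[keep][1L] == vy[keep][n])
      keep[which(keep)[n]] <- FALSE
    v <- cbind(x = vx[keep], y = vy[keep])
    if (nrow(v) < 3L) next
    a <- .polyArea(v)
    if (a <= 1e-9) next
    nOut <- nOut + 1L
    inpix <- .innerPixel(v, px, cc$level, nr, nc)
    # hole contours (pit boundaries) have their iso-region pixel outside
    # their own polygon; flag them so the raster linker can skip them
    hole <- if (is.null(inpix)) NA else
      !mgcv::in.out(rbind(v, v[1L, ]),
                    cbind(inpix[2L] - 1, inpix[1L] - 1))[1L]
    out[[nOut]] <- list(level = cc$level, v = v, area = a,
                        centroid = .polyCentroid(v),
                        perimeter = .polyPerimeter(v),
                        bbox = c(min(v[, 1L]), min(v[, 2L]),
                                 max(v[, 1L]), max(v[, 2L])),
                        inpix = inpix, hole = hole)
  }
  out <- out[seq_len(nOut)]
  out[order(vapply(out, function(c) c$level, numeric(1L)))]
}

# A pixel guaranteed inside the contour's iso-region: a fractional vertex
# is a marching-squares crossing on a grid edge whose two endpoint pixels
# straddle the level; the >= endpoint lies in the region. Returns 1-based
# c(row, col) or NULL for fully border-clamped contours.
.innerPixel <- function(v, px, level, nr, nc) {
  fx <- which(v[, 1L] %% 1 != 0)
  for (i in fx[seq_len(min(4L, length(fx)))]) {
    row <- v[i, 2L] + 1
    if (row %% 1 != 0) next
    for (col in c(floor(v[i, 1L]) + 1, floor(v[i, 1L]) + 2)) {
      if (col >= 1 && col <= nc && row >= 1 && row <= nr &&
          px[row, col] >= level) return(c(row, col))
    }
  }
  fy <- which(v[, 2L] %% 1 != 0)
  for (i in fy[seq_len(min(4L, length(fy)))]) {
    col <- v[i, 1L] + 1
    if (col %% 1 != 0) next
    for (row in c(floor(v[i, 2L]) + 1, floor(v[i, 2L]) + 2)) {
      if (col >= 1 && col <= nc && row >= 1 && row <= nr &&
          px[row, col] >= level) return(c(row, col))
    }
  }
  NULL
}

# squared distance from points (px, py) to segment (x1,y1)-(x2,y2)
.pointSegDist2 <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / pmax(l2, 1e-300), 0), 1)
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

# Containment during linking needs only one test point: iso-regions at
# level l + k are strictly nested inside regions at level l, and each
# connected component lies in exactly one parent component, so any interior
# point of the inner contour decides its parent. A marching-squares vertex
# with a fractional coordinate is a true interpolated crossing, strictly
# interior to the parent region; border-clamped vertices (both coordinates
# integer) are ambiguous, triggering the all-vertex test (.containsRec).

#' @rdname containsContour
#' @export
setMethod("containsContour", signature("IsoContour", "IsoContour"),
  function(outer, inner) {
    bo <- outer@bbox; bi <- inner@bbox
    eps <- 1e-9
    if (bi[1L] < bo[1L] - eps || bi[2L] < bo[2L] - eps ||
        bi[3L] > bo[3L] + eps || bi[4L] > bo[4L] + eps) return(FALSE)
    vo <- outer@vertices
    bnd <- rbind(vo, vo[1L, ])
    vi <- inner@vertices
    inside <- mgcv::in.out(bnd, vi)
    if (all(inside)) return(TRUE)
    # in.out is strict-interior: allow vertices lying on the outer boundary
    for (i in which(!inside)) {
      d2 <- .pointSegDist2(vi[i, 1L], vi[i, 2L],
                           bnd[-nrow(bnd), 1L], bnd[-nrow(bnd), 2L],
                           bnd[-1L, 1L], bnd[-1L, 2L])
      if (min(d2) > 1e-12) return(FALSE)
    }
    TRUE
  })

#' Dissimilarity between consecutive nested contours
#'
#' The discard rule's measure of how much a contour differs from the nested
#' one obtained at the previous gradation step: the maximum of the
#' area-ratio deviation \code{|1 - area(next)/area(prev)|} and the centroid
#' shift normalized by the equivalent radius \code{sqrt(area(prev)/pi)}.
#' Zero for identical contours; grows with abrupt expansion (parenchyma
#' flooding) or drift (merging with an adjacent structure).
#'
#' @param prev,next_ consecutive \linkS4class{IsoContour}s,
#'   \code{containsContour(prev, next_)} assumed.
#' @return Non-negative real.
#' @examples
#' sq <- function(s) IsoContour(1, cbind(c(-s,s,s,-s), c(-s,-s,s,s)))
#' stepDissimilarity(sq(10), sq(8))   # |1 - 64/100| = 0.36
#' @export
stepDissimilarity <- function(prev, next_) {
  stopifnot(is(prev, "IsoContour"), is(next_, "IsoContour"))
  if (prev@area <= 0) stop("zero-area reference contour")
  max(abs(1 - next_@area / prev@area),
      sqrt(sum((next_@centroid - prev@centroid)^2)) / sqrt(prev@area / pi))
}

.dissimComponents <- function(prev, next_) {
  c(area = abs(1 - next_@area / prev@area),
    shift = sqrt(sum((next_@centroid - prev@centroid)^2)) /
      sqrt(prev@area / pi))
}

#' Link contours into nested chains
#'
#' Chains are grown greedily from the lowest brightness level upward: a
#' contour at level l + k is appended to the chain whose level-l tip
#' contains it (the innermost containing tip when contours at a level are
#' themselves nested); a tip containing no next-level contour terminates its
#' chain; a tip containing several candidates extends with the
#' largest-area one (ties broken by the smallest centroid shift) while the
#' others start new chains. Every contour belongs to at most one chain.
#'
#' @param contourList list of \linkS4class{IsoContour} from
#'   \code{\link{buildLevelContours}} (constant step k).
#' @param params an \linkS4class{NCAParams}; only \code{k} is consulted (to
#'   recognise consecutive levels; \code{NA} infers it from the level grid).
#' @return List of \linkS4class{ContourNest} with populated dissimilarity
#'   traces, ordered by outermost level then area (deterministic).
#' @export
linkNestedChains <- function(contourList, params = NCAParams()) {
  recs <- lapply(contourList, .asContourRec)
  chains <- .linkChainsIdx(recs, params@k)
  nests <- lapply(chains, function(idx) ContourNest(contourList[idx]))
  key <- vapply(nests, function(n)
    c(level(n@contours[[1L]]), -area(n@contours[[1L]])), numeric(2L))
  if (length(nests) > 1L) nests[order(key[1L, ], key[2L, ])] else nests
}

.asContourRec <- function(c) {
  if (is.list(c)) return(c)
  list(level = c@level, v = c@vertices, area = c@area,
       centroid = c@centroid, perimeter = c@perimeter, bbox = c@bbox)
}

# containment of a contour record in another during linking: one interior
# point decides (see note above .containsFast)
.containsRec <- function(outer, inner) {
  v <- inner$v
  frac <- which((v[, 1L] %% 1 != 0) | (v[, 2L] %% 1 != 0))
  bnd <- rbind(outer$v, outer$v[1L, ])
  if (length(frac))
    return(mgcv::in.out(bnd, v[frac[1L], , drop = FALSE])[1L])
  # fully border-clamped inner contour: fall back to the all-vertex test
  inside <- mgcv::in.out(bnd, v)
  if (all(inside)) return(TRUE)
  for (i in which(!inside)) {
    d2 <- .pointSegDist2(v[i, 1L], v[i, 2L],
                         bnd[-nrow(bnd), 1L], bnd[-nrow(bnd), 2L],
                         bnd[-1L, 1L], bnd[-1L, 2L])
    if (min(d2) > 1e-12) return(FALSE)
  }
  TRUE
}

.linkChainsIdx <- function(recs, k = NA_real_, px = NULL) {
  if (length(recs) == 0L) return(list())
  lv <- vapply(recs, function(c) c$level, numeric(1L))
  ulev <- sort(unique(lv))
  if (is.na(k)) k <- if (length(ulev) > 1L) min(diff(ulev)) else 1
  tol <- k * 1e-6

  byLevel <- lapply(ulev, function(l) which(abs(lv - l) < tol))
  bb <- t(vapply(recs, function(c) c$bbox, numeric(4L)))
  ar <- vapply(recs, function(c) c$area, numeric(1L))
  cen <- t(vapply(recs, function(c) c$centroid, numeric(2L)))

  chains <- list()    # each: integer vector of contour indices
  tips <- integer(0L) # tip contour index per active chain
  active <- integer(0L)   # indices into chains
  finished <- integer(0L)

  for (j in seq_along(ulev)) {
    cs <- byLevel[[j]]
    consecutive <- j > 1L && abs(ulev[j] - ulev[j - 1L] - k) < tol
    parent <- rep(NA_integer_, length(cs))   # position in `active`
    if (consecutive && length(active)) {
      tipOrd <- order(ar[tips])               # innermost container first
      # bbox pre-check against all tips, then one-point containment.
      # Every consecutive-level contour lies in exactly one level-l
      # region, whose boundary is among the bbox-passing tips, so the
      # last untested candidate needs no polygon test.
      assignPoly <- function(i) {
        ok <- bb[tips, 1L] <= bb[i, 1L] + 1e-9 &
              bb[tips, 2L] <= bb[i, 2L] + 1e-9 &
              bb[tips, 3L] >= bb[i, 3L] - 1e-9 &
              bb[tips, 4L] >= bb[i, 4L] - 1e-9
        cand <- tipOrd[ok[tipOrd]]
        nc <- length(cand)
        if (nc == 0L) return(NA_integer_)
        for (ti in seq_len(nc)) {
          t <- cand[ti]
          if (ti == nc || .containsRec(recs[[tips[t]]], recs[[i]]))
            return(t)
        }
        NA_integer_
      }
      if (!is.null(px) && length(tips) * length(cs) > 2e4) {
        # raster fast path for speckle-heavy levels: label the level-l
        # regions once and match tips to children by component label; holes
        # and border-clamped contours (ambiguous labels) fall back to the
        # polygon test
        lab <- EBImage::imageData(EBImage::bwlabel((px >= ulev[j - 1L]) * 1))
        tipLab <- vapply(seq_along(tips), function(t) {
          r <- recs[[tips[t]]]
          # hole contours never parent a child under the innermost rule
          if (is.null(r$inpix) || is.na(r$hole) || r$hole) NA_real_
          else lab[r$inpix[1L], r$inpix[2L]]
        }, numeric(1L))
        dup <- unique(tipLab[duplicated(tipLab)])
        childLab <- vapply(cs, function(i) {
          ip <- recs[[i]]$inpix
          if (is.null(ip)) NA_real_ else lab[ip[1L], ip[2L]]
        }, numeric(1L))
        hit <- match(childLab, tipLab)
        for (ci in seq_along(cs)) {
          if (!is.na(hit[ci]) && childLab[ci] > 0 &&
              !(childLab[ci] %in% dup)) {
            parent[ci] <- hit[ci]
          } else {
            parent[ci] <- assignPoly(cs[ci])
          }
        }
      } else {
        for (ci in seq_along(cs)) parent[ci] <- assignPoly(cs[ci])
      }
    }
    extendedActive <- integer(0L); extendedTips <- integer(0L)
    starters <- cs[is.na(parent)]   # orphans start their own chains
    if (length(active)) {
      kidPos <- which(!is.na(parent))
      if (length(kidPos)) {
        pv <- parent[kidPos]; kv <- cs[kidPos]
        # best child per parent: largest area, ties by smallest shift
        sh <- sqrt((cen[kv, 1L] - cen[tips[pv], 1L])^2 +
                   (cen[kv, 2L] - cen[tips[pv], 2L])^2)
        o <- order(pv, -ar[kv], sh)
        isBest <- !duplicated(pv[o])
        bestPar <- pv[o][isBest]; bestKid <- kv[o][isBest]
        for (m in seq_along(bestPar))
          chains[[active[bestPar[m]]]] <-
            c(chains[[active[bestPar[m]]]], bestKid[m])
        extendedActive <- active[bestPar]
        extendedTips <- bestKid
        starters <- c(starters, kv[o][!isBest])  # siblings -> new chains
        finished <- c(finished, active[-bestPar])
      } else {
        finished <- c(finished, active)
      }
    }
    nNew <- length(starters)
    if (nNew) {
      chains[length(chains) + seq_len(nNew)] <- as.list(starters)
    }
    active <- c(extendedActive, length(chains) - nNew + seq_len(nNew) - 0L)
    tips <- c(extendedTips, starters)
  }
  finished <- c(finished, active)
  chains[finished]
}

# discard-rule run splitting on an index chain; returns list of index runs
# that satisfy minDepth and the area bounds
.splitRunsIdx <- function(idx, ar, cen, params, maxArea) {
  d <- length(idx)
  if (d < 2L) {
    if (d == 1L && params@minDepth <= 1L) return(list(idx)) else return(list())
  }
  a <- ar[idx]
  dx <- diff(cen[idx, 1L]); dy <- diff(cen[idx, 2L])
  areaTerm <- abs(1 - a[-1L] / a[-d])
  shiftTerm <- sqrt(dx^2 + dy^2) / sqrt(a[-d] / pi)
  bad <- areaTerm > params@tauArea | shiftTerm > params@tauShift
  runStart <- c(1L, which(bad) + 1L)
  runEnd <- c(which(bad), d)
  out <- list()
  for (r in seq_along(runStart)) {
    i0 <- runStart[r]; i1 <- runEnd[r]
    if (i1 - i0 + 1L < params@minDepth) next
    if (a[i0] < params@minArea || a[i0] > maxArea) next
    out[[length(out) + 1L]] <- idx[i0:i1]
  }
  out
}

#' Apply the discard rule to nested chains
#'
#' A gradation step whose contour differs too much from the nested one of
#' the previous step -- its area-ratio deviation exceeding \code{tauArea}
#' or its normalized centroid shift exceeding \code{tauShift}, each
#' component checked against its own threshold -- concludes that the outer
#' contour of that step does not represent the mass and is discarded. Each
#' chain is therefore cut at every dissimilar step into maximal runs of
#' sequentially similar contours; runs shorter than \code{minDepth}, or
#' whose outermost contour area falls outside \code{[minArea, maxArea]},
#' are removed. Cutting (rather than keeping only the portion below the
#' first dissimilar step) is what separates a mass from the surrounding
#' parenchyma contour it floods into: the flooded outer contours are
#' discarded while the mass's own similar run survives.
#'
#' @param nests list of \linkS4class{ContourNest}.
#' @param params an \linkS4class{NCAParams}.
#' @param imageArea image area in px^2, used to resolve \code{maxArea = NA}
#'   (25\% of the image); \code{Inf} if not supplied.
#' @return Filtered list of \linkS4class{ContourNest} (a chain may yield
#'   more than one surviving run; nested survivors are merged downstream by
#'   \code{\link{detectLesions}}).
#' @export
pruneChains <- function(nests, params = NCAParams(), imageArea = Inf) {
  maxArea <- if (is.na(params@maxArea)) 0.25 * imageArea else params@maxArea
  out <- list()
  for (nest in nests) {
    cs <- nest@contours
    d <- length(cs)
    bad <- vapply(seq_len(d - 1L), function(i) {
      comp <- .dissimComponents(cs[[i]], cs[[i + 1L]])
      comp[["area"]] > params@tauArea || comp[["shift"]] > params@tauShift
    }, logical(1L))
    # maximal runs of sequentially similar contours
    runStart <- c(1L, which(bad) + 1L)
    runEnd <- c(which(bad), d)
    for (r in seq_along(runStart)) {
      i0 <- runStart[r]; i1 <- runEnd[r]
      if (i1 - i0 + 1L < params@minDepth) next
      if (cs[[i0]]@area < params@minArea || cs[[i0]]@area > maxArea) next
      out[[length(out) + 1L]] <- if (i0 == 1L && i1 == d) nest else
        ContourNest(cs[i0:i1],
                    nest@dissimilarityTrace[seq(i0, length.out = i1 - i0)])
    }
  }
  out
}

.boxInBox <- function(inner, outer) {
  all(inner[c(1L, 2L)] >= outer[c(1L, 2L)]) &&
    all(inner[c(3L, 4L)] <= outer[c(3L, 4L)])
}

#' Detect suspicious lesions with the nested contours algorithm
#'
#' Runs the full NCA on the raw image: contour extraction over the whole
#' brightness range at step k, nested-chain linking, the discard rule, and
#' candidate emission. Each surviving chain yields one candidate whose
#' representative contour is the chain's outermost retained contour;
#' candidates whose boxes are nested inside another candidate's box are
#' merged into the outer one. Output is deterministic for fixed input and
#' parameters and sorted by descending score (depth-weighted circularity
#' \code{depth * 4 pi area / perimeter^2}).
#'
#' @param image a \linkS4class{GrayImage}.
#' @param params an \linkS4class{NCAParams}.
#' @return List of \linkS4class{LesionCandidate}; empty for a degenerate
#'   image.
#' @seealso \code{\link{detectionTable}} to convert the candidates to a
#'   data.frame for evaluation or serialization.
#' @export
detectLesions <- function(image, params = NCAParams()) {
  stopifnot(is(image, "GrayImage"), is(params, "NCAParams"))
  recs <- .traceContours(image, params@k)
  chains <- .linkChainsIdx(recs, params@k, px = image@pixels)
  if (!length(chains)) return(list())
  ar <- vapply(recs, function(r) r$area, numeric(1L))
  cen <- t(vapply(recs, function(r) r$centroid, numeric(2L)))
  maxArea <- if (is.na(params@maxArea))
    0.25 * prod(dim(image@pixels)) else params@maxArea
  runs <- unlist(lapply(chains, .splitRunsIdx, ar = ar, cen = cen,
                        params = params, maxArea = maxArea),
                 recursive = FALSE)
  if (!length(runs)) return(list())

  cands <- lapply(runs, function(idx) {
    r <- recs[[idx[1L]]]
    rep_ <- new("IsoContour", level = r$level, vertices = r$v,
                area = r$area, centroid = r$centroid,
                perimeter = r$perimeter, bbox = r$bbox)
    b <- r$bbox
    box <- c(floor(b[1L]), floor(b[2L]), floor(b[3L]) + 1, floor(b[4L]) + 1)
    circ <- 4 * pi * r$area / r$perimeter^2
    new("LesionCandidate", contour = rep_, box = box,
        depth = length(idx), score = length(idx) * circ)
  })

  # Merge candidates whose boxes nest inside another candidate's box and
  # are of closely comparable scale (duplicate detections of the same
  # structure, e.g. the concentric runs a single mass produces); the outer
  # one is kept. A small candidate nested inside a much larger one is a
  # distinct structure (a mass within a broad density region) and stays.
  boxes <- t(vapply(cands, function(c) c@box, numeric(4L)))
  areas <- (boxes[, 3L] - boxes[, 1L]) * (boxes[, 4L] - boxes[, 2L])
  keep <- rep(TRUE, length(cands))
  for (i in seq_along(cands)) {
    for (j in seq_along(cands)) {
      if (i == j || !keep[i]) next
      if (.boxInBox(boxes[i, ], boxes[j, ]) &&
          areas[i] >= 0.5 * areas[j] &&
          (areas[i] < areas[j] ||
           (areas[i] == areas[j] && i > j))) {
        keep[i] <- FALSE
      }
    }
  }
  cands <- cands[keep]
  ord <- order(-vapply(cands, function(c) c@score, numeric(1L)),
               vapply(cands, function(c) c@box[1L], numeric(1L)),
               vapply(cands, function(c) c@box[2L], numeric(1L)))
  cands[ord]
}

#' Burn candidate contours into an image for visual review
#'
#' The NCA marks a lesion by drawing its approximate contour; this renders
#' each candidate's representative contour at full intensity onto a copy of
#' the image (suitable for \code{\link{saveImage}}).
#'
#' @param image a \linkS4class{GrayImage}.
#' @param candidates list of \linkS4class{LesionCandidate}.
#' @return A \linkS4class{GrayImage} with the contours burned in.
#' @export
renderOverlay <- function(image, candidates) {
  px <- image@pixels
  h <- nrow(px); w <- ncol(px)
  mx <- 2^image@bitDepth - 1
  for (cand in candidates) {
    v <- cand@contour@vertices
    v <- rbind(v, v[1L, ])
    for (i in seq_len(nrow(v) - 1L)) {
      n <- max(2L, ceiling(max(abs(v[i + 1L, ] - v[i, ]))) * 2L)
      xs <- round(seq(v[i, 1L], v[i + 1L, 1L], length.out = n))
      ys <- round(seq(v[i, 2L], v[i + 1L, 2L], length.out = n))
      ok <- xs >= 0 & xs < w & ys >= 0 & ys < h
      px[cbind(ys[ok] + 1L, xs[ok] + 1L)] <- mx
    }
  }
  GrayImage(px, image@bitDepth)
}

#' Candidates as a detections data.frame
#'
#' @param candidates list of \linkS4class{LesionCandidate}.
#' @return data.frame with columns x_min, y_min, x_max, y_max, score, depth
#'   (0-based half-open pixel boxes), one row per candidate.
#' @export
detectionTable <- function(candidates) {
  if (!length(candidates))
    return(data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      score = numeric(0), depth = integer(0)))
  b <- t(vapply(candidates, function(c) c@box, numeric(4L)))
  data.frame(x_min = b[, 1L], y_min = b[, 2L], x_max = b[, 3L],
             y_max = b[, 4L],
             score = vapply(candidates, function(c) c@score, numeric(1L)),
             depth = vapply(candidates, function(c) c@depth, integer(1L)))
}
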