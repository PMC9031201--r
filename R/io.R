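# Readers/writers. Coordinates are 0-based, half-open, x = column, y = row
# everywhere; annotation and detection JSON share one versioned schema.

#' Load a grayscale image
#'
#' Reads PNG or TIFF. Multi-channel inputs are converted to gray by
#' luminance (Rec. 709 weights). Bit depth is taken from the file (TIFF) or
#' inferred from the sample values (PNG: 8-bit unless finer quantization is
#' present).
#'
#' @param path file path.
#' @return A \linkS4class{GrayImage}.
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- tryCatch(png::readPNG(path),
                  error = function(e) stop("unreadable PNG '", path, "': ",
                                           conditionMessage(e)))
    bits <- if (all(abs(a * 255 - round(a * 255)) < 1e-6)) 8L else 16L
  } else if (ext %in% c("tif", "tiff")) {
    a <- tryCatch(tiff::readTIFF(path),
                  error = function(e) stop("unreadable TIFF '", path, "': ",
                                           conditionMessage(e)))
    bits <- if (all(abs(a * 255 - round(a * 255)) < 1e-6)) 8L else 16L
  } else {
    stop("unsupported image format '.", ext, "' (PNG and TIFF are supported)")
  }
  if (length(dim(a)) == 3L) {
    wts <- c(0.2126, 0.7152, 0.0722, 0)[seq_len(dim(a)[3L])]
    wts <- wts / sum(wts)
    a <- apply(sweep(a, 3L, wts, `*`), c(1L, 2L), sum)
  }
  GrayImage(a * (2^bits - 1), bits)
}

#' Save a grayscale image
#'
#' PNG output is 8-bit; TIFF preserves the image's bit depth.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param path destination; format chosen by extension.
#' @export
saveImage <- function(image, path) {
  stopifnot(is(image, "GrayImage"))
  norm <- image@pixels / (2^image@bitDepth - 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(norm, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = image@bitDepth)
  } else stop("unsupported output format: .", ext)
  invisible(path)
}

#' Save a 3-channel enhanced image as RGB PNG
#'
#' @param img3 a \linkS4class{ThreeChannelImage}.
#' @param path destination PNG path.
#' @export
saveThreeChannel <- function(img3, path) {
  stopifnot(is(img3, "ThreeChannelImage"))
  mx <- 2^img3@chTrunc@bitDepth - 1
  a <- array(c(img3@chTrunc@pixels, img3@chClahe1@pixels,
               img3@chClahe2@pixels) / mx,
             dim = c(dim(img3@chTrunc@pixels), 3L))
  png::writePNG(a, path)
  invisible(path)
}

.ANNOTATION_SCHEMA_VERSION <- 1L

.annotationsToList <- function(ann) {
  lapply(seq_len(nrow(ann)), function(i) {
    rec <- list(box = c(ann$x_min[i], ann$y_min[i], ann$x_max[i],
                        ann$y_max[i]))
    if ("lesion_type" %in% names(ann) && !is.na(ann$lesion_type[i]))
      rec$lesion_type <- ann$lesion_type[i]
    if ("density_class" %in% names(ann) && !is.na(ann$density_class[i]))
      rec$density_class <- ann$density_class[i]
    if ("score" %in% names(ann)) rec$score <- ann$score[i]
    if ("depth" %in% names(ann)) rec$depth <- ann$depth[i]
    rec
  })
}

.validateAnnotationRecord <- function(rec, i, requireType = TRUE) {
  if (is.null(rec$box) || length(rec$box) != 4L || !is.numeric(rec$box))
    stop("annotation record ", i, ": box must be 4 numbers")
  b <- rec$box
  if (b[1L] >= b[3L] || b[2L] >= b[4L])
    stop("annotation record ", i,
         ": box must satisfy x_min < x_max and y_min < y_max")
  if (requireType) {
    if (is.null(rec$lesion_type))
      stop("annotation record ", i, ": missing lesion_type")
    if (!rec$lesion_type %in% LESION_TYPES)
      stop("annotation record ", i, ": unknown lesion_type '",
           rec$lesion_type, "'")
  }
  if (!is.null(rec$density_class) && !rec$density_class %in% DENSITY_CLASSES)
    stop("annotation record ", i, ": unknown density_class '",
         rec$density_class, "'")
  invisible(TRUE)
}

#' Write annotations to JSON
#'
#' @param ann data.frame with box columns, lesion_type and optionally
#'   density_class.
#' @param path destination JSON path.
#' @export
writeAnnotations <- function(ann, path) {
  obj <- list(version = .ANNOTATION_SCHEMA_VERSION,
              annotations = .annotationsToList(as.data.frame(ann)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read annotations from JSON
#'
#' Round-trip identity with \code{\link{writeAnnotations}}: boxes and
#' labels are reproduced exactly. Schema violations raise an error naming
#' the offending record.
#'
#' @param path JSON path.
#' @param requireType must every record carry a lesion_type? (TRUE for
#'   ground truth, FALSE for detections.)
#' @return data.frame of annotations.
#' @export
readAnnotations <- function(path, requireType = TRUE) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  recs <- obj$annotations %||% obj
  out <- .emptyAnnotations()
  out$density_class <- character(0)
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    rec$box <- unlist(rec$box)
    .validateAnnotationRecord(rec, i, requireType)
    out <- rbind(out, data.frame(
      x_min = rec$box[1L], y_min = rec$box[2L], x_max = rec$box[3L],
      y_max = rec$box[4L],
      lesion_type = rec$lesion_type %||% NA_character_,
      density_class = rec$density_class %||% NA_character_))
  }
  out
}

#' Write detections (with contours) to JSON
#'
#' @param candidates list of \linkS4class{LesionCandidate}.
#' @param path destination JSON path.
#' @export
writeDetections <- function(candidates, path) {
  obj <- lapply(candidates, function(c) list(
    box = c@box, score = c@score, depth = c@depth,
    contour = unname(apply(c@contour@vertices, 1L, function(v) v,
                           simplify = FALSE))))
  jsonlite::write_json(list(version = .ANNOTATION_SCHEMA_VERSION,
                            detections = obj),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read detections from JSON as a data.frame
#'
#' @param path JSON path written by \code{\link{writeDetections}} (or any
#'   JSON with a compatible detections list).
#' @return data.frame with x_min, y_min, x_max, y_max, score, depth.
#' @export
readDetections <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  recs <- obj$detections %||% obj
  out <- detectionTable(list())
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    rec$box <- unlist(rec$box)
    .validateAnnotationRecord(rec, i, requireType = FALSE)
    out <- rbind(out, data.frame(
      x_min = rec$box[1L], y_min = rec$box[2L], x_max = rec$box[3L],
      y_max = rec$box[4L], score = rec$score %||% 0,
      depth = as.integer(rec$depth %||% NA_integer_)))
  }
  out
}
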