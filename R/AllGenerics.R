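# Accessor generics. Slot access outside the package goes through these.

#' @rdname GrayImage-class
#' @param object,x a package object.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname GrayImage-class
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' Maximum representable intensity of an image
#' @param x a \linkS4class{GrayImage}.
#' @export
setGeneric("maxIntensity", function(x) standardGeneric("maxIntensity"))

#' @rdname IsoContour-class
#' @export
setGeneric("level", function(x) standardGeneric("level"))

#' @rdname IsoContour-class
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname IsoContour-class
#' @export
setGeneric("area", function(x) standardGeneric("area"))

#' @rdname IsoContour-class
#' @export
setGeneric("centroid", function(x) standardGeneric("centroid"))

#' @rdname IsoContour-class
#' @export
setGeneric("perimeter", function(x) standardGeneric("perimeter"))

#' Axis-aligned bounding box
#'
#' Returns c(xmin, ymin, xmax, ymax). For an \linkS4class{IsoContour} this is
#' the tight float box of its vertices; for a \linkS4class{LesionCandidate}
#' the integer pixel box (0-based, half-open).
#'
#' @param x an object with a spatial extent.
#' @export
setGeneric("boundingBox", function(x) standardGeneric("boundingBox"))

#' Geometric containment of one contour in another
#'
#' TRUE iff every vertex of \code{inner} lies inside or on \code{outer}.
#' A bounding-box pre-check gives a fast reject; boundary vertices are
#' accepted via a point-to-segment distance test.
#'
#' @param outer,inner \linkS4class{IsoContour}s (both simple polygons).
#' @return logical scalar.
#' @export
setGeneric("containsContour",
           function(outer, inner) standardGeneric("containsContour"))

#' @rdname ContourNest-class
#' @export
setGeneric("contours", function(x) standardGeneric("contours"))

#' Chain depth / candidate depth
#' @param x a \linkS4class{ContourNest} or \linkS4class{LesionCandidate}.
#' @export
setGeneric("depth", function(x) standardGeneric("depth"))

#' @rdname ContourNest-class
#' @export
setGeneric("dissimilarityTrace",
           function(x) standardGeneric("dissimilarityTrace"))

#' @rdname LesionCandidate-class
#' @export
setGeneric("score", function(x) standardGeneric("score"))
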