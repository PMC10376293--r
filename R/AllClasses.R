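#' AnchorSet: prior box sizes for the three detection scales
#'
#' Nine (w, h) anchor priors grouped three per pyramid scale, mapped to
#' strides 8 / 16 / 32 in ascending size order. Anchors are the reference
#' templates against which the detection heads regress offsets.
#'
#' @slot pairs 9x2 numeric matrix of (w, h) in pixels, all positive.
#' @slot strides Integer vector of the three head strides (8, 16, 32).
#' @export
setClass("AnchorSet",
         representation(pairs = "matrix", strides = "integer"),
         prototype(strides = c(8L, 16L, 32L)))

setValidity("AnchorSet", function(object) {
  p <- object@pairs
  if (!is.numeric(p) || nrow(p) != 9 || ncol(p) != 2)
    return("pairs must be a 9x2 numeric matrix")
  if (any(p <= 0)) return("anchor widths/heights must be positive")
  if (length(object@strides) != 3) return("exactly three strides required")
  areas <- p[, 1] * p[, 2]
  gmax <- tapply(areas, rep(1:3, each = 3), max)
  gmin <- tapply(areas, rep(1:3, each = 3), min)
  if (any(gmax[-3] > gmin[-1]))
    return("anchor groups must be ordered by area (smallest on stride 8)")
  TRUE
})

#' Construct an AnchorSet
#'
#' @param pairs 9x2 matrix of (w, h) anchor sizes in pixels, ordered so the
#'   three smallest-area anchors come first (stride 8 group).
#' @param strides Head strides, default \code{c(8, 16, 32)}.
#' @return An [AnchorSet-class] object.
#' @export
AnchorSet <- function(pairs, strides = c(8L, 16L, 32L)) {
  pairs <- matrix(as.numeric(pairs), ncol = 2,
                  dimnames = list(NULL, c("w", "h")))
  new("AnchorSet", pairs = pairs, strides = as.integer(strides))
}

#' @describeIn AnchorSet-class the 9x2 (w, h) matrix.
#' @param object,x An \code{AnchorSet}.
#' @export
setGeneric("anchorPairs", function(object) standardGeneric("anchorPairs"))

#' @rdname AnchorSet-class
#' @export
setMethod("anchorPairs", "AnchorSet", function(object) object@pairs)

#' @describeIn AnchorSet-class anchors of one scale group (1..3).
#' @param scale Scale group index, 1 = finest (stride 8).
#' @export
setGeneric("anchorsAtScale",
           function(object, scale) standardGeneric("anchorsAtScale"))

#' @rdname AnchorSet-class
#' @export
setMethod("anchorsAtScale", "AnchorSet", function(object, scale) {
  stopifnot(scale %in% 1:3)
  object@pairs[(scale - 1) * 3 + 1:3, , drop = FALSE]
})

#' @describeIn AnchorSet-class the head strides.
#' @export
setGeneric("anchorStrides", function(object) standardGeneric("anchorStrides"))

#' @rdname AnchorSet-class
#' @export
setMethod("anchorStrides", "AnchorSet", function(object) object@strides)

setMethod("show", "AnchorSet", function(object) {
  cat("AnchorSet: 9 (w,h) priors over strides",
      paste(object@strides, collapse = "/"), "\n")
  for (s in 1:3) {
    g <- anchorsAtScale(object, s)
    cat(sprintf("  stride %2d: %s\n", object@strides[s],
                paste(sprintf("(%g,%g)", g[, 1], g[, 2]), collapse = " ")))
  }
})

#' FaceAnnotation: ground-truth boxes for one image
#'
#' Single-class ("goat_face") annotation of one image: its identifier,
#' pixel size, and ground-truth boxes in center-size form. Boxes carry an
#' optional per-box weight (used by mixup-blended labels).
#'
#' @slot imageID Character scalar.
#' @slot imageSize Integer (width, height) in pixels.
#' @slot boxes n x 4 matrix, columns cx, cy, w, h.
#' @slot weights Numeric per-box weights in (0, 1].
#' @export
setClass("FaceAnnotation",
         representation(imageID = "character", imageSize = "integer",
                        boxes = "matrix", weights = "numeric"))

setValidity("FaceAnnotation", function(object) {
  if (length(object@imageSize) != 2 || any(object@imageSize <= 0))
    return("imageSize must be two positive integers (width, height)")
  b <- object@boxes
  if (nrow(b) > 0) {
    if (ncol(b) != 4) return("boxes must have 4 columns (cx, cy, w, h)")
    if (any(b[, 3] <= 0 | b[, 4] <= 0))
      return("box widths/heights must be positive")
    cr <- boxToCorners(b)
    tol <- 1e-6
    if (any(cr[, 1] < -tol | cr[, 2] < -tol |
              cr[, 3] > object@imageSize[1] + tol |
              cr[, 4] > object@imageSize[2] + tol))
      return("boxes must lie within image bounds")
    if (length(object@weights) != nrow(b))
      return("one weight per box required")
    if (any(object@weights <= 0 | object@weights > 1))
      return("box weights must be in (0, 1]")
  }
  TRUE
})

#' Construct a FaceAnnotation
#'
#' @param imageID Image identifier (file stem).
#' @param imageSize (width, height) in pixels.
#' @param boxes n x 4 center-size matrix (may have zero rows).
#' @param weights Optional per-box weights, default 1.
#' @return A [FaceAnnotation-class] object.
#' @export
FaceAnnotation <- function(imageID, imageSize, boxes = NULL, weights = NULL) {
  if (is.null(boxes) || length(boxes) == 0)
    boxes <- matrix(numeric(0), 0, 4)
  boxes <- .asBoxMatrix(boxes)
  colnames(boxes) <- c("cx", "cy", "w", "h")
  if (is.null(weights)) weights <- rep(1, nrow(boxes))
  new("FaceAnnotation", imageID = as.character(imageID),
      imageSize = as.integer(round(imageSize)), boxes = boxes,
      weights = as.numeric(weights))
}

#' @describeIn FaceAnnotation-class the center-size box matrix.
#' @param object An annotation.
#' @export
setGeneric("annotationBoxes",
           function(object) standardGeneric("annotationBoxes"))

#' @rdname FaceAnnotation-class
#' @export
setMethod("annotationBoxes", "FaceAnnotation", function(object) object@boxes)

#' @describeIn FaceAnnotation-class image identifier.
#' @export
setGeneric("imageID", function(object) standardGeneric("imageID"))

#' @rdname FaceAnnotation-class
#' @export
setMethod("imageID", "FaceAnnotation", function(object) object@imageID)

#' @describeIn FaceAnnotation-class image (width, height).
#' @export
setGeneric("imageSize", function(object) standardGeneric("imageSize"))

#' @rdname FaceAnnotation-class
#' @export
setMethod("imageSize", "FaceAnnotation", function(object) object@imageSize)

#' @describeIn FaceAnnotation-class per-box label weights.
#' @export
setGeneric("boxWeights", function(object) standardGeneric("boxWeights"))

#' @rdname FaceAnnotation-class
#' @export
setMethod("boxWeights", "FaceAnnotation", function(object) object@weights)

setMethod("show", "FaceAnnotation", function(object) {
  cat(sprintf("FaceAnnotation '%s' (%dx%d px): %d goat face(s)\n",
              object@imageID, object@imageSize[1], object@imageSize[2],
              nrow(object@boxes)))
  if (nrow(object@boxes) > 0) {
    sides <- pmax(object@boxes[, 3], object@boxes[, 4])
    cat(sprintf("  max side range: [%.1f, %.1f] px\n",
                min(sides), max(sides)))
  }
})

#' RankTable: per-metric ranks of competing models
#'
#' A k-models x n-metrics matrix of ranks (1 = best, ties as average
#' ranks), the input to the Friedman test and Nemenyi post-hoc comparison.
#'
#' @slot ranks k x n numeric matrix, rownames = models, colnames = metrics.
#' @export
setClass("RankTable", representation(ranks = "matrix"))

setValidity("RankTable", function(object) {
  r <- object@ranks
  if (!is.numeric(r) || nrow(r) < 2 || ncol(r) < 1)
    return("ranks must be a numeric matrix with >= 2 models")
  k <- nrow(r)
  if (any(r < 1 - 1e-9 | r > k + 1e-9)) return("ranks must lie in [1, k]")
  want <- k * (k + 1) / 2
  if (any(abs(colSums(r) - want) > 1e-6))
    return(sprintf("each column's ranks must sum to k(k+1)/2 = %g", want))
  TRUE
})

#' Construct a RankTable
#'
#' @param ranks k x n matrix of (possibly tied, averaged) ranks; each
#'   column must contain a valid ranking of the k models.
#' @param models,metrics Optional dimnames.
#' @return A [RankTable-class] object.
#' @export
RankTable <- function(ranks, models = rownames(ranks),
                      metrics = colnames(ranks)) {
  ranks <- as.matrix(ranks)
  if (!is.null(models)) rownames(ranks) <- models
  if (!is.null(metrics)) colnames(ranks) <- metrics
  new("RankTable", ranks = ranks)
}

#' @describeIn RankTable-class the rank matrix.
#' @param object A rank table.
#' @export
setGeneric("modelRanks", function(object) standardGeneric("modelRanks"))

#' @rdname RankTable-class
#' @export
setMethod("modelRanks", "RankTable", function(object) object@ranks)

#' @describeIn RankTable-class mean rank per model across metrics.
#' @export
setGeneric("averageRanks", function(object) standardGeneric("averageRanks"))

#' @rdname RankTable-class
#' @export
setMethod("averageRanks", "RankTable", function(object) rowMeans(object@ranks))

setMethod("show", "RankTable", function(object) {
  cat(sprintf("RankTable: %d models x %d metrics\n",
              nrow(object@ranks), ncol(object@ranks)))
  print(cbind(object@ranks, Average = averageRanks(object)))
})
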