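#' @useDynLib capriDetect, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# Boxes travel as numeric matrices with columns cx, cy, w, h (continuous
# pixel units, center-size form). Corner form is x1, y1, x2, y2 with
# x2 = x1 + w: real-valued extents, no +1 pixel convention.

.BOX_EPS <- 1e-7

#' Construct boxes in center-size form
#'
#' Boxes are plain numeric matrices with columns \code{cx, cy, w, h} in
#' continuous pixel units. Degenerate widths/heights are clamped to a small
#' positive epsilon so downstream area ratios stay defined.
#'
#' @param cx,cy Box center coordinates (pixels); recycled to a common length.
#' @param w,h Box width and height (pixels, > 0).
#' @param clamp If \code{TRUE} (default) nonpositive sides are clamped to
#'   \code{1e-7}; if \code{FALSE} they are an error.
#' @return A numeric matrix with one row per box and columns
#'   \code{cx, cy, w, h}.
#' @examples
#' boxCS(5, 5, 10, 10)
#' @export
boxCS <- function(cx, cy, w, h, clamp = TRUE) {
  m <- cbind(cx = as.numeric(cx), cy = as.numeric(cy),
             w = as.numeric(w), h = as.numeric(h))
  if (any(!is.finite(m))) stop("box coordinates must be finite")
  bad <- m[, "w"] <= 0 | m[, "h"] <= 0
  if (any(bad)) {
    if (!clamp) stop("box width/height must be positive")
    m[, "w"] <- pmax(m[, "w"], .BOX_EPS)
    m[, "h"] <- pmax(m[, "h"], .BOX_EPS)
  }
  m
}

#' Construct boxes from corner coordinates
#'
#' @param x1,y1 Top-left corner (pixels).
#' @param x2,y2 Bottom-right corner (pixels); must exceed the top-left.
#' @inheritParams boxCS
#' @return Center-size box matrix (see [boxCS()]).
#' @examples
#' boxFromCorners(0, 0, 2, 2)
#' @export
boxFromCorners <- function(x1, y1, x2, y2, clamp = TRUE) {
  boxCS((x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1, clamp = clamp)
}

#' Convert center-size boxes to corner form
#'
#' Exact inverse of [boxFromCorners()]: the round trip through both
#' conversions reproduces the input bitwise for well-formed boxes.
#'
#' @param boxes Center-size box matrix.
#' @return Matrix with columns \code{x1, y1, x2, y2}.
#' @export
boxToCorners <- function(boxes) {
  boxes <- .asBoxMatrix(boxes)
  cbind(x1 = boxes[, 1] - boxes[, 3] / 2,
        y1 = boxes[, 2] - boxes[, 4] / 2,
        x2 = boxes[, 1] + boxes[, 3] / 2,
        y2 = boxes[, 2] + boxes[, 4] / 2)
}

.asBoxMatrix <- function(boxes) {
  if (is.null(dim(boxes))) {
    stopifnot(length(boxes) == 4)
    boxes <- matrix(as.numeric(boxes), nrow = 1)
  }
  stopifnot(ncol(boxes) == 4)
  boxes
}

# Pairwise (row-by-row) geometric decomposition of two equal-length box sets.
# Returns all intermediates the IoU family needs.
.overlapParts <- function(a, b) {
  a <- .asBoxMatrix(a); b <- .asBoxMatrix(b)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  stopifnot(nrow(a) == nrow(b))
  ca <- boxToCorners(a); cb <- boxToCorners(b)
  iw <- pmax(0, pmin(ca[, 3], cb[, 3]) - pmax(ca[, 1], cb[, 1]))
  ih <- pmax(0, pmin(ca[, 4], cb[, 4]) - pmax(ca[, 2], cb[, 2]))
  inter <- iw * ih
  areaA <- a[, 3] * a[, 4]
  areaB <- b[, 3] * b[, 4]
  union <- areaA + areaB - inter
  ew <- pmax(ca[, 3], cb[, 3]) - pmin(ca[, 1], cb[, 1])
  eh <- pmax(ca[, 4], cb[, 4]) - pmin(ca[, 2], cb[, 2])
  list(inter = as.numeric(inter), union = as.numeric(union),
       iou = as.numeric(inter / pmax(union, .BOX_EPS)),
       encArea = as.numeric(ew * eh),
       centerDistSq = as.numeric((a[, 1] - b[, 1])^2 +
                                   (a[, 2] - b[, 2])^2),
       diagSq = as.numeric(pmax(ew^2 + eh^2, .BOX_EPS)),
       a = a, b = b)
}

#' Intersection over union of two box sets
#'
#' Row-wise IoU of two center-size box matrices (a single box recycles
#' against a set). Disjoint pairs score 0, coincident pairs 1.
#'
#' @param a,b Center-size box matrices (see [boxCS()]).
#' @return Numeric vector of IoU values in \[0, 1\].
#' @examples
#' boxIoU(boxFromCorners(0, 0, 2, 2), boxFromCorners(1, 1, 3, 3)) # 1/7
#' @export
boxIoU <- function(a, b) .overlapParts(a, b)$iou

#' Generalized IoU
#'
#' IoU minus the fraction of the smallest enclosing box not covered by the
#' union, so non-overlapping pairs are graded by how far apart they are.
#'
#' @inheritParams boxIoU
#' @return Numeric vector in (-1, 1\].
#' @export
boxGIoU <- function(a, b) {
  p <- .overlapParts(a, b)
  p$iou - (p$encArea - p$union) / pmax(p$encArea, .BOX_EPS)
}

#' Distance IoU
#'
#' IoU penalized by the squared center distance normalized by the squared
#' diagonal of the smallest enclosing box.
#'
#' @inheritParams boxIoU
#' @return Numeric vector in (-1, 1\].
#' @export
boxDIoU <- function(a, b) {
  p <- .overlapParts(a, b)
  p$iou - p$centerDistSq / p$diagSq
}

#' Complete IoU
#'
#' Distance IoU with an additional aspect-ratio consistency penalty
#' \eqn{\alpha v}, where \eqn{v = (4/\pi^2)(\arctan(w_{gt}/h_{gt}) -
#' \arctan(w_{pr}/h_{pr}))^2} and \eqn{\alpha = v / ((1 - IoU) + v)}.
#' Asymmetric: the first argument is the prediction, the second the ground
#' truth. When both aspect ratios agree the penalty vanishes and CIoU
#' equals DIoU.
#'
#' @param pr Predicted boxes (center-size matrix).
#' @param gt Ground-truth boxes.
#' @return Numeric vector in (-1, 1\].
#' @export
boxCIoU <- function(pr, gt) {
  p <- .overlapParts(pr, gt)
  v <- as.numeric((4 / pi^2) *
    (atan(p$b[, 3] / p$b[, 4]) - atan(p$a[, 3] / p$a[, 4]))^2)
  alpha <- ifelse(v == 0, 0, v / ((1 - p$iou) + v))
  p$iou - p$centerDistSq / p$diagSq - alpha * v
}

#' Width-height decomposed CIoU
#'
#' Variant of CIoU for small-target regression: instead of one aspect-ratio
#' term, the width and height of the prediction are compared separately to
#' their ground-truth values through
#' \eqn{\epsilon = (2/\pi^2)\,[(\arctan(w_{pr}/w_{gt}) - \pi/4)^2 \pm
#' (\arctan(h_{pr}/h_{gt}) - \pi/4)^2]} and
#' \eqn{\beta = \epsilon / ((1 - IoU) + \epsilon)}; the score is
#' \eqn{IoU - \rho^2/d^2 - \beta\epsilon}. The default combines the two
#' squared deviations by summation (\code{epsCombine = "plus"}, so the
#' penalty is nonnegative and zero exactly when both sides match); the
#' subtractive form is available as \code{"as_printed_minus"}.
#'
#' @param pr Predicted boxes (center-size matrix).
#' @param gt Ground-truth boxes; zero-sized ground truth is an error.
#' @param epsCombine \code{"plus"} or \code{"as_printed_minus"}.
#' @return Numeric vector; 1 exactly when \code{pr == gt}.
#' @export
boxWHCIoU <- function(pr, gt, epsCombine = c("plus", "as_printed_minus")) {
  epsCombine <- match.arg(epsCombine)
  gtm <- .asBoxMatrix(gt)
  if (any(gtm[, 3] <= 0 | gtm[, 4] <= 0))
    stop("ground-truth boxes must have positive width and height")
  p <- .overlapParts(pr, gt)
  tw <- as.numeric((atan(p$a[, 3] / p$b[, 3]) - pi / 4)^2)
  th <- as.numeric((atan(p$a[, 4] / p$b[, 4]) - pi / 4)^2)
  eps <- (2 / pi^2) * if (epsCombine == "plus") tw + th else tw - th
  beta <- ifelse(eps == 0, 0, eps / ((1 - p$iou) + eps))
  p$iou - p$centerDistSq / p$diagSq - beta * eps
}

#' Full overlap decomposition
#'
#' All five overlap scores plus the geometric intermediates (enclosure
#' area, squared center distance, squared enclosure diagonal) for a pair
#' of box sets, as one data frame.
#'
#' @inheritParams boxWHCIoU
#' @return A data.frame with columns \code{iou, giou, diou, ciou, whciou,
#'   enclosureArea, centerDistSq, diagSq}.
#' @examples
#' overlapMetrics(boxCS(5, 5, 4, 4), boxCS(5, 5, 4, 4))
#' @export
overlapMetrics <- function(pr, gt, epsCombine = "plus") {
  p <- .overlapParts(pr, gt)
  data.frame(iou = p$iou,
             giou = boxGIoU(pr, gt),
             diou = boxDIoU(pr, gt),
             ciou = boxCIoU(pr, gt),
             whciou = boxWHCIoU(pr, gt, epsCombine = epsCombine),
             enclosureArea = p$encArea,
             centerDistSq = p$centerDistSq,
             diagSq = p$diagSq)
}
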