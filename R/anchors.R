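#' Anchor priors tuned for small goat faces
#'
#' The nine (w, h) priors used for the small-target heads, obtained by
#' clustering the training-set box sizes (faces between 8 and 55 px, most
#' side lengths between 24 and 32 px):
#' (5,9) (12,16) (19,36) on stride 8, (42,31) (40,28) (55,48) on
#' stride 16, (36,75) (76,55) (72,146) on stride 32.
#'
#' @return An [AnchorSet-class].
#' @examples
#' anchorPairs(defaultSmallTargetAnchors())[1, ] # (5, 9)
#' @export
defaultSmallTargetAnchors <- function() {
  AnchorSet(matrix(c(5, 9, 12, 16, 19, 36,
                     42, 31, 40, 28, 55, 48,
                     36, 75, 76, 55, 72, 146),
                   ncol = 2, byrow = TRUE))
}

#' Stock YOLOv7 COCO anchor priors
#'
#' The generic nine priors shipped with YOLOv7 for COCO-scale objects;
#' kept for comparison against [defaultSmallTargetAnchors()].
#'
#' @return An [AnchorSet-class].
#' @export
yolov7DefaultAnchors <- function() {
  AnchorSet(matrix(c(12, 16, 19, 36, 40, 28,
                     36, 75, 76, 55, 72, 146,
                     142, 110, 192, 243, 459, 401),
                   ncol = 2, byrow = TRUE))
}

# IoU of (w,h) pairs placed at a common origin: overlap of the size
# templates themselves, the YOLO clustering metric.
.whIoU <- function(wh, centroids) {
  iw <- outer(wh[, 1], centroids[, 1], pmin)
  ih <- outer(wh[, 2], centroids[, 2], pmin)
  inter <- iw * ih
  areas <- wh[, 1] * wh[, 2]
  careas <- centroids[, 1] * centroids[, 2]
  inter / (outer(areas, careas, `+`) - inter)
}

#' Cluster box sizes into anchor priors
#'
#' k-means under the 1 - IoU distance (sizes compared at a common origin,
#' the YOLO convention), with seeded k-means++ initialization and Lloyd
#' iterations until the assignment stabilizes. Centroids are returned
#' sorted by area; for \code{k = 9} the result is an [AnchorSet-class],
#' otherwise a plain matrix.
#'
#' @param wh n x 2 matrix of box (w, h) in pixels.
#' @param k Number of clusters (\code{k <= n}).
#' @param seed Integer seed controlling initialization.
#' @param maxIter Iteration cap.
#' @return AnchorSet (k = 9) or k x 2 matrix, plus attribute
#'   \code{"objective"}: the mean 1 - IoU to the nearest centroid per
#'   iteration (non-increasing).
#' @export
kmeansAnchors <- function(wh, k = 9, seed = 1, maxIter = 100) {
  wh <- matrix(as.numeric(wh), ncol = 2)
  n <- nrow(wh)
  if (k > n) stop("k must not exceed the number of boxes")
  if (any(wh <= 0)) stop("box sizes must be positive")
  set.seed(seed)
  # k-means++ seeding under d = 1 - IoU
  centroids <- wh[sample.int(n, 1), , drop = FALSE]
  while (nrow(centroids) < k) {
    d <- 1 - apply(.whIoU(wh, centroids), 1, max)
    p <- if (sum(d^2) > 0) d^2 / sum(d^2) else rep(1 / n, n)
    centroids <- rbind(centroids, wh[sample.int(n, 1, prob = p), ])
  }
  objective <- numeric(0)
  assign_prev <- rep(0L, n)
  for (it in seq_len(maxIter)) {
    sim <- .whIoU(wh, centroids)
    assign_cur <- max.col(sim, ties.method = "first")
    objective <- c(objective, mean(1 - sim[cbind(seq_len(n), assign_cur)]))
    if (all(assign_cur == assign_prev)) break
    assign_prev <- assign_cur
    for (j in seq_len(k)) {
      members <- wh[assign_cur == j, , drop = FALSE]
      if (nrow(members) > 0) centroids[j, ] <- colMeans(members)
    }
  }
  ord <- order(centroids[, 1] * centroids[, 2])
  centroids <- centroids[ord, , drop = FALSE]
  out <- if (k == 9) AnchorSet(centroids) else centroids
  attr(out, "objective") <- objective
  out
}

#' Summarize ground-truth box sizes
#'
#' Reports the extremes and the modal size band of a box-size set, the
#' quantities that guided the small-target anchor choice (dataset extremes
#' 8 and 55 px, modal sides 24-32 px).
#'
#' @param wh n x 2 matrix of (w, h) in pixels.
#' @param binWidth Histogram bin width for the modal band (default 8 px).
#' @return List with \code{minSide}, \code{maxSide} (min over per-box
#'   sides, max over per-box max-sides) and \code{modalRange}, the
#'   \code{[lo, hi)} bounds of the most populated side bin.
#' @export
boxSizeSummary <- function(wh, binWidth = 8) {
  wh <- matrix(as.numeric(wh), ncol = 2)
  if (nrow(wh) == 0) stop("no boxes supplied")
  sides <- as.numeric(wh)
  maxSides <- pmax(wh[, 1], wh[, 2])
  bins <- floor(sides / binWidth)
  tab <- table(bins)
  modal <- as.integer(names(tab)[which.max(tab)])
  list(minSide = min(sides), maxSide = max(maxSides),
       modalRange = c(modal * binWidth, (modal + 1) * binWidth))
}
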