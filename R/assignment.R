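# Training-sample assignment: shape-ratio gated anchor matching with
# neighbor-cell expansion (the YOLOv5-style scheme; dynamic OTA matching
# is deliberately out of scope).

#' Head grid specifications for an input size
#'
#' @param inputSize Square input side in pixels, divisible by 32.
#' @param strides Head strides (default 8/16/32).
#' @return data.frame with columns \code{level, stride, gw, gh}.
#' @export
headSpecs <- function(inputSize = 640, strides = c(8L, 16L, 32L)) {
  if (inputSize %% 32 != 0) stop("input size must be divisible by 32")
  data.frame(level = seq_along(strides), stride = as.integer(strides),
             gw = as.integer(inputSize %/% strides),
             gh = as.integer(inputSize %/% strides))
}

#' Assign ground-truth boxes to anchors and grid cells
#'
#' For every ground-truth box and pyramid level, an anchor is a positive
#' match when \code{max(w/aw, aw/w, h/ah, ah/h) < ratioThresh}; matched
#' anchors produce positives at the box's grid cell and at its two nearest
#' neighbor cells (chosen by which side of the cell center the box center
#' falls on), clamped to the grid. Ground truths outside the image are
#' rejected with a warning.
#'
#' @param ann A [FaceAnnotation-class] whose image is the network input
#'   (boxes in input-pixel units).
#' @param anchors An [AnchorSet-class].
#' @param specs Head grid table from [headSpecs()].
#' @param ratioThresh Shape-ratio gate (default 4).
#' @return data.frame with one row per positive sample: \code{level,
#'   anchor} (index within the level, 1..3), \code{gi, gj} (0-based cell),
#'   \code{gtIndex}, the ground-truth box columns \code{cx, cy, w, h}, and
#'   \code{weight}.
#' @export
assignTargets <- function(ann, anchors, specs = headSpecs(),
                          ratioThresh = 4.0) {
  boxes <- annotationBoxes(ann)
  weights <- boxWeights(ann)
  sz <- imageSize(ann)
  keep <- boxes[, 1] >= 0 & boxes[, 1] <= sz[1] &
    boxes[, 2] >= 0 & boxes[, 2] <= sz[2]
  if (any(!keep)) {
    warning(sprintf("%d ground truth(s) outside image '%s' rejected",
                    sum(!keep), imageID(ann)))
  }
  out <- list()
  for (l in specs$level) {
    stride <- specs$stride[specs$level == l]
    gw <- specs$gw[specs$level == l]; gh <- specs$gh[specs$level == l]
    awh <- anchorsAtScale(anchors, l)
    for (g in which(keep)) {
      b <- unname(boxes[g, ])
      for (a in 1:3) {
        rw <- b[3] / awh[a, 1]; rh <- b[4] / awh[a, 2]
        if (max(rw, 1 / rw, rh, 1 / rh) >= ratioThresh) next
        gx <- b[1] / stride; gy <- b[2] / stride
        gi <- floor(gx); gj <- floor(gy)
        cells <- rbind(c(gi, gj),
                       c(gi + ifelse(gx - gi < 0.5, -1, 1), gj),
                       c(gi, gj + ifelse(gy - gj < 0.5, -1, 1)))
        cells[, 1] <- pmin(pmax(cells[, 1], 0), gw - 1)
        cells[, 2] <- pmin(pmax(cells[, 2], 0), gh - 1)
        cells <- unique(cells)
        out[[length(out) + 1]] <- data.frame(
          level = l, anchor = a, gi = cells[, 1], gj = cells[, 2],
          gtIndex = g, cx = b[1], cy = b[2], w = b[3], h = b[4],
          weight = weights[g])
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(level = integer(0), anchor = integer(0),
                      gi = numeric(0), gj = numeric(0), gtIndex = integer(0),
                      cx = numeric(0), cy = numeric(0), w = numeric(0),
                      h = numeric(0), weight = numeric(0)))
  }
  res <- do.call(rbind, out)
  # one target per (level, anchor, cell): keep the first gt for determinism
  key <- paste(res$level, res$anchor, res$gi, res$gj)
  res[!duplicated(key), , drop = FALSE]
}
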