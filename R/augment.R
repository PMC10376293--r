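# Mosaic and mixup augmentation with bounding-box bookkeeping.

# Nearest-neighbor image resize (scale factor applied to both axes).
.resizeImage <- function(img, sh, sw) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ri <- pmin(h, pmax(1, ceiling(seq_len(sh) / sh * h)))
  ci <- pmin(w, pmax(1, ceiling(seq_len(sw) / sw * w)))
  img[ri, ci, , drop = FALSE]
}

#' Mosaic augmentation
#'
#' Stitches four annotated images into one: a mosaic center splits the
#' output into four quadrants, each filled with a randomly scaled and
#' cropped source image; boxes are transformed, clipped to their quadrant,
#' and dropped when the surviving area falls below \code{minBoxArea}
#' (8 px^2). Deterministic per seed.
#'
#' @param items List of four \code{list(image =, annotation =)} pairs (as
#'   returned by [synthScene()]).
#' @param outSize Output (width, height), default 640 square.
#' @param seed Integer seed.
#' @param scaleRange Per-source scale jitter range; \code{c(1, 1)}
#'   disables scaling.
#' @param center Optional mosaic center as fractions of outSize (random in
#'   \[0.25, 0.75\] when NULL).
#' @param cropOffsets Optional list of four (ox, oy) integer crop offsets
#'   into each scaled source (random when NULL).
#' @param minBoxArea Minimum surviving clipped box area, px^2.
#' @return \code{list(image =, annotation =)} of size \code{outSize}.
#' @export
mosaicAugment <- function(items, outSize = c(640, 640), seed = 1,
                          scaleRange = c(0.6, 1.4), center = NULL,
                          cropOffsets = NULL, minBoxArea = 8) {
  stopifnot(length(items) == 4)
  set.seed(seed)
  W <- outSize[1]; H <- outSize[2]
  if (is.null(center)) center <- stats::runif(2, 0.25, 0.75)
  cxp <- round(W * center[1]); cyp <- round(H * center[2])
  quads <- list(c(1, 1, cxp, cyp), c(cxp + 1, 1, W, cyp),
                c(1, cyp + 1, cxp, H), c(cxp + 1, cyp + 1, W, H))
  out <- array(0.4, c(H, W, 3))
  boxes <- NULL; wts <- NULL
  for (q in 1:4) {
    r <- quads[[q]]
    qw <- r[3] - r[1] + 1; qh <- r[4] - r[2] + 1
    if (qw < 1 || qh < 1) next
    img <- items[[q]]$image; ann <- items[[q]]$annotation
    s <- stats::runif(1, scaleRange[1], scaleRange[2])
    sh <- max(qh, round(dim(img)[1] * s)); sw <- max(qw, round(dim(img)[2] * s))
    simg <- .resizeImage(img, sh, sw)
    sx <- sw / dim(img)[2]; sy <- sh / dim(img)[1]
    off <- if (is.null(cropOffsets)) {
      c(sample.int(sw - qw + 1, 1) - 1, sample.int(sh - qh + 1, 1) - 1)
    } else cropOffsets[[q]]
    out[r[2]:r[4], r[1]:r[3], ] <-
      simg[off[2] + seq_len(qh), off[1] + seq_len(qw), , drop = FALSE]
    b <- annotationBoxes(ann)
    if (nrow(b) > 0) {
      cr <- boxToCorners(b)
      cr[, c(1, 3)] <- cr[, c(1, 3)] * sx - off[1] + (r[1] - 1)
      cr[, c(2, 4)] <- cr[, c(2, 4)] * sy - off[2] + (r[2] - 1)
      cr[, 1] <- pmax(cr[, 1], r[1] - 1); cr[, 2] <- pmax(cr[, 2], r[2] - 1)
      cr[, 3] <- pmin(cr[, 3], r[3]); cr[, 4] <- pmin(cr[, 4], r[4])
      keep <- (cr[, 3] - cr[, 1]) * (cr[, 4] - cr[, 2]) >= minBoxArea &
        cr[, 3] > cr[, 1] & cr[, 4] > cr[, 2]
      if (any(keep)) {
        boxes <- rbind(boxes, boxFromCorners(cr[keep, 1], cr[keep, 2],
                                             cr[keep, 3], cr[keep, 4]))
        wts <- c(wts, boxWeights(ann)[keep])
      }
    }
  }
  list(image = out,
       annotation = FaceAnnotation(
         sprintf("mosaic_%d", seed), outSize, boxes, wts))
}

#' Mixup augmentation
#'
#' Blends two annotated images pixelwise as \eqn{\lambda a + (1-\lambda)b}
#' and unites their label sets, each box carrying weight \eqn{\lambda} or
#' \eqn{1 - \lambda}. When \code{lambda} is NULL it is drawn from
#' Beta(8, 8), the YOLO-family convention.
#'
#' @param a,b \code{list(image =, annotation =)} pairs of equal image size.
#' @param lambda Mixing ratio in \[0, 1\], or NULL to sample.
#' @param seed Seed for the sampled \code{lambda}.
#' @return \code{list(image =, annotation =)}; boxes from \code{a} first.
#' @export
mixupAugment <- function(a, b, lambda = NULL, seed = 1) {
  stopifnot(all(dim(a$image) == dim(b$image)))
  if (is.null(lambda)) {
    set.seed(seed)
    lambda <- stats::rbeta(1, 8, 8)
  }
  stopifnot(lambda >= 0, lambda <= 1)
  img <- lambda * a$image + (1 - lambda) * b$image
  ba <- annotationBoxes(a$annotation); bb <- annotationBoxes(b$annotation)
  if (lambda == 1) { boxes <- ba; wts <- boxWeights(a$annotation) }
  else if (lambda == 0) { boxes <- bb; wts <- boxWeights(b$annotation) }
  else {
    boxes <- rbind(ba, bb)
    wts <- c(boxWeights(a$annotation) * lambda,
             boxWeights(b$annotation) * (1 - lambda))
  }
  sz <- imageSize(a$annotation)
  list(image = img,
       annotation = FaceAnnotation(
         paste0(imageID(a$annotation), "_mix"), sz, boxes, wts))
}
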