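# Independent oracles used across the suite. These recompute quantities
# by brute force (rasterization, exhaustive enumeration) and must stay
# free of the package's analytic code paths.

# IoU by counting subpixel grid cells inside each box. Boxes in
# center-size form; `res` subdivisions per pixel.
gridIoU <- function(a, b, res = 4) {
  ca <- capriDetect::boxToCorners(a)
  cb <- capriDetect::boxToCorners(b)
  lo <- floor(pmin(ca[1, c(1, 2)], cb[1, c(1, 2)]))
  hi <- ceiling(pmax(ca[1, c(3, 4)], cb[1, c(3, 4)]))
  xs <- seq(lo[1] + 1 / (2 * res), hi[1], by = 1 / res)
  ys <- seq(lo[2] + 1 / (2 * res), hi[2], by = 1 / res)
  inA <- outer(ys >= ca[1, 2] & ys <= ca[1, 4],
               xs >= ca[1, 1] & xs <= ca[1, 3], `&`)
  inB <- outer(ys >= cb[1, 2] & ys <= cb[1, 4],
               xs >= cb[1, 1] & xs <= cb[1, 3], `&`)
  sum(inA & inB) / sum(inA | inB)
}

# Average precision by enumerating every score cut as a rectangle sum
# over the (recall, interpolated precision) staircase.
bruteForceAP <- function(dets, gts, iouThresh = 0.7) {
  m <- capriDetect::matchDetections(dets, gts, iouThresh)
  flags <- m$flags
  nGT <- m$TP + m$FN
  if (length(flags) == 0 || nGT == 0) return(0)
  rec <- cumsum(flags) / nGT
  prec <- cumsum(flags) / seq_along(flags)
  ap <- 0
  prev <- 0
  for (i in seq_along(flags)) {
    if (rec[i] > prev) {
      # interpolated precision: best precision at any cut with recall >= rec[i]
      pint <- max(prec[i:length(flags)])
      ap <- ap + (rec[i] - prev) * pint
      prev <- rec[i]
    }
  }
  ap
}

# Exhaustive positive-sample enumeration mirroring the documented
# assignment contract, written independently of assignTargets().
bruteForceAssign <- function(box, anchors, specs, ratioThresh = 4) {
  rows <- list()
  for (l in specs$level) {
    stride <- specs$stride[specs$level == l]
    gw <- specs$gw[specs$level == l]; gh <- specs$gh[specs$level == l]
    awh <- capriDetect::anchorsAtScale(anchors, l)
    for (a in 1:3) {
      r1 <- box[3] / awh[a, 1]; r2 <- box[4] / awh[a, 2]
      if (max(r1, 1 / r1, r2, 1 / r2) >= ratioThresh) next
      gx <- box[1] / stride; gy <- box[2] / stride
      gi <- floor(gx); gj <- floor(gy)
      ni <- if (gx - gi < 0.5) gi - 1 else gi + 1
      nj <- if (gy - gj < 0.5) gj - 1 else gj + 1
      cand <- rbind(c(gi, gj), c(ni, gj), c(gi, nj))
      cand[, 1] <- pmin(pmax(cand[, 1], 0), gw - 1)
      cand[, 2] <- pmin(pmax(cand[, 2], 0), gh - 1)
      cand <- unique(cand)
      for (i in seq_len(nrow(cand)))
        rows[[length(rows) + 1]] <-
          c(level = l, anchor = a, gi = cand[i, 1], gj = cand[i, 2])
    }
  }
  if (length(rows) == 0)
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("level", "anchor", "gi", "gj"))))
  out <- do.call(rbind, rows)
  out[order(out[, 1], out[, 2], out[, 3], out[, 4]), , drop = FALSE]
}

# Small in-memory scenes for training/augmentation tests.
tinyScenes <- function(n = 8, size = 64, seedBase = 1) {
  p <- capriDetect::sceneParams(imageSize = c(size, size), nFaces = c(2, 2),
                                faceSideRange = c(12, 28), clusterProb = 0,
                                noiseSD = 0.01)
  lapply(seq_len(n), function(i) {
    p$seed <- seedBase + i - 1L
    capriDetect::synthScene(p)
  })
}

randomBoxPair <- function() {
  c1 <- sort(sample(0:64, 2))
  c2 <- sort(sample(0:64, 2))
  while (c1[1] == c1[2]) c1 <- sort(sample(0:64, 2))
  while (c2[1] == c2[2]) c2 <- sort(sample(0:64, 2))
  d1 <- sort(sample(0:64, 2)); while (d1[1] == d1[2]) d1 <- sort(sample(0:64, 2))
  d2 <- sort(sample(0:64, 2)); while (d2[1] == d2[2]) d2 <- sort(sample(0:64, 2))
  list(a = capriDetect::boxFromCorners(c1[1], c2[1], c1[2], c2[2]),
       b = capriDetect::boxFromCorners(d1[1], d2[1], d1[2], d2[2]))
}
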