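# Detection metrics: greedy IoU matching at a fixed threshold (0.7 in the
# study), precision / recall / F1 at a confidence cutoff, and all-point
# interpolated average precision.

#' Match detections to ground truths
#'
#' Greedy one-to-one matching in descending score order (ties broken by
#' detection index): a detection is a true positive iff its best-IoU
#' unmatched ground truth reaches \code{iouThresh}.
#'
#' @param dets data.frame with columns \code{cx, cy, w, h, score} (and
#'   optionally \code{imageID}; matching is within-image when present).
#' @param gts Center-size box matrix of ground truths, or a data.frame
#'   with box columns and optional \code{imageID}.
#' @param iouThresh IoU threshold (default 0.7).
#' @return List: \code{TP}, \code{FP}, \code{FN}, and \code{flags} —
#'   logical TP flag per detection in descending-score order, with the
#'   score order as attribute \code{"order"}.
#' @export
matchDetections <- function(dets, gts, iouThresh = 0.7) {
  gtd <- if (is.data.frame(gts)) gts else
    as.data.frame(.asBoxMatrix(gts)) |> stats::setNames(c("cx", "cy", "w", "h"))
  if (is.null(gtd$imageID)) gtd$imageID <- "img"
  if (is.null(dets$imageID)) dets$imageID <- "img"
  nGT <- nrow(gtd)
  if (nrow(dets) == 0)
    return(list(TP = 0L, FP = 0L, FN = nGT,
                flags = logical(0)))
  ord <- order(-dets$score, seq_len(nrow(dets)))
  flags <- logical(length(ord))
  gtUsed <- logical(nGT)
  dm <- as.matrix(dets[, c("cx", "cy", "w", "h")])
  gm <- as.matrix(gtd[, c("cx", "cy", "w", "h")])
  for (i in seq_along(ord)) {
    d <- ord[i]
    cand <- which(!gtUsed & gtd$imageID == dets$imageID[d])
    if (length(cand) == 0) next
    ious <- boxIoU(dm[rep(d, length(cand)), , drop = FALSE],
                   gm[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= iouThresh) {
      flags[i] <- TRUE
      gtUsed[cand[j]] <- TRUE
    }
  }
  tp <- sum(flags)
  structure(list(TP = tp, FP = length(ord) - tp, FN = nGT - tp,
                 flags = flags),
            order = ord)
}

#' Precision, recall and F1
#'
#' \code{precisionMetric = TP/(TP+FP)}, \code{recallMetric = TP/(TP+FN)},
#' and their harmonic mean \code{f1Metric = 2PR/(P+R)}; all three are 0
#' when their denominator is 0.
#'
#' @param TP,FP,FN Match counts.
#' @param P,R Precision and recall.
#' @return Scalar ratio in \[0, 1\].
#' @examples
#' f1Metric(0.9042, 0.7593) # ~0.8255
#' @export
precisionMetric <- function(TP, FP) if (TP + FP == 0) 0 else TP / (TP + FP)

#' @rdname precisionMetric
#' @export
recallMetric <- function(TP, FN) if (TP + FN == 0) 0 else TP / (TP + FN)

#' @rdname precisionMetric
#' @export
f1Metric <- function(P, R) if (P + R == 0) 0 else 2 * P * R / (P + R)

#' Precision-recall curve
#'
#' Sweeps the score-sorted detections, accumulating TP/FP against the
#' fixed ground-truth set.
#'
#' @inheritParams matchDetections
#' @return data.frame with columns \code{score, recall, precision, tp,
#'   fp}; recall is non-decreasing down the rows.
#' @export
prCurve <- function(dets, gts, iouThresh = 0.7) {
  m <- matchDetections(dets, gts, iouThresh)
  nGT <- m$TP + m$FN
  if (length(m$flags) == 0)
    return(data.frame(score = numeric(0), recall = numeric(0),
                      precision = numeric(0), tp = integer(0),
                      fp = integer(0)))
  tp <- cumsum(m$flags)
  fp <- cumsum(!m$flags)
  data.frame(score = dets$score[attr(m, "order")],
             recall = if (nGT > 0) tp / nGT else rep(0, length(tp)),
             precision = tp / (tp + fp), tp = tp, fp = fp)
}

#' Average precision
#'
#' Area under the precision-recall curve with all-point interpolation
#' (precision envelope made non-increasing, then integrated over recall).
#'
#' @inheritParams matchDetections
#' @return AP in \[0, 1\].
#' @export
averagePrecision <- function(dets, gts, iouThresh = 0.7) {
  pc <- prCurve(dets, gts, iouThresh)
  if (nrow(pc) == 0) return(0)
  r <- c(0, pc$recall); p <- c(1, pc$precision)
  # non-increasing precision envelope from the right
  p <- rev(cummax(rev(p)))
  sum(diff(r) * p[-1])
}

#' Per-model metric table
#'
#' Evaluates each model's detections against the shared ground truth:
#' P/R/F1 at a confidence cutoff (default 0.5; the IoU matching threshold
#' applies throughout) and threshold-free AP.
#'
#' @param results Named list of detection data.frames (one per model).
#' @param gts Shared ground truth (see [matchDetections()]).
#' @param iouThresh IoU matching threshold.
#' @param confThresh Confidence cutoff for P/R/F1.
#' @return data.frame with columns \code{model, P, R, F1, AP}.
#' @export
metricTable <- function(results, gts, iouThresh = 0.7, confThresh = 0.5) {
  rows <- lapply(names(results), function(nm) {
    dets <- results[[nm]]
    cut <- dets[dets$score >= confThresh, , drop = FALSE]
    m <- matchDetections(cut, gts, iouThresh)
    P <- precisionMetric(m$TP, m$FP); R <- recallMetric(m$TP, m$FN)
    data.frame(model = nm, P = P, R = R, F1 = f1Metric(P, R),
               AP = averagePrecision(dets, gts, iouThresh))
  })
  do.call(rbind, rows)
}
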