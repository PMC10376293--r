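#' Detection loss configuration
#'
#' Bundles the loss-term weights (confidence 0.1, class 0.125,
#' localization 0.05 — the one-stage detector's composite loss
#' \eqn{0.1 L_{con} + 0.125 L_{cla} + 0.05 L_{loc}}), the IoU variant used
#' for localization, the BCE sample weight, and the width-height penalty
#' combination rule.
#'
#' @param wConf,wCls,wLoc Nonnegative term weights.
#' @param iouVariant One of \code{"iou"}, \code{"giou"}, \code{"diou"},
#'   \code{"ciou"}, \code{"wh_ciou"}.
#' @param bceWeight Sample weight \eqn{\omega} applied inside the binary
#'   cross-entropy terms (default 1).
#' @param epsCombine Passed to [boxWHCIoU()].
#' @return A list of class \code{"LossConfig"}.
#' @export
lossConfig <- function(wConf = 0.1, wCls = 0.125, wLoc = 0.05,
                       iouVariant = c("wh_ciou", "iou", "giou", "diou", "ciou"),
                       bceWeight = 1.0,
                       epsCombine = c("plus", "as_printed_minus")) {
  iouVariant <- match.arg(iouVariant)
  epsCombine <- match.arg(epsCombine)
  stopifnot(wConf >= 0, wCls >= 0, wLoc >= 0, bceWeight >= 0)
  structure(list(wConf = wConf, wCls = wCls, wLoc = wLoc,
                 iouVariant = iouVariant, bceWeight = bceWeight,
                 epsCombine = epsCombine),
            class = "LossConfig")
}

.iouVariantFun <- function(variant, epsCombine = "plus") {
  switch(variant,
         iou = boxIoU,
         giou = boxGIoU,
         diou = boxDIoU,
         ciou = boxCIoU,
         wh_ciou = function(pr, gt) boxWHCIoU(pr, gt, epsCombine = epsCombine),
         stop("unknown IoU variant: ", variant))
}

#' Localization loss
#'
#' \code{1 - score} under the configured overlap variant; 0 for a perfect
#' prediction, and (for the plain IoU variant) 1 for disjoint boxes.
#'
#' @param pr,gt Center-size box matrices (prediction, ground truth).
#' @param cfg A [lossConfig()].
#' @return Numeric vector of per-pair losses.
#' @export
localizationLoss <- function(pr, gt, cfg = lossConfig()) {
  f <- .iouVariantFun(cfg$iouVariant, cfg$epsCombine)
  1 - f(pr, gt)
}

#' Weighted binary cross-entropy
#'
#' \eqn{-\omega \, (t \ln p + (1 - t)\ln(1 - p))} averaged over the inputs,
#' with probabilities clamped to \eqn{[10^{-7}, 1 - 10^{-7}]} before the
#' logarithm.
#'
#' @param target True probabilities in \[0, 1\].
#' @param pred Predicted probabilities.
#' @param weight Scalar or per-sample weight \eqn{\omega}.
#' @return Mean weighted BCE (scalar).
#' @examples
#' bceLoss(1, 0.5) # log(2)
#' @export
bceLoss <- function(target, pred, weight = 1.0) {
  stopifnot(length(target) == length(pred) || length(target) == 1 ||
              length(pred) == 1)
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  mean(-weight * (target * log(p) + (1 - target) * log(1 - p)))
}

#' Composite detection loss
#'
#' Weighted sum of the confidence, classification and localization terms
#' under a [lossConfig()].
#'
#' @param lConf,lCls,lLoc Scalar term values.
#' @param cfg A [lossConfig()].
#' @return Scalar total loss.
#' @examples
#' totalLoss(1, 1, 1) # 0.1 + 0.125 + 0.05
#' @export
totalLoss <- function(lConf, lCls, lLoc, cfg = lossConfig()) {
  cfg$wConf * lConf + cfg$wCls * lCls + cfg$wLoc * lLoc
}

# Central finite-difference gradient of the localization loss with respect
# to the prediction's (cx, cy, w, h). Used by the training engine: the
# overlap scores are piecewise-smooth scalar maps of four variables, so a
# 4-point central stencil is accurate and far simpler than the closed-form
# derivative of the enclosure terms.
.locLossGrad <- function(pr, gt, cfg, h = 1e-4) {
  pr <- .asBoxMatrix(pr)
  g <- matrix(0, nrow(pr), 4)
  for (j in seq_len(4)) {
    up <- pr; up[, j] <- up[, j] + h
    dn <- pr; dn[, j] <- dn[, j] - h
    g[, j] <- (localizationLoss(up, gt, cfg) -
                 localizationLoss(dn, gt, cfg)) / (2 * h)
  }
  g
}

#' Regress one box onto a target by gradient descent
#'
#' Demonstration/diagnostic utility: runs plain gradient descent on a
#' single predicted box under the configured localization loss and returns
#' the loss trajectory. Useful for inspecting the convergence behavior of
#' the overlap variants (the width-height decomposed CIoU in particular).
#'
#' @param pr Starting box (center-size, one row).
#' @param gt Fixed target box.
#' @param cfg A [lossConfig()].
#' @param steps Number of descent steps.
#' @param lr Step size in pixels per unit gradient.
#' @return Numeric vector of \code{steps + 1} loss values (initial
#'   included), with the final box as attribute \code{"box"}.
#' @export
regressBoxDemo <- function(pr, gt, cfg = lossConfig(), steps = 500,
                           lr = 1.0) {
  pr <- .asBoxMatrix(pr)
  losses <- numeric(steps + 1)
  losses[1] <- localizationLoss(pr, gt, cfg)
  for (s in seq_len(steps)) {
    g <- .locLossGrad(pr, gt, cfg)
    pr <- pr - lr * g
    pr[, 3:4] <- pmax(pr[, 3:4], 1e-3)
    losses[s + 1] <- localizationLoss(pr, gt, cfg)
  }
  attr(losses, "box") <- pr
  losses
}
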