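# Detector assembly: compact CSP-style backbone tapped at strides
# 8/16/32, spatial-pyramid pooling on the deepest tap, a context module
# at every level, feature-complementary fusion blocks toward the finest
# and coarsest strides, and three anchor-based YOLO heads.

#' Detector configuration
#'
#' @param inputSize Square input side (pixels), divisible by 32
#'   (default 640, giving head grids 80/40/20).
#' @param numClasses Number of object classes (default 1: goat face).
#' @param anchorsPerScale Anchors per head level (default 3).
#' @param baseChannels Stem width; pyramid channels grow as 2/4/8/16x.
#'   Must be divisible by 4 (the context module splits channels four
#'   ways).
#' @param ecaKernel \code{"adaptive"} or an odd integer.
#' @return List of class \code{"ModelConfig"}.
#' @export
modelConfig <- function(inputSize = 640, numClasses = 1,
                        anchorsPerScale = 3, baseChannels = 16,
                        ecaKernel = "adaptive") {
  if (inputSize %% 32 != 0) stop("inputSize must be divisible by 32")
  if (baseChannels %% 4 != 0) stop("baseChannels must be divisible by 4")
  structure(list(inputSize = as.integer(inputSize),
                 numClasses = as.integer(numClasses),
                 anchorsPerScale = as.integer(anchorsPerScale),
                 baseChannels = as.integer(baseChannels),
                 ecaKernel = ecaKernel),
            class = "ModelConfig")
}

.collectParams <- function(named) .mergeKids(named)

#' Build the small-target face detector
#'
#' Assembles backbone, neck and heads under a fixed seed (Kaiming
#' convolution init, unit-gamma batch norm). For a 640-px input, one
#' class and three anchors the three head tensors have shapes
#' (80, 80, 18), (40, 40, 18) and (20, 20, 18): each 18-channel slot
#' splits into three anchors x (4 box + 1 objectness + 1 class).
#'
#' @param cfg A [modelConfig()].
#' @param anchors An [AnchorSet-class] stored with the model.
#' @param seed Integer seed for weight initialization.
#' @return A \code{"goatDetector"} list: \code{cfg}, \code{anchors},
#'   \code{modules}, flat \code{params}, and \code{nParams}.
#' @export
buildDetector <- function(cfg = modelConfig(),
                          anchors = defaultSmallTargetAnchors(),
                          seed = 1) {
  set.seed(seed)
  B <- cfg$baseChannels
  Cn <- 4 * B                       # common neck width
  headC <- cfg$anchorsPerScale * (5 + cfg$numClasses)
  mods <- list(
    stem  = mkConv(3, B, k = 3, stride = 2),        # stride 2
    d1    = mkConv(B, 2 * B, k = 3, stride = 2),    # stride 4
    c1    = mkCSP(2 * B),
    d2    = mkConv(2 * B, 4 * B, k = 3, stride = 2),  # stride 8 tap
    c2    = mkCSP(4 * B),
    d3    = mkConv(4 * B, 8 * B, k = 3, stride = 2),  # stride 16 tap
    c3    = mkCSP(8 * B),
    d4    = mkConv(8 * B, 16 * B, k = 3, stride = 2), # stride 32 tap
    c4    = mkCSP(16 * B),
    spp   = mkSPPCSPC(16 * B, Cn),
    lat3  = mkConv(4 * B, Cn, k = 1),
    lat4  = mkConv(8 * B, Cn, k = 1),
    ctx3  = mkContextModule(Cn, Ccoarse = Cn, Cfine = NULL,
                            ecaKernel = cfg$ecaKernel),
    ctx4  = mkContextModule(Cn, Ccoarse = Cn, Cfine = Cn,
                            ecaKernel = cfg$ecaKernel),
    ctx5  = mkContextModule(Cn, Ccoarse = NULL, Cfine = Cn,
                            ecaKernel = cfg$ecaKernel),
    fcmUp   = mkFCMBlock(Cn, Cn, Cn, Cn, "up"),
    fcmDown = mkFCMBlock(Cn, Cn, Cn, Cn, "down"),
    neck4 = mkConv(Cn, Cn, k = 3),
    head3 = mkConv(Cn, headC, k = 1, bn = FALSE, act = FALSE),
    head4 = mkConv(Cn, headC, k = 1, bn = FALSE, act = FALSE),
    head5 = mkConv(Cn, headC, k = 1, bn = FALSE, act = FALSE))
  flat <- .collectParams(mods)
  n <- sum(vapply(flat$params, function(p) length(p$value), 0))
  structure(list(cfg = cfg, anchors = anchors, modules = mods,
                 params = flat$params, states = flat$states,
                 nParams = n, seed = seed),
            class = "goatDetector")
}

#' @export
print.goatDetector <- function(x, ...) {
  cat(sprintf(
    "goatDetector: input %d, %d class(es), %d parameters, strides 8/16/32\n",
    x$cfg$inputSize, x$cfg$numClasses, x$nParams))
  invisible(x)
}

#' Forward pass of the detector
#'
#' @param model A [buildDetector()] result.
#' @param x Input array (H, W, 3, N) in \[0, 1\], H = W divisible by 32.
#' @param training Batch-norm mode.
#' @param tape Internal tape for training (NULL for inference).
#' @return List of three raw head tensors (environments; \code{$value}
#'   arrays of shape (H/8, W/8, A(5+nc), N) etc.).
#' @export
forwardDetector <- function(model, x, training = FALSE, tape = NULL) {
  m <- model$modules
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  if (dim(x)[1] %% 32 != 0 || dim(x)[2] %% 32 != 0)
    stop("input spatial size must be divisible by 32")
  t0 <- tvar(x)
  y <- m$stem$fwd(tape, t0, training)
  y <- m$c1$fwd(tape, m$d1$fwd(tape, y, training), training)
  p3 <- m$c2$fwd(tape, m$d2$fwd(tape, y, training), training)
  p4 <- m$c3$fwd(tape, m$d3$fwd(tape, p3, training), training)
  p5 <- m$c4$fwd(tape, m$d4$fwd(tape, p4, training), training)
  p5 <- m$spp$fwd(tape, p5, training)
  l3 <- m$lat3$fwd(tape, p3, training)
  l4 <- m$lat4$fwd(tape, p4, training)
  f3 <- m$ctx3$fwd(tape, l3, fCoarse = l4, fFine = NULL, training = training)
  f4 <- m$ctx4$fwd(tape, l4, fCoarse = p5, fFine = l3, training = training)
  f5 <- m$ctx5$fwd(tape, p5, fCoarse = NULL, fFine = l4, training = training)
  n3 <- m$fcmUp$fwd(tape, f3, f4, f5, training)
  n5 <- m$fcmDown$fwd(tape, f3, f4, f5, training)
  n4 <- m$neck4$fwd(tape, f4, training)
  list(m$head3$fwd(tape, n3, training),
       m$head4$fwd(tape, n4, training),
       m$head5$fwd(tape, n5, training))
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Decode one head's raw array for image n at one level.
.decodeLevel <- function(raw, level, anchors, stride, numClasses, n = 1) {
  A <- 3
  d <- dim(raw)
  gh <- d[1]; gw <- d[2]
  per <- 5 + numClasses
  awh <- anchorsAtScale(anchors, level)
  out <- list()
  for (a in 1:A) {
    ch <- (a - 1) * per
    tx <- .sigmoid(raw[, , ch + 1, n]); ty <- .sigmoid(raw[, , ch + 2, n])
    tw <- .sigmoid(raw[, , ch + 3, n]); th <- .sigmoid(raw[, , ch + 4, n])
    obj <- .sigmoid(raw[, , ch + 5, n])
    cls <- .sigmoid(raw[, , ch + 5 + seq_len(numClasses), n, drop = FALSE])
    gj <- matrix(0:(gh - 1), gh, gw)          # rows = y cells
    gi <- matrix(0:(gw - 1), gh, gw, byrow = TRUE)
    out[[a]] <- data.frame(
      cx = as.numeric((2 * tx - 0.5 + gi) * stride),
      cy = as.numeric((2 * ty - 0.5 + gj) * stride),
      w = as.numeric((2 * tw)^2 * awh[a, 1]),
      h = as.numeric((2 * th)^2 * awh[a, 2]),
      score = as.numeric(obj) * as.numeric(apply(cls, c(1, 2), max)))
  }
  do.call(rbind, out)
}

# Greedy non-maximum suppression; ties broken by original index.
.nms <- function(dets, iouThresh = 0.5) {
  if (nrow(dets) == 0) return(dets)
  ord <- order(-dets$score, seq_len(nrow(dets)))
  keep <- integer(0)
  boxes <- as.matrix(dets[, c("cx", "cy", "w", "h")])
  for (i in ord) {
    if (length(keep) > 0) {
      ious <- boxIoU(boxes[rep(i, length(keep)), , drop = FALSE],
                     boxes[keep, , drop = FALSE])
      if (any(ious > iouThresh)) next
    }
    keep <- c(keep, i)
  }
  dets[keep, , drop = FALSE]
}

#' Decode raw head outputs into detections
#'
#' Sigmoid-decodes objectness, class scores and anchor-relative box
#' offsets (cell offset range \eqn{2\sigma - 0.5}, size factor
#' \eqn{(2\sigma)^2} times the anchor), thresholds on the combined score
#' and applies greedy non-maximum suppression.
#'
#' @param heads List of three raw head arrays (or tensors) from
#'   [forwardDetector()].
#' @param anchors The model's [AnchorSet-class].
#' @param cfg The [modelConfig()].
#' @param confThresh Minimum objectness x class score (default 0.25).
#' @param nmsIoU NMS IoU threshold (default 0.5).
#' @param imageID Identifier attached to the detections.
#' @param n Batch index to decode.
#' @return data.frame of detections: \code{imageID, cx, cy, w, h, score}.
#' @export
decodePredictions <- function(heads, anchors, cfg, confThresh = 0.25,
                              nmsIoU = 0.5, imageID = "img", n = 1) {
  strides <- anchorStrides(anchors)
  all <- list()
  for (l in 1:3) {
    raw <- if (is.environment(heads[[l]])) heads[[l]]$value else heads[[l]]
    all[[l]] <- .decodeLevel(raw, l, anchors, strides[l], cfg$numClasses, n)
  }
  dets <- do.call(rbind, all)
  dets <- dets[dets$score >= confThresh, , drop = FALSE]
  dets <- .nms(dets, nmsIoU)
  if (nrow(dets) > 0) dets <- cbind(imageID = imageID, dets)
  rownames(dets) <- NULL
  dets
}
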