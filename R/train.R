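# Training loop, composite loss, checkpointing, evaluation, prediction.

#' Training configuration
#'
#' Defaults follow the study protocol: batches of eight images, initial
#' learning rate 1e-4, AdamW, 100 epochs with checkpoints every 10.
#'
#' @param batchSize Images per optimizer step (>= 1).
#' @param learningRate AdamW learning rate.
#' @param epochs Training epochs.
#' @param checkpointEvery Checkpoint cadence in epochs (must divide into a
#'   positive epoch budget).
#' @param weightDecay Decoupled weight decay (skipped for biases, batch
#'   norm and attention parameters).
#' @param seed Seed for batch shuffling (weights are seeded at
#'   [buildDetector()]).
#' @param mosaicProb,mixupProb Per-batch-item augmentation probabilities
#'   (default 0: raw scenes).
#' @param loss A [lossConfig()].
#' @return List of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(batchSize = 8, learningRate = 1e-4, epochs = 100,
                        checkpointEvery = 10, weightDecay = 0.01,
                        seed = 1, mosaicProb = 0, mixupProb = 0,
                        loss = lossConfig()) {
  stopifnot(batchSize >= 1, epochs >= 1, checkpointEvery >= 1)
  structure(list(batchSize = as.integer(batchSize),
                 learningRate = learningRate, epochs = as.integer(epochs),
                 checkpointEvery = as.integer(checkpointEvery),
                 weightDecay = weightDecay, seed = as.integer(seed),
                 mosaicProb = mosaicProb, mixupProb = mixupProb,
                 loss = loss),
            class = "TrainConfig")
}

# Composite detection loss on a forward pass. heads: list of three head
# tensors; anns: list of FaceAnnotation (input-pixel coordinates), one
# per batch image. Returns term values plus gradient seeds for backprop.
# Objectness/class BCE gradients are analytic; the localization term's
# gradient is taken by central finite differences on each positive's
# four raw box outputs.
detectionLoss <- function(heads, anns, model, lcfg = lossConfig()) {
  cfg <- model$cfg
  per <- 5 + cfg$numClasses
  strides <- anchorStrides(model$anchors)
  specs <- headSpecs(cfg$inputSize, strides)
  N <- dim(heads[[1]]$value)[4]
  assigns <- lapply(anns, assignTargets, anchors = model$anchors,
                    specs = specs)
  seeds <- vector("list", 3)
  objLossNum <- 0; objCount <- 0
  clsLossNum <- 0; clsCount <- 0
  locLossNum <- 0; locCount <- 0
  gradObjAll <- list(); gradClsAll <- list(); gradLocAll <- list()
  for (l in 1:3) {
    raw <- heads[[l]]$value
    d <- dim(raw)
    tobj <- array(0, d)
    wobj <- array(lcfg$bceWeight, d)   # omega on every obj slot
    gradLoc <- array(0, d)
    objIdx <- (0:2) * per + 5
    stride <- strides[l]
    awh <- anchorsAtScale(model$anchors, l)
    for (n in seq_len(N)) {
      pos <- assigns[[n]]
      pos <- pos[pos$level == l, , drop = FALSE]
      for (i in seq_len(nrow(pos))) {
        a <- pos$anchor[i]; gi <- pos$gi[i]; gj <- pos$gj[i]
        ch <- (a - 1) * per
        tobj[gj + 1, gi + 1, ch + 5, n] <- 1
        wobj[gj + 1, gi + 1, ch + 5, n] <- pos$weight[i] * lcfg$bceWeight
        gt <- boxCS(pos$cx[i], pos$cy[i], pos$w[i], pos$h[i])
        r <- raw[gj + 1, gi + 1, ch + 1:4, n]
        decode <- function(rv) {
          s <- 1 / (1 + exp(-rv))
          boxCS((2 * s[1] - 0.5 + gi) * stride,
                (2 * s[2] - 0.5 + gj) * stride,
                (2 * s[3])^2 * awh[a, 1],
                (2 * s[4])^2 * awh[a, 2])
        }
        li <- localizationLoss(decode(r), gt, lcfg)
        locLossNum <- locLossNum + pos$weight[i] * li
        locCount <- locCount + 1
        h <- 1e-3
        for (j in 1:4) {
          up <- r; up[j] <- up[j] + h
          dn <- r; dn[j] <- dn[j] - h
          gradLoc[gj + 1, gi + 1, ch + j, n] <- pos$weight[i] *
            (localizationLoss(decode(up), gt, lcfg) -
               localizationLoss(decode(dn), gt, lcfg)) / (2 * h)
        }
        # class term (single class: target 1 at positives)
        for (cc in seq_len(cfg$numClasses)) {
          zi <- raw[gj + 1, gi + 1, ch + 5 + cc, n]
          pcl <- 1 / (1 + exp(-zi))
          clsLossNum <- clsLossNum +
            lcfg$bceWeight * (-log(pmax(pcl, 1e-12)))
          clsCount <- clsCount + 1
        }
      }
    }
    zobj <- raw[, , objIdx, , drop = FALSE]
    pobj <- 1 / (1 + exp(-zobj))
    t <- tobj[, , objIdx, , drop = FALSE]
    w <- wobj[, , objIdx, , drop = FALSE]
    objLossNum <- objLossNum +
      sum(-w * (t * log(pmax(pobj, 1e-12)) +
                  (1 - t) * log(pmax(1 - pobj, 1e-12))))
    objCount <- objCount + length(zobj)
    gradObj <- array(0, d)
    gradObj[, , objIdx, ] <- w * (pobj - t)
    gradCls <- array(0, d)
    for (a in 1:3) {
      chs <- (a - 1) * per + 5 + seq_len(cfg$numClasses)
      zc <- raw[, , chs, , drop = FALSE]
      pc <- 1 / (1 + exp(-zc))
      mask <- array(0, dim(zc))        # positives mask per class channel
      for (cc in seq_len(cfg$numClasses))
        mask[, , cc, ] <- tobj[, , (a - 1) * per + 5, ]
      gradCls[, , chs, ] <- lcfg$bceWeight * (pc - 1) * mask
    }
    gradObjAll[[l]] <- gradObj
    gradClsAll[[l]] <- gradCls
    gradLocAll[[l]] <- gradLoc
  }
  lConf <- objLossNum / max(objCount, 1)
  lCls <- if (clsCount > 0) clsLossNum / clsCount else 0
  lLoc <- if (locCount > 0) locLossNum / locCount else 0
  for (l in 1:3) {
    g <- lcfg$wConf * gradObjAll[[l]] / max(objCount, 1)
    if (clsCount > 0) g <- g + lcfg$wCls * gradClsAll[[l]] / clsCount
    if (locCount > 0) g <- g + lcfg$wLoc * gradLocAll[[l]] / locCount
    seeds[[l]] <- list(tensor = heads[[l]], grad = g)
  }
  list(total = totalLoss(lConf, lCls, lLoc, lcfg),
       lConf = lConf, lCls = lCls, lLoc = lLoc,
       nPositives = locCount, seeds = seeds)
}

# Stack a list of (H, W, 3) images into an (H, W, 3, N) batch.
.stackImages <- function(imgs) {
  d <- dim(imgs[[1]])
  x <- array(0, c(d[1], d[2], 3, length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]
  x
}

#' Load a dataset manifest
#'
#' Reads the two-column (image TAB annotation) manifest written by
#' [writeSyntheticDataset()], loading PNG images and VOC annotations,
#' optionally resizing to the model input size (boxes rescaled).
#'
#' @param path Manifest path.
#' @param inputSize Target square size, or NULL to keep native size.
#' @return List of \code{list(image =, annotation =)} items.
#' @export
loadManifest <- function(path, inputSize = NULL) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.table(path, sep = "\t", col.names = c("image", "xml"),
                           stringsAsFactors = FALSE)
  if (nrow(man) == 0) stop("empty manifest: ", path)
  lapply(seq_len(nrow(man)), function(i) {
    img <- png::readPNG(man$image[i])
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img <- img[, , 1:3, drop = FALSE]
    ann <- readVOC(man$xml[i])
    if (!is.null(inputSize)) {
      sy <- inputSize / dim(img)[1]; sx <- inputSize / dim(img)[2]
      img <- .resizeImage(img, inputSize, inputSize)
      b <- annotationBoxes(ann)
      if (nrow(b) > 0)
        b <- boxCS(b[, 1] * sx, b[, 2] * sy, b[, 3] * sx, b[, 4] * sy)
      ann <- FaceAnnotation(imageID(ann), c(inputSize, inputSize), b,
                            boxWeights(ann))
    }
    list(image = img, annotation = ann)
  })
}

#' Train the detector
#'
#' Full-precision CPU training with AdamW under the composite loss.
#' Deterministic for fixed seeds in single-threaded BLAS. Writes a
#' per-epoch loss log and periodic checkpoints when \code{outDir} is
#' given.
#'
#' @param model A [buildDetector()] model (modified in place and
#'   returned).
#' @param dataset List of \code{list(image =, annotation =)} items sized
#'   to the model input (see [loadManifest()] / [synthScene()]), or a
#'   manifest path.
#' @param tcfg A [trainConfig()].
#' @param outDir Optional output directory for \code{loss_log.csv} and
#'   checkpoints.
#' @param verbose Print epoch losses.
#' @return The model, with the loss log (data.frame) as attribute
#'   \code{"lossLog"}.
#' @export
trainDetector <- function(model, dataset, tcfg = trainConfig(),
                          outDir = NULL, verbose = FALSE) {
  if (is.character(dataset))
    dataset <- loadManifest(dataset, model$cfg$inputSize)
  if (length(dataset) == 0) stop("empty training dataset")
  if (!is.null(outDir))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  optState <- new.env(parent = emptyenv())
  optState$m <- list(); optState$v <- list()
  set.seed(tcfg$seed)
  log <- data.frame(epoch = integer(0), total = numeric(0),
                    conf = numeric(0), cls = numeric(0), loc = numeric(0))
  for (epoch in seq_len(tcfg$epochs)) {
    ord <- sample(length(dataset))
    batches <- split(ord, ceiling(seq_along(ord) / tcfg$batchSize))
    esum <- c(total = 0, conf = 0, cls = 0, loc = 0); nb <- 0
    for (bt in batches) {
      items <- dataset[bt]
      if (tcfg$mosaicProb > 0 || tcfg$mixupProb > 0)
        items <- lapply(items, function(it) {
          if (stats::runif(1) < tcfg$mosaicProb) {
            pick <- dataset[sample(length(dataset), 4, replace = TRUE)]
            it <- mosaicAugment(pick, imageSize(it$annotation),
                                seed = sample.int(1e6, 1))
          }
          if (stats::runif(1) < tcfg$mixupProb) {
            other <- dataset[[sample(length(dataset), 1)]]
            it <- mixupAugment(it, other, seed = sample.int(1e6, 1))
          }
          it
        })
      x <- .stackImages(lapply(items, `[[`, "image"))
      anns <- lapply(items, `[[`, "annotation")
      tape <- newTape()
      heads <- forwardDetector(model, x, training = TRUE, tape = tape)
      ls <- detectionLoss(heads, anns, model, tcfg$loss)
      zeroGrads(model$params)
      backprop(tape, ls$seeds)
      adamwStep(model$params, optState, lr = tcfg$learningRate,
                weightDecay = tcfg$weightDecay)
      esum <- esum + c(ls$total, ls$lConf, ls$lCls, ls$lLoc); nb <- nb + 1
    }
    esum <- esum / nb
    log <- rbind(log, data.frame(epoch = epoch, total = esum[1],
                                 conf = esum[2], cls = esum[3],
                                 loc = esum[4]))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f (conf %.5f cls %.5f loc %.5f)",
                      epoch, esum[1], esum[2], esum[3], esum[4]))
    if (!is.null(outDir)) {
      utils::write.csv(log, file.path(outDir, "loss_log.csv"),
                       row.names = FALSE)
      if (epoch %% tcfg$checkpointEvery == 0)
        saveCheckpoint(model, file.path(outDir,
                                        sprintf("ckpt_%04d.rds", epoch)))
    }
  }
  attr(model, "lossLog") <- log
  model
}

#' Save / load a self-describing checkpoint
#'
#' A checkpoint holds the model configuration, anchor set, weight values
#' and batch-norm running statistics; [loadCheckpoint()] rebuilds the
#' model without any external configuration.
#'
#' @param model A \code{"goatDetector"}.
#' @param path Checkpoint file path.
#' @return \code{path} (save) / the rebuilt model (load).
#' @export
saveCheckpoint <- function(model, path) {
  obj <- list(cfg = model$cfg,
              anchorPairs = anchorPairs(model$anchors),
              anchorStrides = anchorStrides(model$anchors),
              seed = model$seed,
              params = lapply(model$params, function(p) p$value),
              states = lapply(model$states, function(s)
                list(runMean = s$runMean, runVar = s$runVar)))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  model <- buildDetector(obj$cfg, AnchorSet(obj$anchorPairs,
                                            obj$anchorStrides),
                         seed = obj$seed)
  for (nm in names(obj$params)) model$params[[nm]]$value <- obj$params[[nm]]
  for (nm in names(obj$states)) {
    model$states[[nm]]$runMean <- obj$states[[nm]]$runMean
    model$states[[nm]]$runVar <- obj$states[[nm]]$runVar
  }
  model
}

#' Evaluate a detector on a dataset
#'
#' Runs inference on every item, decodes detections and scores them
#' against the ground truth (P/R/F1 at \code{confThresh}, threshold-free
#' AP).
#'
#' @param model A \code{"goatDetector"} (or checkpoint path).
#' @param dataset Items as for [trainDetector()], or a manifest path.
#' @param iouThresh Matching IoU threshold (default 0.7).
#' @param confThresh Confidence cutoff for P/R/F1 (default 0.5).
#' @param decodeThresh Decoder score floor (default 0.05; keeps the PR
#'   sweep informative below \code{confThresh}).
#' @param nmsIoU NMS threshold.
#' @return One metric row (model, P, R, F1, AP) with the detection and
#'   ground-truth tables as attributes \code{"detections"}, \code{"gts"}.
#' @export
evaluateDetector <- function(model, dataset, iouThresh = 0.7,
                             confThresh = 0.5, decodeThresh = 0.05,
                             nmsIoU = 0.5) {
  if (is.character(model)) model <- loadCheckpoint(model)
  if (is.character(dataset))
    dataset <- loadManifest(dataset, model$cfg$inputSize)
  dets <- list(); gts <- list()
  for (it in dataset) {
    id <- imageID(it$annotation)
    heads <- forwardDetector(model, it$image, training = FALSE)
    dd <- decodePredictions(heads, model$anchors, model$cfg,
                            confThresh = decodeThresh, nmsIoU = nmsIoU,
                            imageID = id)
    if (nrow(dd) > 0) dets[[length(dets) + 1]] <- dd
    b <- annotationBoxes(it$annotation)
    if (nrow(b) > 0)
      gts[[length(gts) + 1]] <-
        data.frame(imageID = id, cx = b[, 1], cy = b[, 2], w = b[, 3],
                   h = b[, 4])
  }
  dets <- if (length(dets)) do.call(rbind, dets) else
    data.frame(imageID = character(0), cx = numeric(0), cy = numeric(0),
               w = numeric(0), h = numeric(0), score = numeric(0))
  gts <- if (length(gts)) do.call(rbind, gts) else
    data.frame(imageID = character(0), cx = numeric(0), cy = numeric(0),
               w = numeric(0), h = numeric(0))
  tab <- metricTable(list(detector = dets), gts, iouThresh = iouThresh,
                     confThresh = confThresh)
  attr(tab, "detections") <- dets
  attr(tab, "gts") <- gts
  tab
}

#' Run the detector on images
#'
#' @param model A \code{"goatDetector"} or checkpoint path.
#' @param images A single (H, W, 3) array, a list of them, or PNG paths.
#' @param confThresh Minimum detection score.
#' @param nmsIoU NMS threshold.
#' @return List per image: \code{detections} (data.frame) and
#'   \code{overlay} (the image with detection boxes burned in red).
#' @export
predictDetector <- function(model, images, confThresh = 0.25,
                            nmsIoU = 0.5) {
  if (is.character(model)) model <- loadCheckpoint(model)
  if (!is.list(images)) {
    images <- if (is.character(images)) as.list(images) else list(images)
  }
  lapply(seq_along(images), function(i) {
    img <- images[[i]]
    if (is.character(img)) img <- png::readPNG(img)[, , 1:3]
    heads <- forwardDetector(model, img, training = FALSE)
    dd <- decodePredictions(heads, model$anchors, model$cfg,
                            confThresh = confThresh, nmsIoU = nmsIoU,
                            imageID = sprintf("image_%d", i))
    over <- img
    if (nrow(dd) > 0) {
      cr <- boxToCorners(as.matrix(dd[, c("cx", "cy", "w", "h")]))
      H <- dim(img)[1]; W <- dim(img)[2]
      for (r in seq_len(nrow(cr))) {
        x1 <- max(1, round(cr[r, 1])); y1 <- max(1, round(cr[r, 2]))
        x2 <- min(W, round(cr[r, 3])); y2 <- min(H, round(cr[r, 4]))
        over[y1:y2, c(x1, x2), 1] <- 1
        over[y1:y2, c(x1, x2), 2:3] <- 0
        over[c(y1, y2), x1:x2, 1] <- 1
        over[c(y1, y2), x1:x2, 2:3] <- 0
      }
    }
    list(detections = dd, overlay = over)
  })
}
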