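# Synthetic goat-scene generator. The field dataset it emulates is not
# public: pasture/barn frames of 1920x1080 px holding several small
# (8-55 px) goat faces, often clustered, captured between 06:00 and 18:00
# under varying light. Scenes are rendered procedurally and fully
# determined by their seed, with exact bounding boxes emitted.

#' Scene-generator parameters
#'
#' Defaults emulate the study conditions: full-HD frames, 4-11 faces per
#' frame (the field set averages ~7.4 faces/image), face sides uniform in
#' 8-55 px, half the scenes with clustered placement, global illumination
#' between dawn-dim and midday, and mild sensor noise.
#'
#' @param imageSize (width, height) in pixels; use \code{c(640, 640)} for
#'   training-sized scenes.
#' @param nFaces Integer range (min, max) of faces per scene.
#' @param faceSideRange Range of the face bounding-box max side, pixels.
#' @param clusterProb Probability a scene places faces in clusters.
#' @param illuminationRange Global brightness multiplier range.
#' @param noiseSD Gaussian pixel noise standard deviation (image in
#'   \[0, 1\]).
#' @param seed Integer seed fixing the full scene.
#' @return A list of class \code{"SceneParams"}.
#' @export
sceneParams <- function(imageSize = c(1920, 1080), nFaces = c(4, 11),
                        faceSideRange = c(8, 55), clusterProb = 0.5,
                        illuminationRange = c(0.5, 1.1), noiseSD = 0.02,
                        seed = 1) {
  stopifnot(length(imageSize) == 2, all(imageSize > 0),
            faceSideRange[1] > 0,
            faceSideRange[2] < min(imageSize),
            clusterProb >= 0, clusterProb <= 1, noiseSD >= 0)
  structure(list(imageSize = as.integer(imageSize),
                 nFaces = as.integer(nFaces),
                 faceSideRange = as.numeric(faceSideRange),
                 clusterProb = clusterProb,
                 illuminationRange = as.numeric(illuminationRange),
                 noiseSD = noiseSD, seed = as.integer(seed)),
            class = "SceneParams")
}

# Bilinear upscale of a small matrix to (h, w): cheap smooth clutter field.
.upscaleMatrix <- function(m, h, w) {
  rows <- t(apply(m, 1, function(r)
    stats::approx(seq_along(r), r, n = w)$y))
  apply(rows, 2, function(cc) stats::approx(seq_along(cc), cc, n = h)$y)
}

.renderBackground <- function(h, w) {
  base <- 0.35 + 0.2 * outer(seq(0, 1, length.out = h),
                             seq(0, 1, length.out = w),
                             function(y, x) y * 0.5 + x * 0.2)
  blobs <- .upscaleMatrix(matrix(stats::runif(15 * 26, -0.15, 0.15), 15, 26),
                          h, w)
  fine <- matrix(stats::runif(h * w, -0.04, 0.04), h, w)
  ch <- base + blobs + fine
  img <- array(0, c(h, w, 3))
  img[, , 1] <- ch * 0.95
  img[, , 2] <- ch * 1.05   # grass/barn tint
  img[, , 3] <- ch * 0.8
  img
}

# Draw one two-tone goat face whose rendered extent exactly fills the
# (w x h) box centered at (cx, cy). 0-based continuous image coordinates.
.renderFace <- function(img, cx, cy, w, h, tone) {
  H <- dim(img)[1]; W <- dim(img)[2]
  x0 <- max(1, floor(cx - w / 2) + 1); x1 <- min(W, ceiling(cx + w / 2))
  y0 <- max(1, floor(cy - h / 2) + 1); y1 <- min(H, ceiling(cy + h / 2))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- (x0:x1) - 0.5; ys <- (y0:y1) - 0.5
  dx <- outer(rep(1, length(ys)), (xs - cx) / (w / 2))
  dy <- outer((ys - cy) / (h / 2), rep(1, length(xs)))
  inside <- dx^2 + dy^2 <= 1
  muzzle <- inside & dy > 0.25            # darker lower half
  eyeL <- (dx + 0.4)^2 + (dy + 0.25)^2 <= 0.02
  eyeR <- (dx - 0.4)^2 + (dy + 0.25)^2 <= 0.02
  texture <- 0.04 * sin(dx * 9) * cos(dy * 7)
  for (c in 1:3) {
    patch <- img[y0:y1, x0:x1, c]
    coat <- tone[c] + texture
    patch[inside] <- coat[inside]
    patch[muzzle] <- patch[muzzle] * 0.55
    patch[eyeL | eyeR] <- 0.05
    img[y0:y1, x0:x1, c] <- patch
  }
  img
}

#' Render a synthetic goat scene
#'
#' Procedurally renders a cluttered pasture background and a set of small
#' two-tone elliptical goat faces (with eye dots and darker muzzles),
#' applies a global illumination factor and Gaussian sensor noise, and
#' returns the image together with exact ground-truth boxes. Bit-identical
#' for a fixed seed.
#'
#' @param p A [sceneParams()] object.
#' @param id Image identifier for the annotation.
#' @return List with \code{image} (H x W x 3 array in \[0, 1\]) and
#'   \code{annotation} (a [FaceAnnotation-class]).
#' @export
synthScene <- function(p = sceneParams(), id = sprintf("scene_%06d", p$seed)) {
  set.seed(p$seed)
  w <- p$imageSize[1]; h <- p$imageSize[2]
  img <- .renderBackground(h, w)
  n <- if (p$nFaces[1] == p$nFaces[length(p$nFaces)]) p$nFaces[1] else
    sample(p$nFaces[1]:p$nFaces[2], 1)
  boxes <- NULL
  if (n > 0) {
    sides <- stats::runif(n, p$faceSideRange[1], p$faceSideRange[2])
    ws <- sides * stats::runif(n, 0.7, 1)   # faces slightly taller than wide
    hs <- sides
    clustered <- stats::runif(1) < p$clusterProb
    if (clustered) {
      nc <- sample(1:3, 1)
      centers <- cbind(stats::runif(nc, 0.2 * w, 0.8 * w),
                       stats::runif(nc, 0.2 * h, 0.8 * h))
      pick <- sample(nc, n, replace = TRUE)
      cx <- stats::rnorm(n, centers[pick, 1], 0.06 * w)
      cy <- stats::rnorm(n, centers[pick, 2], 0.06 * h)
    } else {
      cx <- stats::runif(n, 0, w)
      cy <- stats::runif(n, 0, h)
    }
    cx <- pmin(pmax(cx, ws / 2 + 1), w - ws / 2 - 1)
    cy <- pmin(pmax(cy, hs / 2 + 1), h - hs / 2 - 1)
    tones <- matrix(stats::runif(3 * n, 0.55, 0.95), n, 3)
    tones[, 2] <- tones[, 2] * 0.95; tones[, 3] <- tones[, 3] * 0.85
    for (i in seq_len(n))
      img <- .renderFace(img, cx[i], cy[i], ws[i], hs[i], tones[i, ])
    boxes <- boxCS(cx, cy, ws, hs)
  }
  illum <- stats::runif(1, p$illuminationRange[1], p$illuminationRange[2])
  img <- img * illum
  if (p$noiseSD > 0)
    img <- img + array(stats::rnorm(length(img), 0, p$noiseSD), dim(img))
  img <- pmin(pmax(img, 0), 1)
  list(image = img,
       annotation = FaceAnnotation(id, p$imageSize, boxes))
}

#' Write a synthetic dataset to disk
#'
#' Renders \code{n} scenes (seeds \code{seed, seed+1, ...}), writing PNG
#' images, VOC XML annotations and a two-column manifest (image path TAB
#' annotation path).
#'
#' @param n Number of scenes.
#' @param dir Output directory (created if needed).
#' @param p Base [sceneParams()]; its seed is replaced per scene.
#' @param seed First scene seed.
#' @return Path of the manifest file, invisibly; the manifest as a
#'   data.frame as attribute \code{"manifest"}.
#' @export
writeSyntheticDataset <- function(n, dir, p = sceneParams(), seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p$seed <- seed + i - 1L
    sc <- synthScene(p)
    ipath <- file.path(dir, paste0(imageID(sc$annotation), ".png"))
    apath <- file.path(dir, paste0(imageID(sc$annotation), ".xml"))
    png::writePNG(sc$image, ipath)
    writeVOC(sc$annotation, apath)
    rows[[i]] <- data.frame(image = ipath, annotation = apath)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.txt")
  utils::write.table(manifest, mpath, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  out <- invisible(mpath)
  attr(out, "manifest") <- manifest
  out
}

#' Keep only small-target images
#'
#' Image-level filter used when constructing the small-target dataset: an
#' image is kept iff every face box has \code{max(w, h) <= maxSide}
#' (default 50 px, the small-target definition; a 50-px face itself is
#' small). \code{mode = "box"} instead drops the offending boxes and keeps
#' the images.
#'
#' @param anns List of [FaceAnnotation-class] objects.
#' @param maxSide Size threshold in pixels.
#' @param mode \code{"image"} (default) or \code{"box"}.
#' @return List with \code{kept} (annotations) and \code{report}
#'   (data.frame: imageID, nBoxes, nOver, kept).
#' @export
smallTargetFilter <- function(anns, maxSide = 50,
                              mode = c("image", "box")) {
  mode <- match.arg(mode)
  report <- data.frame(imageID = character(0), nBoxes = integer(0),
                       nOver = integer(0), kept = logical(0))
  kept <- list()
  for (ann in anns) {
    b <- annotationBoxes(ann)
    over <- if (nrow(b) == 0) logical(0) else pmax(b[, 3], b[, 4]) > maxSide
    keepImage <- !any(over)
    if (mode == "image") {
      if (keepImage) kept[[length(kept) + 1]] <- ann
    } else {
      kept[[length(kept) + 1]] <-
        FaceAnnotation(imageID(ann), imageSize(ann),
                       b[!over, , drop = FALSE],
                       boxWeights(ann)[!over])
      keepImage <- TRUE
    }
    report <- rbind(report,
                    data.frame(imageID = imageID(ann), nBoxes = nrow(b),
                               nOver = sum(over), kept = keepImage))
  }
  list(kept = kept, report = report)
}
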