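test_that("VOC annotations round-trip losslessly", {
  dir <- withr::local_tempdir()
  ann <- FaceAnnotation("img001", c(1920, 1080),
                        boxFromCorners(c(0, 100.5), c(0, 200.5),
                                       c(50, 130.5), c(50, 240.5)))
  path <- file.path(dir, "img001.xml")
  writeVOC(ann, path)
  back <- readVOC(path)
  expect_equal(imageID(back), "img001")
  expect_equal(imageSize(back), c(1920L, 1080L))
  expect_equal(annotationBoxes(back), annotationBoxes(ann))
  # VOC 1-based inclusive corners: (1,1,50,50) is a 50-px box
  expect_equal(unname(annotationBoxes(back)[1, c("w", "h")]), c(50, 50))
  # malformed XML errors name the file
  badPath <- file.path(dir, "broken.xml")
  writeLines("<annotation><object>", badPath)
  expect_error(readVOC(badPath), "broken.xml")
  expect_error(readVOC(file.path(dir, "absent.xml")), "not found")
})

test_that("a bulk synthetic dataset survives VOC round-trips", {
  dir <- withr::local_tempdir()
  p <- sceneParams(imageSize = c(128, 128), nFaces = c(0, 5),
                   faceSideRange = c(8, 30))
  for (i in 1:200) {
    p$seed <- i
    sc <- synthScene(p)
    path <- file.path(dir, paste0(imageID(sc$annotation), ".xml"))
    writeVOC(sc$annotation, path)
    back <- readVOC(path)
    expect_equal(annotationBoxes(back), annotationBoxes(sc$annotation),
                 tolerance = 1e-9)
  }
})

test_that("small-target filter keeps <= 50 px images and is idempotent", {
  mk <- function(id, sides) {
    FaceAnnotation(id, c(640, 640),
                   boxCS(seq(60, by = 70, length.out = length(sides)),
                         100, sides, sides))
  }
  anns <- list(mk("ok", c(30, 49)), mk("edge", c(50, 8)),
               mk("over", c(20, 51)), FaceAnnotation("none", c(640, 640)))
  res <- smallTargetFilter(anns)
  keptIDs <- vapply(res$kept, imageID, "")
  expect_setequal(keptIDs, c("ok", "edge", "none"))
  expect_false(res$report$kept[res$report$imageID == "over"])
  # idempotence
  res2 <- smallTargetFilter(res$kept)
  expect_equal(vapply(res2$kept, imageID, ""), keptIDs)
  expect_equal(length(smallTargetFilter(list())$kept), 0)
  # box-level mode keeps the image, drops the oversized box
  resBox <- smallTargetFilter(anns, mode = "box")
  expect_equal(length(resBox$kept), 4)
  over <- resBox$kept[[3]]
  expect_equal(nrow(annotationBoxes(over)), 1)
  expect_lte(max(annotationBoxes(over)[, 3:4]), 50)
})

test_that("synthetic scenes honor their parameters deterministically", {
  p <- sceneParams(imageSize = c(96, 96), nFaces = c(0, 0), seed = 4)
  sc0 <- synthScene(p)
  expect_equal(nrow(annotationBoxes(sc0$annotation)), 0)
  p <- sceneParams(imageSize = c(96, 96), nFaces = c(3, 7),
                   faceSideRange = c(8, 40), seed = 12)
  a <- synthScene(p); b <- synthScene(p)
  expect_identical(a$image, b$image)
  expect_identical(annotationBoxes(a$annotation),
                   annotationBoxes(b$annotation))
  expect_true(all(a$image >= 0 & a$image <= 1))
  # box max-sides stay in range across many scenes
  p2 <- sceneParams(imageSize = c(128, 128), nFaces = c(1, 6),
                    faceSideRange = c(8, 55))
  for (s in 1:60) {
    p2$seed <- s
    bx <- annotationBoxes(synthScene(p2)$annotation)
    if (nrow(bx) == 0) next
    ms <- pmax(bx[, 3], bx[, 4])
    expect_true(all(ms >= 8 & ms <= 55))
    cr <- boxToCorners(bx)
    expect_true(all(cr[, 1] >= 0 & cr[, 2] >= 0 &
                      cr[, 3] <= 128 & cr[, 4] <= 128))
  }
})

test_that("mosaic stitches, clips and preserves bounds", {
  scenes <- tinyScenes(4, size = 64)
  mz <- mosaicAugment(scenes, outSize = c(64, 64), seed = 5)
  expect_equal(dim(mz$image), c(64, 64, 3))
  bx <- annotationBoxes(mz$annotation)
  if (nrow(bx) > 0) {
    cr <- boxToCorners(bx)
    expect_true(all(cr[, 1] >= -1e-9 & cr[, 2] >= -1e-9 &
                      cr[, 3] <= 64 + 1e-9 & cr[, 4] <= 64 + 1e-9))
  }
  # four copies of a single-box image: at most 4 surviving boxes
  one <- scenes[[1]]
  one$annotation <- FaceAnnotation("one", c(64, 64), boxCS(32, 32, 20, 20))
  mz4 <- mosaicAugment(list(one, one, one, one), c(64, 64), seed = 9)
  expect_lte(nrow(annotationBoxes(mz4$annotation)), 4)
  # degenerate configuration: center at the middle, no scale jitter,
  # crops aligned with the quadrants -> each quadrant equals its source
  mzd <- mosaicAugment(list(one, one, one, one), c(64, 64), seed = 1,
                       scaleRange = c(1, 1), center = c(0.5, 0.5),
                       cropOffsets = list(c(0, 0), c(32, 0),
                                          c(0, 32), c(32, 32)))
  expect_equal(mzd$image[1:32, 1:32, ], one$image[1:32, 1:32, ])
  expect_equal(mzd$image[33:64, 33:64, ], one$image[33:64, 33:64, ])
  # bound preservation across random seeds
  for (s in 1:20) {
    m <- mosaicAugment(scenes, c(64, 64), seed = s)
    bx <- annotationBoxes(m$annotation)
    if (nrow(bx) == 0) next
    cr <- boxToCorners(bx)
    expect_true(all(cr[, 1] >= -1e-9 & cr[, 2] >= -1e-9 &
                      cr[, 3] <= 64 + 1e-9 & cr[, 4] <= 64 + 1e-9))
    expect_true(all(bx[, 3] * bx[, 4] >= 8))
  }
})

test_that("mixup blends pixels and unites weighted labels", {
  a <- list(image = array(100 / 255, c(16, 16, 3)),
            annotation = FaceAnnotation("a", c(16, 16), boxCS(8, 8, 4, 4)))
  b <- list(image = array(200 / 255, c(16, 16, 3)),
            annotation = FaceAnnotation("b", c(16, 16),
                                        boxCS(c(4, 12), 8, 3, 3)))
  half <- mixupAugment(a, b, lambda = 0.5)
  expect_equal(unique(as.numeric(half$image)), 150 / 255)
  expect_equal(nrow(annotationBoxes(half$annotation)), 3)
  expect_equal(sum(boxWeights(half$annotation)), 0.5 * 1 + 0.5 * 2)
  pure <- mixupAugment(a, b, lambda = 1)
  expect_equal(pure$image, a$image)
  expect_equal(nrow(annotationBoxes(pure$annotation)), 1)
  expect_equal(boxWeights(pure$annotation), 1)
  lam <- 0.3
  mixed <- mixupAugment(a, b, lambda = lam)
  expect_equal(sum(boxWeights(mixed$annotation)), lam * 1 + (1 - lam) * 2)
  # sampled lambda is seed-deterministic
  m1 <- mixupAugment(a, b, seed = 7); m2 <- mixupAugment(a, b, seed = 7)
  expect_identical(m1$image, m2$image)
})

test_that("synthetic datasets write and reload through the manifest", {
  dir <- withr::local_tempdir()
  p <- sceneParams(imageSize = c(64, 64), nFaces = c(1, 3),
                   faceSideRange = c(8, 24))
  mpath <- writeSyntheticDataset(5, dir, p, seed = 2)
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  items <- loadManifest(file.path(dir, "manifest.txt"))
  expect_length(items, 5)
  expect_equal(dim(items[[1]]$image), c(64, 64, 3))
  # resize path rescales boxes proportionally
  items32 <- loadManifest(file.path(dir, "manifest.txt"), inputSize = 32)
  b64 <- annotationBoxes(items[[1]]$annotation)
  b32 <- annotationBoxes(items32[[1]]$annotation)
  expect_equal(b32, b64 / 2, tolerance = 1e-9)
})
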