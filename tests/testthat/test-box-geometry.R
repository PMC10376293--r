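test_that("corner/center conversion round-trips exactly", {
  set.seed(1)
  for (i in 1:20) {
    b <- boxCS(runif(1, 0, 100), runif(1, 0, 100),
               runif(1, 0.1, 50), runif(1, 0.1, 50))
    cr <- boxToCorners(b)
    b2 <- boxFromCorners(cr[, 1], cr[, 2], cr[, 3], cr[, 4])
    expect_equal(unname(b2), unname(b))
  }
  expect_error(boxCS(0, 0, -1, 1, clamp = FALSE), "positive")
  clamped <- boxCS(0, 0, 0, 1)
  expect_gt(clamped[, "w"], 0)
})

test_that("IoU matches hand values and the rasterization oracle", {
  a <- boxFromCorners(0, 0, 2, 2)
  b <- boxFromCorners(1, 1, 3, 3)
  expect_equal(boxIoU(a, b), 1 / 7)
  expect_equal(gridIoU(a, b, res = 8), 1 / 7, tolerance = 1e-9)
  expect_equal(boxIoU(a, a), 1)
  expect_equal(boxIoU(a, boxFromCorners(5, 5, 7, 7)), 0)
  set.seed(7)
  for (i in 1:200) {
    p <- randomBoxPair()
    if (boxIoU(p$a, p$b) == 0 && gridIoU(p$a, p$b) == 0) next
    expect_equal(boxIoU(p$a, p$b), gridIoU(p$a, p$b), tolerance = 1e-6)
  }
})

test_that("GIoU penalizes empty enclosure and never exceeds IoU", {
  expect_equal(boxGIoU(boxCS(5, 5, 2, 2), boxCS(5, 5, 2, 2)), 1)
  a <- boxFromCorners(0, 0, 1, 1)
  b <- boxFromCorners(2, 0, 3, 1)
  expect_equal(boxGIoU(a, b), -1 / 3)
  set.seed(11)
  for (i in 1:50) {
    p <- randomBoxPair()
    expect_lte(boxGIoU(p$a, p$b), boxIoU(p$a, p$b) + 1e-12)
  }
})

test_that("DIoU equals IoU minus the normalized center distance", {
  expect_equal(boxDIoU(boxCS(5, 5, 4, 4), boxCS(5, 5, 4, 4)), 1)
  # concentric boxes: zero center penalty
  expect_equal(boxDIoU(boxCS(10, 10, 8, 8), boxCS(10, 10, 2, 2)),
               boxIoU(boxCS(10, 10, 8, 8), boxCS(10, 10, 2, 2)))
  set.seed(13)
  for (i in 1:50) {
    p <- randomBoxPair()
    ca <- boxToCorners(p$a); cb <- boxToCorners(p$b)
    rho2 <- (p$a[1] - p$b[1])^2 + (p$a[2] - p$b[2])^2
    ew <- max(ca[3], cb[3]) - min(ca[1], cb[1])
    eh <- max(ca[4], cb[4]) - min(ca[2], cb[2])
    expect_equal(boxDIoU(p$a, p$b),
                 boxIoU(p$a, p$b) - rho2 / (ew^2 + eh^2),
                 tolerance = 1e-9)
  }
})

test_that("CIoU reduces to DIoU at equal aspect ratios", {
  pr <- boxCS(4, 4, 10, 5)
  gt <- boxCS(9, 7, 6, 3)   # same 2:1 aspect
  expect_equal(boxCIoU(pr, gt), boxDIoU(pr, gt), tolerance = 1e-12)
  # explicit aspect-consistency term for 1:1 vs 2:1
  pr <- boxCS(5, 5, 4, 4); gt <- boxCS(6, 6, 8, 4)
  v <- (4 / pi^2) * (atan(2) - atan(1))^2
  iou <- boxIoU(pr, gt)
  alpha <- v / ((1 - iou) + v)
  expect_equal(boxCIoU(pr, gt), boxDIoU(pr, gt) - alpha * v,
               tolerance = 1e-12)
  expect_equal(boxCIoU(pr, pr), 1)
})

test_that("width-height CIoU matches its scalar formula", {
  gt <- boxCS(20, 20, 10, 8)
  expect_equal(boxWHCIoU(gt, gt), 1)
  # equal sizes, offset centers: size penalty vanishes entirely
  pr <- boxCS(23, 21, 10, 8)
  expect_equal(boxWHCIoU(pr, gt), boxDIoU(pr, gt), tolerance = 1e-12)
  # width ratio 2, height ratio 1 under the summed penalty
  pr <- boxCS(20, 20, 20, 8)
  iou <- boxIoU(pr, gt)
  rho2d2 <- boxIoU(pr, gt) - boxDIoU(pr, gt)
  eps <- (2 / pi^2) * ((atan(2) - pi / 4)^2 + (atan(1) - pi / 4)^2)
  beta <- eps / ((1 - iou) + eps)
  expect_equal(boxWHCIoU(pr, gt, "plus"), iou - rho2d2 - beta * eps,
               tolerance = 1e-12)
  # printed subtractive variant
  epsM <- (2 / pi^2) * ((atan(2) - pi / 4)^2 - (atan(1) - pi / 4)^2)
  betaM <- epsM / ((1 - iou) + epsM)
  expect_equal(boxWHCIoU(pr, gt, "as_printed_minus"),
               iou - rho2d2 - betaM * epsM, tolerance = 1e-12)
  # the ratios are defined directionally (wpr/wgt, hpr/hgt), yet the
  # value is swap-invariant because atan(x) + atan(1/x) = pi/2 makes each
  # squared deviation invariant under reciprocals; verify both facts
  a <- boxCS(10, 10, 12, 6); b <- boxCS(11, 12, 6, 9)
  expect_equal(boxWHCIoU(a, b), boxWHCIoU(b, a), tolerance = 1e-12)
  expect_equal((atan(12 / 6) - pi / 4)^2, (atan(6 / 12) - pi / 4)^2)
  expect_error(boxWHCIoU(a, cbind(10, 10, 0, 5)), "positive")
})

test_that("overlap family ordering and invariance properties hold", {
  set.seed(17)
  for (i in 1:100) {
    p <- randomBoxPair()
    iou <- boxIoU(p$a, p$b)
    expect_gte(iou, 0); expect_lte(iou, 1)
    expect_lte(boxGIoU(p$a, p$b), iou + 1e-12)
    expect_lte(boxDIoU(p$a, p$b), iou + 1e-12)
    expect_lte(boxCIoU(p$a, p$b), boxDIoU(p$a, p$b) + 1e-12)
    expect_lte(boxWHCIoU(p$a, p$b), iou + 1e-12)
    # symmetry of the symmetric members
    expect_equal(boxIoU(p$a, p$b), boxIoU(p$b, p$a))
    expect_equal(boxGIoU(p$a, p$b), boxGIoU(p$b, p$a))
    expect_equal(boxDIoU(p$a, p$b), boxDIoU(p$b, p$a))
    # translation and uniform-scale invariance of IoU
    sh <- runif(2, -20, 20); sc <- runif(1, 0.5, 3)
    at <- boxCS((p$a[1] + sh[1]) * sc, (p$a[2] + sh[2]) * sc,
                p$a[3] * sc, p$a[4] * sc)
    bt <- boxCS((p$b[1] + sh[1]) * sc, (p$b[2] + sh[2]) * sc,
                p$b[3] * sc, p$b[4] * sc)
    expect_equal(boxIoU(at, bt), iou, tolerance = 1e-9)
  }
  m <- overlapMetrics(boxCS(5, 5, 4, 4), boxCS(5, 5, 4, 4))
  expect_equal(unlist(m[1, 1:5]), c(iou = 1, giou = 1, diou = 1,
                                    ciou = 1, whciou = 1))
})

test_that("BCE and composite loss match closed forms", {
  expect_lt(bceLoss(1, 1 - 1e-9), 1e-6)
  expect_equal(bceLoss(1, 0.5), log(2))
  expect_equal(bceLoss(c(1, 0), c(0.5, 0.5), weight = 2),
               2 * bceLoss(c(1, 0), c(0.5, 0.5)))
  expect_equal(totalLoss(0, 0, 0), 0)
  expect_equal(totalLoss(1, 0, 0), 0.1)
  expect_equal(totalLoss(0, 1, 0), 0.125)
  expect_equal(totalLoss(0, 0, 1), 0.05)
  expect_equal(totalLoss(1, 1, 1), 0.275)
})

test_that("localization loss composes with the overlap variants", {
  b <- boxCS(5, 5, 4, 4)
  for (v in c("iou", "giou", "diou", "ciou", "wh_ciou"))
    expect_equal(localizationLoss(b, b, lossConfig(iouVariant = v)), 0)
  far <- boxCS(50, 50, 4, 4)
  expect_equal(localizationLoss(b, far, lossConfig(iouVariant = "iou")), 1)
  pr <- boxCS(6, 7, 5, 3)
  expect_equal(localizationLoss(pr, b, lossConfig(iouVariant = "wh_ciou")),
               1 - boxWHCIoU(pr, b))
})

test_that("gradient descent on the width-height CIoU loss is monotone", {
  set.seed(23)
  gt <- boxCS(30, 30, 18, 14)
  pr <- boxCS(44, 21, 7, 25)
  losses <- regressBoxDemo(pr, gt, lossConfig(iouVariant = "wh_ciou"),
                           steps = 500, lr = 1)
  expect_true(all(diff(losses) <= 1e-8))
  expect_lt(losses[length(losses)], 0.6 * losses[1])
})
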