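# The network engine is exercised at desk scale: 32-64 px inputs and
# narrow channel widths keep each forward pass in milliseconds while
# preserving every architectural contract (strides, channel bookkeeping,
# attention gating, fusion wiring).

tinyModel <- function(input = 64, base = 8, seed = 1,
                      anchors = defaultSmallTargetAnchors())
  buildDetector(modelConfig(inputSize = input, baseChannels = base),
                anchors, seed = seed)

test_that("head tensors obey the stride and channel contract", {
  m <- tinyModel(64, 8)
  x <- array(0.5, c(64, 64, 3, 1))
  h <- forwardDetector(m, x)
  expect_equal(dim(h[[1]]$value), c(8, 8, 18, 1))
  expect_equal(dim(h[[2]]$value), c(4, 4, 18, 1))
  expect_equal(dim(h[[3]]$value), c(2, 2, 18, 1))
  # 18 = anchorsPerScale * (4 box + 1 objectness + 1 class)
  cfg <- m$cfg
  expect_equal(cfg$anchorsPerScale * (5 + cfg$numClasses), 18)
  # head grids scale with input size (640 -> 80/40/20, 416 -> 52/26/13)
  expect_equal(headSpecs(640)$gw, c(80L, 40L, 20L))
  expect_equal(headSpecs(416)$gw, c(52L, 26L, 13L))
  expect_error(headSpecs(100), "divisible")
  expect_error(modelConfig(inputSize = 100), "divisible")
  expect_error(modelConfig(baseChannels = 6), "divisible")
  expect_error(forwardDetector(m, array(0, c(60, 60, 3, 1))), "divisible")
})

test_that("parameter count is deterministic for a fixed configuration", {
  m1 <- tinyModel(32, 4, seed = 5)
  m2 <- tinyModel(32, 4, seed = 5)
  expect_equal(m1$nParams, m2$nParams)
  expect_identical(m1$params$stem.W$value, m2$params$stem.W$value)
  m3 <- tinyModel(32, 4, seed = 6)
  expect_equal(m1$nParams, m3$nParams)
  expect_false(identical(m1$params$stem.W$value, m3$params$stem.W$value))
})

test_that("forward passes stay finite over many random inputs", {
  m <- tinyModel(32, 4, seed = 2)
  for (s in 1:100) {
    set.seed(s)
    x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
    h <- forwardDetector(m, x)
    for (l in 1:3) expect_true(all(is.finite(h[[l]]$value)))
  }
})

test_that("channel attention gates without changing shape", {
  set.seed(71)
  eca <- capriDetect:::mkECA(8)
  x <- capriDetect:::tvar(array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2)))
  y <- eca$fwd(NULL, x)
  expect_equal(dim(y$value), dim(x$value))
  # zero input stays zero (multiplicative gate)
  z <- eca$fwd(NULL, capriDetect:::tvar(array(0, c(6, 6, 8, 1))))
  expect_equal(max(abs(z$value)), 0)
  # channel-constant input: each channel scaled by a factor in (0, 1)
  xc <- array(rep(1:8, each = 36), c(6, 6, 8, 1))
  g <- eca$fwd(NULL, capriDetect:::tvar(xc))
  ratio <- g$value[1, 1, , 1] / xc[1, 1, , 1]
  expect_true(all(ratio > 0 & ratio < 1))
  expect_error(capriDetect:::mkECA(8, kernel = 4), "odd")
})

test_that("multi-rate local context preserves shape and validates width", {
  set.seed(73)
  lc <- capriDetect:::mkLocalContext(8)
  x <- capriDetect:::tvar(array(rnorm(12 * 12 * 8), c(12, 12, 8, 1)))
  y <- lc$fwd(NULL, x)
  expect_equal(dim(y$value), c(12, 12, 8, 1))
  expect_error(capriDetect:::mkLocalContext(6), "divisible")
})

test_that("context module sums the branches that are present", {
  set.seed(79)
  cm <- capriDetect:::mkContextModule(8, Ccoarse = 8, Cfine = NULL)
  fCur <- capriDetect:::tvar(array(rnorm(8 * 8 * 8), c(8, 8, 8, 1)))
  fCoarse <- capriDetect:::tvar(array(rnorm(4 * 4 * 8), c(4, 4, 8, 1)))
  out <- cm$fwd(NULL, fCur, fCoarse = fCoarse)
  expect_equal(dim(out$value), c(8, 8, 8, 1))
  # zero inputs propagate to zero (batch-norm beta = 0, SiLU(0) = 0)
  z <- cm$fwd(NULL, capriDetect:::tvar(array(0, c(8, 8, 8, 1))),
              fCoarse = capriDetect:::tvar(array(0, c(4, 4, 8, 1))))
  expect_equal(max(abs(z$value)), 0)
})

test_that("cross-resolution product algebra matches scalar arithmetic", {
  # operator-level trace of the fusion equations on constant maps with
  # the convolutions replaced by identity: f12 = down(f1) * f2,
  # f21 = up(f2) * f1, up-path = f21 * up(f12), down-path = f12 * down(f21)
  a <- 3; b <- 5
  f1 <- capriDetect:::tvar(array(a, c(4, 4, 1, 1)))   # fine, stride s
  f2 <- capriDetect:::tvar(array(b, c(2, 2, 1, 1)))   # coarse, stride 2s
  t <- NULL
  f12 <- capriDetect:::opMul(t, capriDetect:::opDown2(t, f1), f2)
  expect_equal(unique(as.numeric(f12$value)), a * b)
  f21 <- capriDetect:::opMul(t, capriDetect:::opUp2(t, f2), f1)
  expect_equal(unique(as.numeric(f21$value)), a * b)
  up <- capriDetect:::opMul(t, f21, capriDetect:::opUp2(t, f12))
  expect_equal(unique(as.numeric(up$value)), (a * b)^2)
  down <- capriDetect:::opMul(t, f12, capriDetect:::opDown2(t, f21))
  expect_equal(unique(as.numeric(down$value)), (a * b)^2)
  # absolute difference: elementwise, symmetric, nonnegative
  fa <- capriDetect:::tvar(array(3, c(4, 4, 2, 1)))
  fb <- capriDetect:::tvar(array(5, c(4, 4, 2, 1)))
  d1 <- capriDetect:::opAbsDiff(t, fa, fb)
  d2 <- capriDetect:::opAbsDiff(t, fb, fa)
  expect_equal(unique(as.numeric(d1$value)), 2)
  expect_identical(d1$value, d2$value)
  expect_true(all(d1$value >= 0))
  set.seed(83)
  ra <- capriDetect:::tvar(array(rnorm(64), c(4, 4, 4, 1)))
  rb <- capriDetect:::tvar(array(rnorm(64), c(4, 4, 4, 1)))
  expect_true(all(capriDetect:::opAbsDiff(t, ra, rb)$value >= 0))
})

test_that("fusion blocks meet their resolution contracts", {
  set.seed(89)
  x1 <- capriDetect:::tvar(array(rnorm(8 * 8 * 8), c(8, 8, 8, 1)))
  x2 <- capriDetect:::tvar(array(rnorm(4 * 4 * 8), c(4, 4, 8, 1)))
  x3 <- capriDetect:::tvar(array(rnorm(2 * 2 * 8), c(2, 2, 8, 1)))
  upB <- capriDetect:::mkFCMBlock(8, 8, 8, 8, "up")
  dnB <- capriDetect:::mkFCMBlock(8, 8, 8, 8, "down")
  expect_equal(dim(upB$fwd(NULL, x1, x2, x3)$value), c(8, 8, 8, 1))
  expect_equal(dim(dnB$fwd(NULL, x1, x2, x3)$value), c(2, 2, 8, 1))
  z1 <- capriDetect:::tvar(array(0, c(8, 8, 8, 1)))
  z2 <- capriDetect:::tvar(array(0, c(4, 4, 8, 1)))
  z3 <- capriDetect:::tvar(array(0, c(2, 2, 8, 1)))
  expect_equal(max(abs(upB$fwd(NULL, z1, z2, z3)$value)), 0)
  pair <- capriDetect:::mkFCMPair(8)
  po <- pair$fwd(NULL, x1, x2)
  expect_equal(dim(po$up$value), c(8, 8, 8, 1))
  expect_equal(dim(po$down$value), c(4, 4, 8, 1))
})

test_that("pyramid pooling block preserves resolution deterministically", {
  set.seed(97)
  spp1 <- capriDetect:::mkSPPCSPC(16, 16)
  x <- array(rnorm(8 * 8 * 16), c(8, 8, 16, 1))
  y1 <- spp1$fwd(NULL, capriDetect:::tvar(x))
  expect_equal(dim(y1$value), c(8, 8, 16, 1))
  y2 <- spp1$fwd(NULL, capriDetect:::tvar(x))
  expect_identical(y1$value, y2$value)
  # stride-1 same-padded max pooling of a constant map is the constant
  cst <- capriDetect:::tvar(array(2, c(8, 8, 4, 1)))
  mp <- capriDetect:::opMaxPoolSame(NULL, cst, 5)
  expect_equal(unique(as.numeric(mp$value)), 2)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(101)
  cfg <- modelConfig(inputSize = 32, baseChannels = 4)
  m <- buildDetector(cfg, seed = 3)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  lossOf <- function() {
    h <- forwardDetector(m, x, training = TRUE)
    sum(vapply(h, function(t) sum(t$value^2), 0))
  }
  tape <- capriDetect:::newTape()
  h <- forwardDetector(m, x, training = TRUE, tape = tape)
  seeds <- lapply(h, function(t) list(tensor = t, grad = 2 * t$value))
  capriDetect:::zeroGrads(m$params)
  capriDetect:::backprop(tape, seeds)
  snap <- lapply(m$states, function(s) list(rm = s$runMean, rv = s$runVar))
  reset <- function() for (nm in names(m$states)) {
    m$states[[nm]]$runMean <- snap[[nm]]$rm
    m$states[[nm]]$runVar <- snap[[nm]]$rv
  }
  checked <- 0
  for (nm in c("stem.W", "ctx4.local.b2.W", "fcmUp.p12.cv3.W",
               "ctx4.coarseEca.w", "head3.W", "d3.gamma", "spp.cv7.b")) {
    p <- m$params[[nm]]
    i <- which.max(abs(p$grad))
    h0 <- 1e-5
    v0 <- p$value[i]
    p$value[i] <- v0 + h0; reset(); f1 <- lossOf()
    p$value[i] <- v0 - h0; reset(); f2 <- lossOf()
    p$value[i] <- v0
    fd <- (f1 - f2) / (2 * h0)
    expect_equal(p$grad[i], fd, tolerance = 1e-3)
    checked <- checked + 1
  }
  expect_equal(checked, 7)
})

test_that("prediction decoding inverts the cell arithmetic and suppresses", {
  cfg <- modelConfig(inputSize = 64)
  anchors <- defaultSmallTargetAnchors()
  per <- 6
  heads <- list(array(-20, c(8, 8, 18, 1)), array(-20, c(4, 4, 18, 1)),
                array(-20, c(2, 2, 18, 1)))
  expect_equal(nrow(decodePredictions(heads, anchors, cfg,
                                      confThresh = 0.25)), 0)
  # one hot cell on level 1, anchor 2, cell (gi = 3, gj = 5)
  heads[[1]][6, 4, per + 1:4, 1] <- 0          # sigmoid 0.5
  heads[[1]][6, 4, per + 5, 1] <- 10           # objectness ~ 1
  heads[[1]][6, 4, per + 6, 1] <- 10           # class ~ 1
  dd <- decodePredictions(heads, anchors, cfg, confThresh = 0.5)
  expect_equal(nrow(dd), 1)
  expect_equal(dd$cx, (2 * 0.5 - 0.5 + 3) * 8)  # 28
  expect_equal(dd$cy, (2 * 0.5 - 0.5 + 5) * 8)  # 44
  expect_equal(dd$w, (2 * 0.5)^2 * 12)
  expect_equal(dd$h, (2 * 0.5)^2 * 16)
  # a duplicate at lower score is suppressed by NMS
  heads[[1]][6, 4, 1:4, 1] <- 0                # anchor 1 same cell
  heads[[1]][6, 4, 5, 1] <- 2
  heads[[1]][6, 4, 6, 1] <- 10
  dd2 <- decodePredictions(heads, anchors, cfg, confThresh = 0.2,
                           nmsIoU = 0.2)
  expect_equal(nrow(dd2), 1)
  expect_gt(dd2$score, 0.9)
})
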