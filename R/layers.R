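# Network building blocks. A block is a list(params = <named parameter
# tensors>, states = <named batch-norm state environments>, fwd =
# function(tape, ..., training)); buildDetector() composes blocks and
# flattens parameters/states for the optimizer and for checkpoints.
# Convolution blocks are conv + batch normalization + SiLU unless noted
# bare (YOLO convention).

.kaiming <- function(fanIn, n) stats::rnorm(n, 0, sqrt(2 / fanIn))

# Merge child modules' parameter/state maps under name prefixes.
.mergeKids <- function(kids) {
  params <- list(); states <- list()
  for (m in names(kids)) {
    kid <- kids[[m]]
    if (is.null(kid)) next
    for (nm in names(kid$params))
      params[[paste0(m, ".", nm)]] <- kid$params[[nm]]
    for (nm in names(kid$states))
      states[[paste0(m, ".", nm)]] <- kid$states[[nm]]
  }
  list(params = params, states = states)
}

mkConv <- function(Cin, Cout, k = 1, stride = 1, dil = 1,
                   bn = TRUE, act = TRUE) {
  pad <- dil * (k - 1) %/% 2
  W <- tvar(matrix(.kaiming(k * k * Cin, Cout * k * k * Cin),
                   nrow = Cout))
  b <- tvar(numeric(Cout)); b$noDecay <- TRUE
  params <- list(W = W, b = b)
  states <- list()
  state <- NULL
  if (bn) {
    g <- tvar(rep(1, Cout)); g$noDecay <- TRUE
    be <- tvar(numeric(Cout)); be$noDecay <- TRUE
    params$gamma <- g; params$beta <- be
    state <- new.env(parent = emptyenv())
    state$runMean <- numeric(Cout)
    state$runVar <- rep(1, Cout)
    states$bn <- state
  }
  list(params = params, states = states,
       fwd = function(tape, x, training = TRUE) {
         y <- opConv(tape, x, W, b, k, k, stride = stride, pad = pad,
                     dil = dil)
         if (bn) y <- opBatchNorm(tape, y, params$gamma, params$beta,
                                  state, training)
         if (act) y <- opSiLU(tape, y)
         y
       })
}

# Efficient channel attention: global average pool -> 1-D cross-channel
# conv -> sigmoid gate. Adaptive kernel: nearest odd to log2(C)/2 + 1/2.
.ecaKernelSize <- function(C) {
  k <- round(abs(log2(C) / 2 + 0.5))
  if (k %% 2 == 0) k <- k + 1
  max(k, 3)
}

mkECA <- function(C, kernel = "adaptive") {
  k <- if (identical(kernel, "adaptive")) .ecaKernelSize(C) else kernel
  if (k %% 2 == 0) stop("ECA kernel must be odd")
  w <- tvar(stats::rnorm(k, 0, 0.1)); w$noDecay <- TRUE
  list(params = list(w = w), states = list(),
       fwd = function(tape, x, training = TRUE) {
         s <- opGlobalAvgPool(tape, x)
         s <- opConv1dChannels(tape, s, w)
         gate <- opSigmoidMat(tape, s)
         opScaleChannels(tape, x, gate)
       })
}

# Multi-rate local context: four parallel 3x3 dilated convolutions
# (rates 1..4, padding = rate, C/4 channels each), concatenated back to C.
mkLocalContext <- function(C) {
  if (C %% 4 != 0) stop("local context requires channels divisible by 4")
  branches <- lapply(1:4, function(r) mkConv(C, C %/% 4, k = 3, dil = r))
  names(branches) <- paste0("b", 1:4)
  mk <- .mergeKids(branches)
  list(params = mk$params, states = mk$states,
       fwd = function(tape, x, training = TRUE) {
         opConcatC(tape, lapply(branches, function(br)
           br$fwd(tape, x, training)))
       })
}

# Context module for one pyramid level: local multi-rate context on the
# current level plus attention-gated interaction with the adjacent
# levels, summed. Either neighbor may be absent (pyramid ends), giving
# the reduced variant used at the pyramid extremes.
mkContextModule <- function(Ccur, Ccoarse = NULL, Cfine = NULL,
                            ecaKernel = "adaptive") {
  kids <- list(local = mkLocalContext(Ccur))
  if (!is.null(Ccoarse)) {
    kids$coarseEca <- mkECA(Ccoarse, ecaKernel)
    kids$coarseConv <- mkConv(Ccoarse, Ccur, k = 1)
  }
  if (!is.null(Cfine)) {
    kids$fineEca <- mkECA(Cfine, ecaKernel)
    kids$fineConv <- mkConv(Cfine, Ccur, k = 1)
  }
  mk <- .mergeKids(kids)
  list(params = mk$params, states = mk$states,
       fwd = function(tape, fCur, fCoarse = NULL, fFine = NULL,
                      training = TRUE) {
         parts <- list(kids$local$fwd(tape, fCur, training))
         if (!is.null(fCoarse)) {
           a <- opUp2(tape, fCoarse)
           a <- kids$coarseEca$fwd(tape, a, training)
           parts <- c(parts, list(kids$coarseConv$fwd(tape, a, training)))
         }
         if (!is.null(fFine)) {
           cc <- opDown2(tape, fFine)
           cc <- kids$fineEca$fwd(tape, cc, training)
           parts <- c(parts, list(kids$fineConv$fwd(tape, cc, training)))
         }
         opAdd(tape, parts)
       })
}

# Feature-complementary pair over (fHi, fLo) with equal channels C
# (fLo at twice the stride). Cross-resolution products:
#   f12 = Conv(down(fHi)) * Conv(fLo)          (low resolution)
#   f21 = Conv(up(fLo))   * Conv(fHi)          (high resolution)
#   up path   = Conv(f21) * Conv(up(f12))      (high resolution)
#   down path = Conv(f12) * Conv(down(f21))    (low resolution)
mkFCMPair <- function(C) {
  cv <- lapply(1:8, function(i) mkConv(C, C, k = 3))
  names(cv) <- paste0("cv", 1:8)
  mk <- .mergeKids(cv)
  list(params = mk$params, states = mk$states,
       fwd = function(tape, fHi, fLo, training = TRUE) {
         f12 <- opMul(tape, cv$cv1$fwd(tape, opDown2(tape, fHi), training),
                      cv$cv2$fwd(tape, fLo, training))
         f21 <- opMul(tape, cv$cv3$fwd(tape, opUp2(tape, fLo), training),
                      cv$cv4$fwd(tape, fHi, training))
         upOut <- opMul(tape, cv$cv5$fwd(tape, f21, training),
                        cv$cv6$fwd(tape, opUp2(tape, f12), training))
         downOut <- opMul(tape, cv$cv7$fwd(tape, f12, training),
                          cv$cv8$fwd(tape, opDown2(tape, f21), training))
         list(up = upOut, down = downOut)
       })
}

# Full feature-complementary block over the three pyramid levels.
# Inputs are aligned to a common channel count by dilated convolutions
# with kernels 3/5/7; the (x1,x2) and (x2,x3) pairs each produce an
# up-path and down-path output whose absolute difference suppresses
# shared background; the two difference maps are resampled to the target
# stride (finest for direction "up", coarsest for "down"), concatenated
# and reduced by a 1x1 convolution.
mkFCMBlock <- function(C1, C2, C3, C, direction = c("up", "down")) {
  direction <- match.arg(direction)
  kids <- list(a1 = mkConv(C1, C, k = 3),
               a2 = mkConv(C2, C, k = 5),
               a3 = mkConv(C3, C, k = 7),
               p12 = mkFCMPair(C),
               p23 = mkFCMPair(C),
               red = mkConv(2 * C, C, k = 1))
  mk <- .mergeKids(kids)
  list(params = mk$params, states = mk$states,
       fwd = function(tape, x1, x2, x3, training = TRUE) {
         a1 <- kids$a1$fwd(tape, x1, training)
         a2 <- kids$a2$fwd(tape, x2, training)
         a3 <- kids$a3$fwd(tape, x3, training)
         o12 <- kids$p12$fwd(tape, a1, a2, training)
         o23 <- kids$p23$fwd(tape, a2, a3, training)
         # differences at the finer stride of each pair
         d1 <- opAbsDiff(tape, o12$up, opUp2(tape, o12$down))
         d2 <- opAbsDiff(tape, o23$up, opUp2(tape, o23$down))
         if (direction == "up") {
           d2 <- opUp2(tape, d2)                     # stride 16 -> 8
         } else {
           d1 <- opDown2(tape, opDown2(tape, d1))    # stride 8 -> 32
           d2 <- opDown2(tape, d2)                   # stride 16 -> 32
         }
         kids$red$fwd(tape, opConcatC(tape, list(d1, d2)), training)
       })
}

# Spatial pyramid pooling inside a cross-stage-partial split: one branch
# is pooled at kernels 5/9/13 (stride 1, same padding) and fused, the
# other bypasses; halves are concatenated and reduced.
mkSPPCSPC <- function(Cin, Cout) {
  ch <- max(Cout %/% 2, 4)
  kids <- list(cv1 = mkConv(Cin, ch, k = 1),
               cv2 = mkConv(Cin, ch, k = 1),
               cv5 = mkConv(4 * ch, ch, k = 1),
               cv6 = mkConv(ch, ch, k = 3),
               cv7 = mkConv(2 * ch, Cout, k = 1))
  mk <- .mergeKids(kids)
  list(params = mk$params, states = mk$states,
       fwd = function(tape, x, training = TRUE) {
         a <- kids$cv1$fwd(tape, x, training)
         pools <- opConcatC(tape, list(a,
                                       opMaxPoolSame(tape, a, 5),
                                       opMaxPoolSame(tape, a, 9),
                                       opMaxPoolSame(tape, a, 13)))
         a <- kids$cv6$fwd(tape, kids$cv5$fwd(tape, pools, training),
                           training)
         b <- kids$cv2$fwd(tape, x, training)
         kids$cv7$fwd(tape, opConcatC(tape, list(a, b)), training)
       })
}

# Cross-stage-partial residual block at constant channels.
mkCSP <- function(C) {
  ch <- C %/% 2
  kids <- list(cv1 = mkConv(C, ch, k = 1),
               cv2 = mkConv(C, ch, k = 1),
               cv3 = mkConv(ch, ch, k = 3),
               cv4 = mkConv(2 * ch, C, k = 1))
  mk <- .mergeKids(kids)
  list(params = mk$params, states = mk$states,
       fwd = function(tape, x, training = TRUE) {
         a <- kids$cv1$fwd(tape, x, training)
         a <- opAdd(tape, list(a, kids$cv3$fwd(tape, a, training)))
         b <- kids$cv2$fwd(tape, x, training)
         kids$cv4$fwd(tape, opConcatC(tape, list(a, b)), training)
       })
}
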