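# Minimal reverse-mode tensor engine backing the detection network.
# Tensors are environments holding a (H, W, C, N) array (or a (C, N)
# matrix for pooled channel descriptors); every operation records an
# adjoint closure on a tape, and backprop() replays the tape in reverse.
# Deliberately small: only the operations the network needs exist.

newTape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t
}

tvar <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e
}

.record <- function(tape, out, backfn) {
  if (!is.null(tape)) tape$nodes[[length(tape$nodes) + 1L]] <-
      list(out = out, backfn = backfn)
  out
}

.accGrad <- function(t, g) {
  if (is.null(t$grad)) t$grad <- g else t$grad <- t$grad + g
  invisible(NULL)
}

# Seed output gradients (named list of tensor/grad pairs) and walk the
# tape backwards, accumulating into every upstream tensor's $grad.
backprop <- function(tape, seeds) {
  for (s in seeds) .accGrad(s$tensor, s$grad)
  for (i in rev(seq_along(tape$nodes))) {
    node <- tape$nodes[[i]]
    if (!is.null(node$out$grad)) node$backfn(node$out$grad)
  }
  invisible(NULL)
}

.dims <- function(x) {
  d <- dim(x$value)
  if (length(d) == 4) d else c(d, 1L, 1L)[1:4]
}

# ---- elementwise ----

opAdd <- function(tape, xs) {
  out <- tvar(Reduce(`+`, lapply(xs, function(x) x$value)))
  .record(tape, out, function(g) for (x in xs) .accGrad(x, g))
}

opMul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  out <- tvar(av * bv)
  .record(tape, out, function(g) {
    .accGrad(a, g * bv)
    .accGrad(b, g * av)
  })
}

opAbsDiff <- function(tape, a, b) {
  d <- a$value - b$value
  out <- tvar(abs(d))
  sgn <- sign(d)   # subgradient 0 at ties
  .record(tape, out, function(g) {
    .accGrad(a, g * sgn)
    .accGrad(b, -g * sgn)
  })
}

opSiLU <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  out <- tvar(x$value * s)
  .record(tape, out, function(g)
    .accGrad(x, g * (s * (1 + x$value * (1 - s)))))
}

opSigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  out <- tvar(s)
  .record(tape, out, function(g) .accGrad(x, g * s * (1 - s)))
}

# ---- shape ops ----

opConcatC <- function(tape, xs) {
  ds <- lapply(xs, function(x) dim(x$value))
  C <- sum(vapply(ds, function(d) d[3], 0))
  d1 <- ds[[1]]
  out <- array(0, c(d1[1], d1[2], C, d1[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x$value)[3]
    out[, , at + seq_len(cc), ] <- x$value
    at <- at + cc
  }
  o <- tvar(out)
  .record(tape, o, function(g) {
    at <- 0L
    for (x in xs) {
      cc <- dim(x$value)[3]
      .accGrad(x, g[, , at + seq_len(cc), , drop = FALSE])
      at <- at + cc
    }
  })
}

opSliceC <- function(tape, x, idx) {
  out <- tvar(x$value[, , idx, , drop = FALSE])
  d <- dim(x$value)
  .record(tape, out, function(g) {
    gx <- array(0, d)
    gx[, , idx, ] <- g
    .accGrad(x, gx)
  })
}

# ---- resampling ----

opUp2 <- function(tape, x) {
  d <- dim(x$value)
  out <- tvar(bilinear2x_cpp(x$value, d[1], d[2], d[3], d[4]))
  .record(tape, out, function(g)
    .accGrad(x, bilinear2x_grad_cpp(g, d[1], d[2], d[3], d[4])))
}

opDown2 <- function(tape, x) {
  d <- dim(x$value)
  out <- tvar(avgpool2x_cpp(x$value, d[1], d[2], d[3], d[4]))
  .record(tape, out, function(g)
    .accGrad(x, avgpool2x_grad_cpp(g, d[1], d[2], d[3], d[4])))
}

opMaxPoolSame <- function(tape, x, k) {
  d <- dim(x$value)
  r <- maxpool_same_cpp(x$value, d[1], d[2], d[3], d[4], as.integer(k))
  out <- tvar(r$value)
  .record(tape, out, function(g)
    .accGrad(x, maxpool_same_grad_cpp(g, r$argmax, d[1], d[2], d[3], d[4])))
}

# ---- convolution ----

# Parameters: W is (Cout x KH*KW*Cin) with rows ordered (kh, kw, c);
# b is length Cout. Records adjoints for x, W and b.
opConv <- function(tape, x, Wt, bt, KH, KW, stride = 1, pad = 0, dil = 1) {
  d <- dim(x$value)
  Cin <- d[3]; N <- d[4]
  cols <- im2col_cpp(x$value, d[1], d[2], Cin, N, KH, KW,
                     stride, stride, pad, pad, dil, dil)
  Hout <- (d[1] + 2 * pad - dil * (KH - 1) - 1) %/% stride + 1
  Wout <- (d[2] + 2 * pad - dil * (KW - 1) - 1) %/% stride + 1
  Cout <- nrow(Wt$value)
  Y <- Wt$value %*% cols + bt$value
  out <- tvar(aperm(array(Y, c(Cout, Hout, Wout, N)), c(2, 3, 1, 4)))
  .record(tape, out, function(g) {
    GY <- matrix(aperm(g, c(3, 1, 2, 4)), nrow = Cout)
    .accGrad(Wt, GY %*% t(cols))
    .accGrad(bt, rowSums(GY))
    dcols <- crossprod(Wt$value, GY)
    .accGrad(x, col2im_cpp(dcols, d[1], d[2], Cin, N, KH, KW,
                           stride, stride, pad, pad, dil, dil))
  })
}

# ---- batch normalization ----

# Per-channel statistics over (H, W, N). state holds running moments for
# inference mode; momentum 0.1, eps 1e-5.
opBatchNorm <- function(tape, x, gamma, beta, state, training = TRUE) {
  d <- dim(x$value)
  C <- d[3]; m <- d[1] * d[2] * d[4]
  eps <- 1e-5
  xm <- matrix(aperm(x$value, c(1, 2, 4, 3)), ncol = C)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    state$runMean <- 0.9 * state$runMean + 0.1 * mu
    state$runVar <- 0.9 * state$runVar + 0.1 * va * m / max(m - 1, 1)
  } else {
    mu <- state$runMean
    va <- state$runVar
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, `*`)
  ym <- sweep(sweep(xhat, 2, gamma$value, `*`), 2, beta$value, `+`)
  out <- tvar(aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3)))
  .record(tape, out, function(g) {
    gm <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = C)
    .accGrad(gamma, colSums(gm * xhat))
    .accGrad(beta, colSums(gm))
    gxh <- sweep(gm, 2, gamma$value, `*`)
    if (training) {
      t1 <- sweep(gxh, 2, colMeans(gxh))
      t2 <- sweep(xhat, 2, colMeans(gxh * xhat), `*`)
      gx <- sweep(t1 - t2, 2, istd, `*`)
    } else {
      gx <- sweep(gxh, 2, istd, `*`)
    }
    .accGrad(x, aperm(array(gx, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3)))
  })
}

# ---- channel attention plumbing ----

opGlobalAvgPool <- function(tape, x) {
  d <- dim(x$value)
  out <- tvar(apply(x$value, c(3, 4), mean))
  .record(tape, out, function(g) {
    gx <- aperm(array(rep(as.numeric(g), each = d[1] * d[2]) / (d[1] * d[2]),
                      c(d[1], d[2], d[3], d[4])), c(1, 2, 3, 4))
    .accGrad(x, gx)
  })
}

# 1-D convolution across the channel axis of a (C, N) descriptor with a
# zero-padded odd kernel; weight wt is a length-k tensor.
opConv1dChannels <- function(tape, s, wt) {
  k <- length(wt$value)
  p <- k %/% 2
  C <- nrow(s$value); N <- ncol(s$value)
  sp <- rbind(matrix(0, p, N), s$value, matrix(0, p, N))
  out <- matrix(0, C, N)
  for (j in seq_len(k))
    out <- out + wt$value[j] * sp[(j - 1) + seq_len(C), , drop = FALSE]
  o <- tvar(out)
  .record(tape, o, function(g) {
    gw <- numeric(k)
    for (j in seq_len(k))
      gw[j] <- sum(g * sp[(j - 1) + seq_len(C), , drop = FALSE])
    .accGrad(wt, gw)
    gp <- matrix(0, C + 2 * p, N)
    for (j in seq_len(k))
      gp[(j - 1) + seq_len(C), ] <- gp[(j - 1) + seq_len(C), ] +
        wt$value[j] * g
    .accGrad(s, gp[p + seq_len(C), , drop = FALSE])
  })
}

opSigmoidMat <- function(tape, s) {
  v <- 1 / (1 + exp(-s$value))
  out <- tvar(v)
  .record(tape, out, function(g) .accGrad(s, g * v * (1 - v)))
}

# Multiply each channel of x by gate (C, N).
opScaleChannels <- function(tape, x, gate) {
  d <- dim(x$value)
  gfull <- aperm(array(rep(as.numeric(gate$value), each = d[1] * d[2]),
                       c(d[1], d[2], d[3], d[4])), c(1, 2, 3, 4))
  out <- tvar(x$value * gfull)
  .record(tape, out, function(g) {
    .accGrad(x, g * gfull)
    .accGrad(gate, apply(g * x$value, c(3, 4), sum))
  })
}

# ---- optimizer ----

# Decoupled weight decay Adam. params: flat named list of parameter
# tensors; state persists first/second moments per parameter.
adamwStep <- function(params, state, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weightDecay = 0.01) {
  state$t <- (state$t %||% 0) + 1
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- p$grad * 0
      state$v[[nm]] <- p$grad * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * p$grad
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * p$grad^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    decay <- if (isTRUE(p$noDecay)) 0 else weightDecay
    p$value <- p$value - lr * (mh / (sqrt(vh) + eps) + decay * p$value)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zeroGrads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
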