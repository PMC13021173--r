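# Minimal reverse-mode automatic differentiation over dense arrays.
#
# The model family here (pointwise and depthwise convolutions on
# (batch, channel, height, width) grids, pooled attention, small dense
# heads) needs exact gradients for Adam training; this tape provides them.
# Nodes are environments holding a value, parent links and a backward
# closure; adBackward() walks the tape in reverse creation order. All public
# forward operations in the package call these ops and read `$value`, so
# forward behaviour and training share one code path.
#
# Conventions: grids are arrays dim (B, C, H, W); dense activations are
# matrices (B, D). Convolution kernels are (Cout, Cin, kw) for channel-mixing
# 1-D convolutions along W and (C, kh, kw) for depthwise 2-D convolutions;
# odd kernel sizes with zero padding preserve spatial dims.

adTape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

adNode <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$grad <- NULL
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

adConst <- function(tape, value) adNode(tape, value)

adBackward <- function(tape, root) {
  root$grad <- array(1, dim = if (is.null(dim(root$value))) length(root$value) else dim(root$value))
  if (length(root$value) == 1L) root$grad <- 1
  for (i in seq(root$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(NULL)
}

# ---- elementwise ----

adAdd <- function(tape, a, b)
  adNode(tape, a$value + b$value, list(a, b), function(g) list(g, g))

adSub <- function(tape, a, b)
  adNode(tape, a$value - b$value, list(a, b), function(g) list(g, -g))

adMul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  adNode(tape, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

adScale <- function(tape, a, k)
  adNode(tape, a$value * k, list(a), function(g) list(g * k))

adAddConst <- function(tape, a, k)
  adNode(tape, a$value + k, list(a), function(g) list(g))

adGelu <- function(tape, a) {
  x <- a$value
  adNode(tape, x * stats::pnorm(x), list(a),
         function(g) list(g * (stats::pnorm(x) + x * stats::dnorm(x))))
}

adRelu <- function(tape, a) {
  x <- a$value
  adNode(tape, pmax(x, 0) * 1, list(a), function(g) list(g * (x > 0)))
}

adSigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  adNode(tape, s, list(a), function(g) list(g * s * (1 - s)))
}

# ---- dense ----

adMatmul <- function(tape, A, B) {
  Av <- A$value; Bv <- B$value
  adNode(tape, Av %*% Bv, list(A, B),
         function(g) list(g %*% t(Bv), t(Av) %*% g))
}

adBiasRow <- function(tape, X, b) {
  adNode(tape, sweep(X$value, 2, b$value, "+"), list(X, b),
         function(g) list(g, colSums(g)))
}

adLinear <- function(tape, X, W, b) {
  z <- adMatmul(tape, X, W)
  if (is.null(b)) z else adBiasRow(tape, z, b)
}

adRows <- function(tape, Emb, idx) {
  Ev <- Emb$value
  adNode(tape, Ev[idx, , drop = FALSE], list(Emb), function(g) {
    dE <- array(0, dim(Ev))
    for (i in seq_along(idx)) dE[idx[i], ] <- dE[idx[i], ] + g[i, ]
    list(dE)
  })
}

adReshape <- function(tape, x, dims) {
  old <- dim(x$value)
  v <- x$value; dim(v) <- dims
  adNode(tape, v, list(x), function(g) { dim(g) <- old; list(g) })
}

# ---- convolutions on (B, C, H, W) grids ----

shiftW <- function(X, s) {
  # return X shifted so out[..., w] = X[..., w + s], zero beyond edges
  d <- dim(X); W <- d[4]
  out <- array(0, d)
  src <- (1:W) + s
  ok <- src >= 1 & src <= W
  if (any(ok)) out[, , , which(ok)] <- X[, , , src[ok], drop = FALSE]
  out
}

shiftHW <- function(X, sh, sw) {
  d <- dim(X); H <- d[3]; W <- d[4]
  out <- array(0, d)
  sh_src <- (1:H) + sh; sw_src <- (1:W) + sw
  okh <- sh_src >= 1 & sh_src <= H; okw <- sw_src >= 1 & sw_src <= W
  if (any(okh) && any(okw))
    out[, , which(okh), which(okw)] <- X[, , sh_src[okh], sw_src[okw], drop = FALSE]
  out
}

# Column index of the (b,h,w) blocks for a channel-major matrix view of a
# (B,C,H,W) array: block w spans columns (w-1)*B*H + 1 .. w*B*H.
.wBlockCols <- function(ws, BH) {
  if (!length(ws)) return(integer(0))
  as.vector(outer(seq_len(BH), (ws - 1L) * BH, "+"))
}

convWRaw <- function(X, K, Xm = NULL) {
  # channel-mixing conv along W; K (O, Cin, kw), zero pad same. The input
  # is permuted to a (C, B*H*W) matrix once; taps act as shifted-column
  # matrix products.
  d <- dim(X); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  kw <- dim(K)[3]; O <- dim(K)[1]; off <- (kw - 1) %/% 2
  BH <- B * H
  if (is.null(Xm)) Xm <- matrix(aperm(X, c(2, 1, 3, 4)), nrow = C)
  Ym <- matrix(0, O, BH * W)
  for (tap in seq_len(kw)) {
    s <- tap - 1L - off
    lo <- max(1L, 1L - s); hi <- min(W, W - s)
    if (lo > hi) next
    Kt <- matrix(K[, , tap], nrow = O)
    if (s == 0L) {
      Ym <- Ym + Kt %*% Xm
    } else {
      cy <- .wBlockCols(lo:hi, BH); cx <- .wBlockCols((lo:hi) + s, BH)
      Ym[, cy] <- Ym[, cy] + Kt %*% Xm[, cx, drop = FALSE]
    }
  }
  aperm(array(Ym, c(O, B, H, W)), c(2, 1, 3, 4))
}

adConvW <- function(tape, x, K, bias = NULL) {
  Xv <- x$value; Kv <- K$value
  d <- dim(Xv); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  kw <- dim(Kv)[3]; O <- dim(Kv)[1]; off <- (kw - 1) %/% 2
  BH <- B * H
  Xm <- matrix(aperm(Xv, c(2, 1, 3, 4)), nrow = C)
  out <- convWRaw(Xv, Kv, Xm)
  if (!is.null(bias)) out <- out + rep(bias$value, each = B)
  parents <- if (is.null(bias)) list(x, K) else list(x, K, bias)
  adNode(tape, out, parents, function(g) {
    # dX: correlate g with the transposed, tap-reversed kernel
    Kt <- array(0, c(C, O, kw))
    for (tap in seq_len(kw))
      Kt[, , tap] <- t(matrix(Kv[, , kw + 1L - tap], nrow = O))
    Gm <- matrix(aperm(g, c(2, 1, 3, 4)), nrow = O)
    dX <- convWRaw(g, Kt, Gm)
    dK <- array(0, dim(Kv))
    for (tap in seq_len(kw)) {
      s <- tap - 1L - off
      lo <- max(1L, 1L - s); hi <- min(W, W - s)
      if (lo > hi) next
      if (s == 0L) {
        dK[, , tap] <- Gm %*% t(Xm)
      } else {
        cy <- .wBlockCols(lo:hi, BH); cx <- .wBlockCols((lo:hi) + s, BH)
        dK[, , tap] <- Gm[, cy, drop = FALSE] %*% t(Xm[, cx, drop = FALSE])
      }
    }
    res <- list(dX, dK)
    if (!is.null(bias)) res <- c(res, list(rowSums(Gm)))
    res
  })
}

dwConvRaw <- function(X, K) {
  # depthwise conv; K (C, kh, kw), zero pad same
  d <- dim(X); B <- d[1]; C <- d[2]
  kh <- dim(K)[2]; kw <- dim(K)[3]
  offh <- (kh - 1) %/% 2; offw <- (kw - 1) %/% 2
  out <- array(0, d)
  for (dy in seq_len(kh)) for (dx in seq_len(kw)) {
    kc <- K[, dy, dx]
    if (all(kc == 0)) next
    Xs <- shiftHW(X, dy - 1L - offh, dx - 1L - offw)
    out <- out + Xs * rep(kc, each = B)
  }
  out
}

adDWConv <- function(tape, x, K, bias = NULL) {
  Xv <- x$value; Kv <- K$value
  d <- dim(Xv); B <- d[1]; C <- d[2]
  kh <- dim(Kv)[2]; kw <- dim(Kv)[3]
  offh <- (kh - 1) %/% 2; offw <- (kw - 1) %/% 2
  out <- dwConvRaw(Xv, Kv)
  if (!is.null(bias)) out <- out + rep(bias$value, each = B)
  parents <- if (is.null(bias)) list(x, K) else list(x, K, bias)
  adNode(tape, out, parents, function(g) {
    Kf <- Kv[, rev(seq_len(kh)), rev(seq_len(kw)), drop = FALSE]
    dim(Kf) <- dim(Kv)
    dX <- dwConvRaw(g, Kf)
    dK <- array(0, dim(Kv))
    for (dy in seq_len(kh)) for (dx in seq_len(kw)) {
      Xs <- shiftHW(Xv, dy - 1L - offh, dx - 1L - offw)
      m <- matrix(aperm(Xs * g, c(2, 1, 3, 4)), nrow = C)
      dK[, dy, dx] <- rowSums(m)
    }
    res <- list(dX, dK)
    if (!is.null(bias))
      res <- c(res, list(rowSums(matrix(aperm(g, c(2, 1, 3, 4)), nrow = C))))
    res
  })
}

# ---- pooling and broadcasts ----

poolMat <- function(X) {
  d <- dim(X)
  matrix(X, nrow = d[1] * d[2])   # rows index (b, c); cols index (h, w)
}

adPoolSpat <- function(tape, x, type = c("mean", "max", "median")) {
  type <- match.arg(type)
  Xv <- x$value; d <- dim(Xv)
  B <- d[1]; C <- d[2]; S <- d[3] * d[4]
  m <- poolMat(Xv)
  if (type == "mean") {
    v <- matrix(rowMeans(m), B, C)
    return(adNode(tape, v, list(x), function(g) {
      list(array(rep(as.vector(g) / S, S), d))
    }))
  }
  if (type == "max") {
    idx <- max.col(m, ties.method = "first")
    v <- matrix(m[cbind(seq_len(B * C), idx)], B, C)
    return(adNode(tape, v, list(x), function(g) {
      z <- matrix(0, B * C, S)
      z[cbind(seq_len(B * C), idx)] <- as.vector(g)
      list(array(z, d))
    }))
  }
  # lower median (deterministic tie-break for even counts)
  k <- (S + 1L) %/% 2L
  med <- numeric(B * C); idx <- integer(B * C)
  for (i in seq_len(B * C)) {
    r <- m[i, ]
    med[i] <- sort(r, partial = k)[k]
    idx[i] <- which(r == med[i])[1]
  }
  adNode(tape, matrix(med, B, C), list(x), function(g) {
    z <- matrix(0, B * C, S)
    z[cbind(seq_len(B * C), idx)] <- as.vector(g)
    list(array(z, d))
  })
}

adChanScale <- function(tape, x, a) {
  # x (B,C,H,W) * a (B,C), broadcast over spatial positions
  Xv <- x$value; Av <- a$value; d <- dim(Xv)
  av <- as.vector(Av)
  adNode(tape, Xv * av, list(x, a), function(g) {
    ga <- matrix(rowSums(poolMat(g * Xv)), d[1], d[2])
    list(g * av, ga)
  })
}

adChanAdd <- function(tape, x, a) {
  Xv <- x$value; Av <- a$value; d <- dim(Xv)
  adNode(tape, Xv + as.vector(Av), list(x, a), function(g) {
    list(g, matrix(rowSums(poolMat(g)), d[1], d[2]))
  })
}

expandChan <- function(s, C) {
  # s (B,1,H,W) -> (B,C,H,W)
  d <- dim(s)
  out <- array(0, c(d[1], C, d[3], d[4]))
  for (c in seq_len(C)) out[, c, , ] <- s[, 1, , ]
  out
}

sumOverChan <- function(g) {
  # (B,C,H,W) -> (B,1,H,W) by summing channels
  d <- dim(g)
  m <- matrix(aperm(g, c(2, 1, 3, 4)), nrow = d[2])
  array(colSums(m), c(d[1], 1, d[3], d[4]))
}

adSpatScale <- function(tape, x, s) {
  # x (B,C,H,W) * s (B,1,H,W), broadcast over channels
  Xv <- x$value; Sv <- s$value; C <- dim(Xv)[2]
  Se <- expandChan(Sv, C)
  adNode(tape, Xv * Se, list(x, s), function(g) {
    list(g * Se, sumOverChan(g * Xv))
  })
}

adChanMean <- function(tape, x) {
  Xv <- x$value; d <- dim(Xv); C <- d[2]
  m <- matrix(aperm(Xv, c(2, 1, 3, 4)), nrow = C)
  v <- array(colMeans(m), c(d[1], 1, d[3], d[4]))
  adNode(tape, v, list(x), function(g) list(expandChan(g, C) / C))
}

adChanMax <- function(tape, x) {
  Xv <- x$value; d <- dim(Xv); C <- d[2]
  m <- matrix(aperm(Xv, c(2, 1, 3, 4)), nrow = C)   # C x (B*H*W)
  idx <- max.col(t(m), ties.method = "first")
  v <- array(m[cbind(idx, seq_len(ncol(m)))], c(d[1], 1, d[3], d[4]))
  adNode(tape, v, list(x), function(g) {
    z <- matrix(0, C, ncol(m))
    z[cbind(idx, seq_len(ncol(m)))] <- as.vector(g)
    list(aperm(array(z, c(C, d[1], d[3], d[4])), c(2, 1, 3, 4)))
  })
}

adConcatC <- function(tape, xs) {
  vals <- lapply(xs, function(n) n$value)
  d1 <- dim(vals[[1]])
  Cs <- vapply(vals, function(v) dim(v)[2], numeric(1))
  out <- array(0, c(d1[1], sum(Cs), d1[3], d1[4]))
  at <- 0L
  for (v in vals) { out[, at + seq_len(dim(v)[2]), , ] <- v; at <- at + dim(v)[2] }
  adNode(tape, out, xs, function(g) {
    res <- vector("list", length(xs)); at <- 0L
    for (j in seq_along(xs)) {
      cj <- dim(vals[[j]])[2]
      res[[j]] <- g[, at + seq_len(cj), , , drop = FALSE]
      dim(res[[j]]) <- dim(vals[[j]])
      at <- at + cj
    }
    res
  })
}

adRowScaleConst <- function(tape, base, s, X) {
  # base (B,D) + s (B,1) * X, with X a constant matrix (no gradient)
  sv <- as.vector(s$value)
  adNode(tape, base$value + sv * X, list(base, s), function(g) {
    list(g, matrix(rowSums(g * X), ncol = 1))
  })
}

adScaleByElement <- function(tape, x, w, i) {
  # multiply x by the i-th entry of parameter vector w (learnable scalar)
  wi <- w$value[i]; Xv <- x$value
  n <- length(w$value)
  adNode(tape, Xv * wi, list(x, w), function(g) {
    dw <- numeric(n); dw[i] <- sum(g * Xv)
    list(g * wi, dw)
  })
}

# ---- losses ----

adSoftmaxCE <- function(tape, logits, y, w = NULL) {
  # logits (B,K), y integer class index 1..K, w per-sample weights
  Z <- logits$value
  B <- nrow(Z)
  w <- if (is.null(w)) rep(1, B) else as.numeric(w)
  Zs <- Z - apply(Z, 1, max)
  P <- exp(Zs) / rowSums(exp(Zs))
  nll <- -log(pmax(P[cbind(seq_len(B), y)], 1e-300))
  loss <- mean(w * nll)
  nd <- adNode(tape, loss, list(logits), function(g) {
    G <- P
    G[cbind(seq_len(B), y)] <- G[cbind(seq_len(B), y)] - 1
    list(g * G * (w / B))
  })
  attr(nd, "probs") <- P
  nd
}

adMSE <- function(tape, pred, target) {
  D <- pred$value - target
  n <- length(D)
  adNode(tape, sum(D^2) / n, list(pred), function(g) list(g * 2 * D / n))
}

adMeanAll <- function(tape, x) {
  n <- length(x$value)
  d <- dim(x$value)
  adNode(tape, mean(x$value), list(x), function(g) list(array(g / n, d)))
}

# ---- parameter plumbing ----

# Wrap a flat named list of arrays as tape nodes.
adWrapParams <- function(tape, params) lapply(params, function(p) adConst(tape, p))

# Collect gradients back out of wrapped parameter nodes (zero where unused).
adCollectGrads <- function(nodes, params) {
  g <- vector("list", length(params)); names(g) <- names(params)
  for (nm in names(params)) {
    gv <- nodes[[nm]]$grad
    g[[nm]] <- if (is.null(gv)) array(0, dim = dim(params[[nm]]) %||% length(params[[nm]])) else gv
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Adam optimizer state and update over a flat named parameter list.
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}
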