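# Multiscale embedding-compression attention block.
#
# Three stages on a (B, C, H, W) feature grid:
#   1. global perception: 1x1 convolution + GELU;
#   2. channel attention: mean/max/median spatial pooling, a shared
#      Conv-ReLU-Conv bottleneck MLP, sigmoid per branch, branch sum
#      (values in (0,3)), broadcast-multiplied over spatial positions;
#   3. spatial attention: a 5x5 depthwise convolution followed by three
#      asymmetric depthwise pairs (1x7*7x1, 1x11*11x1, 1x21*21x1) whose
#      outputs are summed; a 1x1 convolution turns the result into a spatial
#      map that gates the channel-enhanced features before a final 1x1
#      output convolution.
# Zero padding keeps spatial dimensions through every stage; the median
# pooling uses the lower median for even counts so results are
# deterministic.

#' Initialize MECS parameters
#'
#' @param cIn Input channel count.
#' @param cMid Working channel count after global perception (default `cIn`).
#' @param cOut Output channel count (default `cMid`).
#' @param reduction Bottleneck ratio of the shared channel MLP (default 4;
#'   hidden size is `max(cMid/reduction, 1)`).
#' @param seed Seed for the random initialization.
#' @return Named list of weight arrays (class `MECSParams`): `Wp`/`bp`
#'   (global-perception 1x1 conv), `mlpW1`/`mlpB1`/`mlpW2`/`mlpB2` (shared
#'   channel MLP), depthwise kernels `dw5`, `dw7a`, `dw7b`, `dw11a`,
#'   `dw11b`, `dw21a`, `dw21b` with biases `bdw*`, `Wps`/`bps`
#'   (spatial-attention 1x1 conv) and `Wpo`/`bpo` (output 1x1 conv).
#' @export
mecsInit <- function(cIn, cMid = cIn, cOut = cMid, reduction = 4, seed = 1L) {
  hid <- max(ceiling(cMid / reduction), 1L)
  withSeed(seed, {
    gl <- function(...) { d <- c(...); array(rnorm(prod(d), sd = sqrt(2 / sum(d[1:2]))), d) }
    dw <- function(C, kh, kw) array(rnorm(C * kh * kw, sd = sqrt(1 / (kh * kw))), c(C, kh, kw))
    p <- list(
      Wp = gl(cMid, cIn, 1), bp = numeric(cMid),
      mlpW1 = matrix(rnorm(cMid * hid, sd = sqrt(2 / (cMid + hid))), cMid, hid),
      mlpB1 = numeric(hid),
      mlpW2 = matrix(rnorm(hid * cMid, sd = sqrt(2 / (cMid + hid))), hid, cMid),
      mlpB2 = numeric(cMid),
      dw5 = dw(cMid, 5, 5), bdw5 = numeric(cMid),
      dw7a = dw(cMid, 1, 7), dw7b = dw(cMid, 7, 1), bdw7 = numeric(cMid),
      dw11a = dw(cMid, 1, 11), dw11b = dw(cMid, 11, 1), bdw11 = numeric(cMid),
      dw21a = dw(cMid, 1, 21), dw21b = dw(cMid, 21, 1), bdw21 = numeric(cMid),
      Wps = gl(cMid, cMid, 1), bps = numeric(cMid),
      Wpo = gl(cOut, cMid, 1), bpo = numeric(cOut))
    class(p) <- c("MECSParams", "list")
    p
  })
}

# Tape-level graphs (shared by the public forwards and classifier training).

mecsGlobalGraph <- function(tape, x, p) {
  adGelu(tape, adConvW(tape, x, p$Wp, p$bp))
}

mecsChannelGraph <- function(tape, xp, p) {
  mlp <- function(v) {
    h <- adRelu(tape, adLinear(tape, v, p$mlpW1, p$mlpB1))
    adSigmoid(tape, adLinear(tape, h, p$mlpW2, p$mlpB2))
  }
  aAvg <- mlp(adPoolSpat(tape, xp, "mean"))
  aMax <- mlp(adPoolSpat(tape, xp, "max"))
  aMed <- mlp(adPoolSpat(tape, xp, "median"))
  ac <- adAdd(tape, adAdd(tape, aAvg, aMax), aMed)
  list(attention = ac, weighted = adChanScale(tape, xp, ac))
}

mecsSpatialGraph <- function(tape, xc, p) {
  base <- adDWConv(tape, xc, p$dw5, p$bdw5)
  b7 <- adDWConv(tape, adDWConv(tape, base, p$dw7a), p$dw7b, p$bdw7)
  b11 <- adDWConv(tape, adDWConv(tape, base, p$dw11a), p$dw11b, p$bdw11)
  b21 <- adDWConv(tape, adDWConv(tape, base, p$dw21a), p$dw21b, p$bdw21)
  adAdd(tape, adAdd(tape, b7, b11), b21)
}

mecsGraph <- function(tape, x, p) {
  xp <- mecsGlobalGraph(tape, x, p)
  ca <- mecsChannelGraph(tape, xp, p)
  xs <- mecsSpatialGraph(tape, ca$weighted, p)
  smap <- adConvW(tape, xs, p$Wps, p$bps)
  gated <- adMul(tape, smap, ca$weighted)
  adConvW(tape, gated, p$Wpo, p$bpo)
}

asGrid <- function(x) {
  if (length(dim(x)) != 4L) stop("expected a rank-4 (B,C,H,W) array", call. = FALSE)
  if (any(!is.finite(x))) stop("feature grid contains non-finite values", call. = FALSE)
  x
}

runGraph <- function(build, x) {
  tape <- adTape()
  build(tape, adConst(tape, asGrid(x)))$value
}

wrapP <- function(tape, p) {
  w <- adWrapParams(tape, unclass(p))
  class(w) <- "list"
  w
}

#' MECS stage: global perception
#'
#' `GELU(Wp * X)`: 1x1 convolution over channels followed by GELU.
#'
#' @param x Rank-4 array `(batch, channel, height, width)`.
#' @param params A `MECSParams` list from [mecsInit()].
#' @return Rank-4 array with `cMid` channels, spatial dims preserved.
#' @export
globalPerception <- function(x, params) {
  runGraph(function(t, xn) mecsGlobalGraph(t, xn, wrapP(t, params)), x)
}

#' MECS stage: channel attention
#'
#' Mean, max and (lower-)median pooling over spatial positions, a shared
#' sigmoid-capped bottleneck MLP per descriptor, and the branch sum
#' `A = A_avg + A_max + A_med` (each entry in (0,3)) broadcast-multiplied
#' with the input.
#'
#' @param xPrime Output of [globalPerception()].
#' @inheritParams globalPerception
#' @return List with `attention` (`(B, C)` matrix) and `weighted` (gated
#'   grid).
#' @export
channelAttention <- function(xPrime, params) {
  tape <- adTape()
  res <- mecsChannelGraph(tape, adConst(tape, asGrid(xPrime)), wrapP(tape, params))
  list(attention = res$attention$value, weighted = res$weighted$value)
}

#' MECS stage: spatial attention
#'
#' A 5x5 depthwise convolution followed by three asymmetric depthwise pairs
#' (1x7*7x1, 1x11*11x1, 1x21*21x1); branch outputs are summed. Zero padding
#' preserves spatial dims.
#'
#' @param xC Channel-weighted grid from [channelAttention()].
#' @inheritParams globalPerception
#' @return Rank-4 array, same shape as the input.
#' @export
spatialAttention <- function(xC, params) {
  runGraph(function(t, xn) mecsSpatialGraph(t, xn, wrapP(t, params)), xC)
}

#' Full MECS forward pass
#'
#' Composition of the three stages plus the closing
#' `Wpo * [(Wps * Xs) (*) Xc]` gating, where `Wps` produces the spatial
#' attention map and `Wpo` is the output 1x1 convolution.
#'
#' @inheritParams globalPerception
#' @return Rank-4 array `(B, cOut, H, W)`.
#' @export
mecsForward <- function(x, params) {
  runGraph(function(t, xn) mecsGraph(t, xn, wrapP(t, params)), x)
}

#' Reshape flat features to a MECS grid
#'
#' Reduced feature vectors are laid out as `(B, channels, 1, D/channels)`
#' single-row grids so the asymmetric kernels act along the feature axis.
#'
#' @param X Matrix `(B, D)`; `D` must be divisible by `channels`.
#' @param channels Channel count (default 8).
#' @return Rank-4 array `(B, channels, 1, D/channels)`.
#' @export
gridFromFeatures <- function(X, channels = 8L) {
  X <- as.matrix(X)
  D <- ncol(X)
  if (D %% channels != 0)
    stop(sprintf("feature dim %d not divisible by %d channels", D, channels), call. = FALSE)
  W <- D %/% channels
  a <- array(X, c(nrow(X), channels, W))   # column j -> (channel, pos) pairs
  array(a, c(nrow(X), channels, 1L, W))
}
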