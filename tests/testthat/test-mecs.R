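# Helpers to surgically set MECS parameters for closed-form checks.
identityMecs <- function(C) {
  p <- mecsInit(C, C, C, seed = 1L)
  eye <- array(0, c(C, C, 1)); for (i in seq_len(C)) eye[i, i, 1] <- 1
  p$Wp <- eye; p$bp <- numeric(C)
  p$Wps <- eye; p$bps <- numeric(C)
  p$Wpo <- eye; p$bpo <- numeric(C)
  # zero MLP: each sigmoid branch contributes 0.5
  p$mlpW1[] <- 0; p$mlpB1[] <- 0; p$mlpW2[] <- 0; p$mlpB2[] <- 0
  # delta (identity) depthwise kernels, zero biases
  delta <- function(C, kh, kw) {
    a <- array(0, c(C, kh, kw)); a[, (kh + 1) %/% 2, (kw + 1) %/% 2] <- 1; a
  }
  p$dw5 <- delta(C, 5, 5); p$dw7a <- delta(C, 1, 7); p$dw7b <- delta(C, 7, 1)
  p$dw11a <- delta(C, 1, 11); p$dw11b <- delta(C, 11, 1)
  p$dw21a <- delta(C, 1, 21); p$dw21b <- delta(C, 21, 1)
  for (nm in c("bdw5", "bdw7", "bdw11", "bdw21")) p[[nm]][] <- 0
  p
}

gelu <- function(x) x * pnorm(x)

test_that("global perception is GELU of the pointwise convolution", {
  p <- identityMecs(2L)
  z <- array(0, c(1, 2, 2, 2))
  expect_equal(globalPerception(z, p), z)              # GELU(0) = 0
  big <- array(50, c(1, 2, 2, 2))
  expect_equal(globalPerception(big, p), big, tolerance = 1e-9)  # GELU saturates
  # random weights vs direct formula on a 1x2x2x2 grid
  p2 <- mecsInit(2L, 2L, seed = 3L)
  set.seed(5); x <- array(rnorm(8), c(1, 2, 2, 2))
  manual <- x * 0
  for (o in 1:2) for (h in 1:2) for (w in 1:2)
    manual[1, o, h, w] <- gelu(sum(p2$Wp[o, , 1] * x[1, , h, w]) + p2$bp[o])
  expect_equal(globalPerception(x, p2), manual, tolerance = 1e-6)
})

test_that("channel attention sums three sigmoid branches and stays in (0,3)", {
  C <- 4L
  p <- identityMecs(C)
  # zero MLP: every branch is sigmoid(0) = 0.5, so A = 1.5 and Xc = 1.5 X'
  set.seed(6); xp <- array(rnorm(2 * C * 3 * 5), c(2, C, 3, 5))
  ca <- channelAttention(xp, p)
  expect_equal(ca$attention, matrix(1.5, 2, C))
  expect_equal(ca$weighted, 1.5 * xp)
  # spatially constant input: the three poolings coincide
  p3 <- mecsInit(C, C, seed = 9L)
  v <- matrix(rnorm(2 * C), 2, C)
  const <- array(rep(as.vector(v), 3 * 5), c(2, C, 3, 5))
  ca3 <- channelAttention(const, p3)
  mlp <- function(m) 1 / (1 + exp(-(pmax(m %*% p3$mlpW1 +
    rep(p3$mlpB1, each = 2), 0) %*% p3$mlpW2 + rep(p3$mlpB2, each = 2))))
  expect_equal(ca3$attention, 3 * mlp(v), tolerance = 1e-9, ignore_attr = TRUE)
  # bounds hold for arbitrary parameters
  for (s in 1:3) {
    pr <- mecsInit(C, C, seed = 100L + s)
    a <- channelAttention(array(rnorm(2 * C * 4 * 4, sd = 3), c(2, C, 4, 4)), pr)$attention
    expect_true(all(a > 0 & a < 3))
  }
})

test_that("spatial attention branches follow the depthwise convolution algebra", {
  C <- 2L
  p <- identityMecs(C)
  set.seed(7); xc <- array(rnorm(2 * C * 2 * 6), c(2, C, 2, 6))
  expect_equal(spatialAttention(xc, p), 3 * xc)        # three identity branches
  pz <- p
  for (nm in c("dw5", "dw7a", "dw7b", "dw11a", "dw11b", "dw21a", "dw21b"))
    pz[[nm]][] <- 0
  expect_equal(spatialAttention(xc, pz), xc * 0)
  # single asymmetric branch vs a hand 1-D convolution on a 1x1x1x8 grid
  p1 <- identityMecs(1L)
  set.seed(8)
  k <- rnorm(7)
  p1$dw7a <- array(k, c(1, 1, 7))
  for (nm in c("dw11a", "dw11b", "dw21a", "dw21b")) p1[[nm]][] <- 0
  x <- array(rnorm(8), c(1, 1, 1, 8))
  manual <- numeric(8)
  for (w in 1:8) for (tap in 1:7) {
    ws <- w + tap - 4L
    if (ws >= 1 && ws <= 8) manual[w] <- manual[w] + k[tap] * x[1, 1, 1, ws]
  }
  expect_equal(as.vector(spatialAttention(x, p1)), manual, tolerance = 1e-6)
})

test_that("the full block matches a straight-line staged computation", {
  C <- 2L
  p <- identityMecs(C)
  set.seed(10); x <- array(rnorm(1 * C * 2 * 4), c(1, C, 2, 4))
  # staged closed form: X' = GELU(x); A = 1.5; Xc = 1.5 X'; Xs = 3 Xc;
  # spatial map = Xs (identity conv); out = (Xs * Xc) through identity Wpo
  xp <- gelu(x)
  xc <- 1.5 * xp
  expect_equal(mecsForward(x, p), (3 * xc) * xc, tolerance = 1e-5)
  expect_equal(mecsForward(x * 0, p), x * 0)           # null-preserving
  # stage composition equals the one-shot forward for random parameters
  pr <- mecsInit(C, C, seed = 33L)
  st1 <- globalPerception(x, pr)
  st2 <- channelAttention(st1, pr)
  st3 <- spatialAttention(st2$weighted, pr)
  smap <- naiveConvW(st3, pr$Wps) + rep(pr$bps, each = 1)
  manual <- naiveConvW(smap * st2$weighted, pr$Wpo) + rep(pr$bpo, each = 1)
  expect_equal(mecsForward(x, pr), manual, tolerance = 1e-5)
})

test_that("spatial dimensions are preserved on classifier-shaped grids", {
  p <- mecsInit(8L, seed = 2L)
  x <- gridFromFeatures(matrix(rnorm(2 * 200), 2, 200), 8L)
  expect_equal(dim(x), c(2L, 8L, 1L, 25L))
  out <- mecsForward(x, p)
  expect_equal(dim(out), c(2L, 8L, 1L, 25L))
  expect_true(all(is.finite(out)))
  expect_error(gridFromFeatures(matrix(0, 2, 30), 8L), "divisible")
})

test_that("tape gradients agree with central finite differences", {
  pf <- asNamespace("pepForge")
  set.seed(12)
  C <- 3L
  p <- mecsInit(C, C, seed = 44L)
  x <- array(rnorm(2 * C * 2 * 5), c(2, C, 2, 5))
  lossOf <- function(pp) sum(mecsForward(x, pp)^2)
  tape <- pf$adTape()
  pn <- pf$adWrapParams(tape, unclass(p))
  out <- pf$mecsGraph(tape, pf$adConst(tape, x), pn)
  loss <- pf$adNode(tape, sum(out$value^2), list(out),
                    function(g) list(g * 2 * out$value))
  pf$adBackward(tape, loss)
  for (nm in c("Wp", "mlpW1", "mlpW2", "dw5", "dw7a", "dw21b", "Wps", "Wpo", "bp")) {
    idx <- sample(length(p[[nm]]), 1)
    h <- 1e-5
    p1 <- p; p1[[nm]][idx] <- p1[[nm]][idx] + h
    p2 <- p; p2[[nm]][idx] <- p2[[nm]][idx] - h
    fd <- (lossOf(p1) - lossOf(p2)) / (2 * h)
    an <- pn[[nm]]$grad[idx]
    expect_equal(an, fd, tolerance = 1e-5)
  }
})
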