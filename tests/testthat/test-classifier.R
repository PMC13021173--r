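test_that("SMOTE balances to the majority and interpolates within classes", {
  set.seed(1)
  X <- rbind(matrix(rnorm(20, mean = 5), 10, 2),
             matrix(rnorm(8, mean = -5), 4, 2))
  y <- c(rep("A", 10), rep("B", 4))
  out <- smoteOversample(X, y, k = 3L, seed = 2L)
  expect_equal(as.integer(table(out$y)), c(10L, 10L))
  # originals preserved verbatim, first
  expect_identical(out$X[1:14, ], X)
  expect_identical(out$synthetic, c(rep(FALSE, 14), rep(TRUE, 6)))
  # every synthetic point is on a segment between two original class-B rows
  Xb <- X[y == "B", ]
  for (r in which(out$synthetic)) {
    expect_identical(out$y[r], "B")
    s <- out$X[r, ]
    onSegment <- FALSE
    for (i in 1:4) for (j in setdiff(1:4, i)) {
      d <- Xb[j, ] - Xb[i, ]
      u <- if (abs(d[1]) > abs(d[2])) (s[1] - Xb[i, 1]) / d[1] else (s[2] - Xb[i, 2]) / d[2]
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          max(abs(Xb[i, ] + u * d - s)) < 1e-9) onSegment <- TRUE
    }
    expect_true(onSegment)
  }
  expect_identical(out$X, smoteOversample(X, y, k = 3L, seed = 2L)$X)
  expect_error(smoteOversample(X, y, k = 4L, seed = 1L), "smallest class")
  expect_error(smoteOversample(X[1:11, ], c(rep("A", 10), "B"), k = 1L), "fewer than 2")
})

test_that("stratified folds keep class proportions within one sample", {
  set.seed(3)
  y <- rep(0:8, times = c(55, 184, 116, 114, 53, 56, 144, 64, 86))
  f <- stratifiedFolds(y, 5L, seed = 4L)
  expect_setequal(unique(f), 1:5)
  for (k in 0:8) {
    per <- table(factor(f[y == k], levels = 1:5))
    expect_lte(diff(range(per)), 1L)
  }
  expect_identical(f, stratifiedFolds(y, 5L, seed = 4L))
})

test_that("noise conditioning is the additive sum of its three embeddings", {
  emb <- sinusoidalEmbedding(0, 16L)
  expect_equal(emb, c(rep(0, 8), rep(1, 8)))      # t = 0 closed form
  set.seed(5)
  d <- 6L
  params <- list(condEmb = matrix(rnorm(10 * d), 10, d),
                 timeW = matrix(rnorm(16 * d), 16, d), timeB = rnorm(d))
  xp <- matrix(rnorm(3 * d), 3, d)
  out <- noiseCondition(xp, c(0L, 4L, NA), 0.3, params)
  manual <- xp
  manual[1, ] <- manual[1, ] + params$condEmb[1, ]
  manual[2, ] <- manual[2, ] + params$condEmb[5, ]
  manual[3, ] <- manual[3, ] + params$condEmb[10, ]   # learned null row
  tv <- as.numeric(sinusoidalEmbedding(0.3, 16L) %*% params$timeW) + params$timeB
  manual <- manual + matrix(tv, 3, d, byrow = TRUE)
  expect_equal(out, manual, tolerance = 1e-12)
  # zero time projection + zero null row leaves x unchanged
  pz <- params; pz$timeW[] <- 0; pz$timeB[] <- 0; pz$condEmb[10, ] <- 0
  expect_equal(noiseCondition(xp, NA, 0.9, pz), xp)
})

test_that("the residual backbone reduces to F(x) and scales branches by w", {
  d <- 8L
  cfg1 <- classifierConfig(branchKernels = 1L, hidden = d)
  params <- list(bbW1 = diag(d), bbB1 = numeric(d),
                 bbW2 = matrix(0, d, d), bbB2 = numeric(d),
                 branchW = 0, branchK1 = array(2, c(1, 1, 1)))
  x <- matrix(rnorm(2 * d), 2, d)
  # all w_i = 0: output is exactly the backbone F(x); here F = identity
  expect_equal(multiscaleResidualForward(x, params, cfg1), x)
  # K = 1, F = identity, G_1 doubles, w_1 = 1  ->  3x
  params$branchW <- 1
  expect_equal(multiscaleResidualForward(x, params, cfg1), 3 * x)
  # seeded K = 2 instance vs independent branch-by-branch recomputation
  set.seed(6)
  cfg2 <- classifierConfig(branchKernels = c(3L, 5L), hidden = d)
  p2 <- list(bbW1 = matrix(rnorm(d * d, sd = 0.3), d, d), bbB1 = rnorm(d),
             bbW2 = matrix(rnorm(d * d, sd = 0.3), d, d), bbB2 = rnorm(d),
             branchW = c(0.7, -0.4),
             branchK1 = array(rnorm(3), c(1, 1, 3)),
             branchK2 = array(rnorm(5), c(1, 1, 5)))
  h <- x %*% p2$bbW1 + rep(p2$bbB1, each = 2)
  f <- x + (h * pnorm(h)) %*% p2$bbW2 + rep(p2$bbB2, each = 2)
  conv1 <- function(v, k) {
    off <- (length(k) - 1) %/% 2
    vapply(seq_along(v), function(w) {
      acc <- 0
      for (tap in seq_along(k)) {
        ws <- w + tap - 1 - off
        if (ws >= 1 && ws <= length(v)) acc <- acc + k[tap] * v[ws]
      }
      acc
    }, numeric(1))
  }
  manual <- f
  for (b in 1:2) {
    manual[b, ] <- manual[b, ] + 0.7 * conv1(x[b, ], as.vector(p2$branchK1)) -
      0.4 * conv1(x[b, ], as.vector(p2$branchK2))
  }
  expect_equal(multiscaleResidualForward(x, p2, cfg2), manual, tolerance = 1e-6)
})

test_that("metric report matches hand-computed and oracle values", {
  # perfect predictions
  y <- rep(0:8, each = 3)
  P <- matrix(1e-9, 27, 9); P[cbind(1:27, y + 1)] <- 1
  P <- P / rowSums(P)
  rep1 <- evaluateMetrics(y, P)
  expect_equal(rep1@accuracy, 1); expect_equal(rep1@macroF1, 1)
  expect_equal(rep1@meanAuc, 1)
  expect_equal(unname(diag(confusionMatrix(rep1))), rep(3L, 9))
  # hand-built 3-class confusion: truths 0,0,1,1,2,2; preds 0,1,1,1,2,0
  yt <- c(0, 0, 1, 1, 2, 2); yp <- c(0, 1, 1, 1, 2, 0)
  P2 <- matrix(1e-9, 6, 9); P2[cbind(1:6, yp + 1)] <- 1; P2 <- P2 / rowSums(P2)
  # per class: P = (1/2, 2/3, 1), R = (1/2, 1, 1/2), F1 = (1/2, 4/5, 2/3)
  suppressWarnings(rep2 <- evaluateMetrics(yt, P2))
  expect_equal(rep2@macroF1, mean(c(1/2, 4/5, 2/3)))
  expect_equal(rep2@macroPrecision, mean(c(1/2, 2/3, 1)))
  expect_equal(rep2@macroRecall, mean(c(1/2, 1, 1/2)))
  expect_warning(evaluateMetrics(yt, P2), "absent")
})

test_that("one-vs-rest AUC matches the pairwise-count oracle and the null level", {
  pf <- asNamespace("pepForge")
  set.seed(8)
  for (i in 1:5) {
    sc <- sample(seq(0, 1, by = 0.05), 100, TRUE)   # many ties -> midranks
    pos <- runif(100) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(pf$rankAuc(sc, pos), pairwiseAucOracle(sc, pos), tolerance = 1e-9)
  }
  # label-independent scores on a balanced two-class sample: AUC ~ 0.5
  set.seed(9)
  n <- 2000
  sc <- runif(n); pos <- rep(c(TRUE, FALSE), n / 2)
  expect_lt(abs(pf$rankAuc(sc, pos) - 0.5), 0.03)
  # cross-check against an established implementation
  expect_equal(pf$rankAuc(sc, pos),
               as.numeric(pROC::auc(pROC::roc(pos, sc, quiet = TRUE))),
               tolerance = 1e-9)
})

test_that("training handles 4:1 imbalance, is seeded, and predicts probabilities", {
  ps <- generatePeptideDataset(syntheticSpec(
    counts = c(24L, 24L, 6L, 6L, 6L, 6L, 6L, 6L, 6L), seed = 10L))
  cfg <- classifierConfig(epochs = 6L, folds = 2L, patience = 6L,
                          nComponents = 32L, smoteK = 2L, seed = 10L)
  model <- trainClassifier(ps, cfg)
  probs <- predict(model, ps)
  expect_equal(dim(probs), c(length(ps), 9L))
  expect_equal(unname(rowSums(probs)), rep(1, length(ps)), tolerance = 1e-6)
  expect_identical(probs, predict(model, ps))          # t = 0 determinism
  # minority classes are not ignored
  yhat <- max.col(probs, ties.method = "first") - 1L
  minority <- peptideLabels(ps) >= 2L
  expect_gt(sum(yhat[minority] == peptideLabels(ps)[minority]), 0L)
  # same config and seed reproduce the loss trajectory exactly
  model2 <- trainClassifier(ps, cfg)
  expect_identical(model$lossHistory, model2$lossHistory)
  expect_identical(model$foldF1, model2$foldF1)
})

test_that("training rejects degenerate label configurations", {
  ps <- generatePeptideDataset(syntheticSpec(counts = rep(4L, 9L), seed = 11L))
  one <- PeptideSet(sequence = peptideSequences(ps), label = rep(0L, length(ps)))
  expect_error(trainClassifier(one), "2 classes")
  unl <- PeptideSet(sequence = peptideSequences(ps)[1:4])
  expect_error(trainClassifier(unl), "labelled")
})
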