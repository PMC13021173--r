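# Noise-conditioned multiclass ACP classifier.
#
# Pipeline per cross-validation fold: fit the standardize+PCA reduction on
# the training split, SMOTE-balance the reduced training features, then
# train the network with class-weighted cross-entropy and Adam. The network
# is: reduced features reshaped to a single-row grid -> MECS attention ->
# linear projection -> plus condition embedding and sinusoidal time
# embedding -> multiscale residual backbone -> softmax head. A stochastic
# time scalar t ~ U(0,1) perturbs training batches (diffusion-inspired
# regularization); inference fixes t = 0 and uses a learned null-condition
# embedding, so predictions are deterministic.

#' Classifier configuration
#'
#' @param nClasses Number of classes (9 cancer types).
#' @param channels Grid channels fed to MECS (default 8).
#' @param nComponents PCA dimensionality (default 200).
#' @param hidden Width of the projected representation (default 64).
#' @param timeDim Sinusoidal time-embedding width (default 32, even).
#' @param branchKernels Kernel sizes of the residual branches (default
#'   3, 5, 7).
#' @param lr Adam learning rate (default 1e-2; at these dataset sizes each
#'   epoch is only a handful of optimizer steps and the larger rate both
#'   converges and generalizes better).
#' @param epochs Maximum epochs (default 200).
#' @param batchSize Minibatch size (default 32, giving the optimizer enough
#'   updates per epoch at desk-scale dataset sizes).
#' @param folds Stratified cross-validation folds (default 5).
#' @param patience Early-stopping patience on validation macro-F1
#'   (default 10).
#' @param smoteK SMOTE neighbour count (default 5).
#' @param conditionDropout Probability of replacing the true label with the
#'   null condition during training (default 0.2).
#' @param classWeights `"inverse-frequency"` (normalized to mean 1) or
#'   `"uniform"`.
#' @param seed Master seed (default 42).
#' @return Named list of settings.
#' @export
classifierConfig <- function(nClasses = 9L, channels = 8L, nComponents = 200L,
                             hidden = 64L, timeDim = 32L,
                             branchKernels = c(3L, 5L, 7L), lr = 1e-2,
                             epochs = 200L, batchSize = 32L, folds = 5L,
                             patience = 10L, smoteK = 5L,
                             conditionDropout = 0.2,
                             classWeights = c("inverse-frequency", "uniform"),
                             seed = 42L) {
  stopifnot(folds >= 2L, patience >= 1L, timeDim %% 2L == 0L,
            length(branchKernels) >= 1L)
  list(nClasses = as.integer(nClasses), channels = as.integer(channels),
       nComponents = as.integer(nComponents), hidden = as.integer(hidden),
       timeDim = as.integer(timeDim), branchKernels = as.integer(branchKernels),
       lr = lr, epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       folds = as.integer(folds), patience = as.integer(patience),
       smoteK = as.integer(smoteK), conditionDropout = conditionDropout,
       classWeights = match.arg(classWeights), seed = as.integer(seed))
}

#' SMOTE oversampling
#'
#' Balances every class up to the majority count. Each synthetic point is
#' `x_i + u (x_nn - x_i)` with `u ~ U(0,1)` and `x_nn` one of the `k`
#' same-class Euclidean nearest neighbours of `x_i`. Original rows are kept
#' verbatim and come first; results are deterministic given the seed.
#'
#' @param X Numeric feature matrix (samples in rows).
#' @param y Class labels (any atomic type).
#' @param k Neighbour count; must not exceed the smallest class size
#'   minus 1.
#' @param seed Integer seed.
#' @return List with balanced `X`, `y`, and `synthetic` (logical flag per
#'   row).
#' @export
smoteOversample <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows and y length differ", call. = FALSE)
  counts <- table(y)
  if (any(counts < 2L))
    stop(sprintf("class '%s' has fewer than 2 samples; SMOTE needs at least 2",
                 names(counts)[which.min(counts)]), call. = FALSE)
  if (k > min(counts) - 1L)
    stop(sprintf("k = %d exceeds smallest class size - 1 (= %d)",
                 k, min(counts) - 1L), call. = FALSE)
  target <- max(counts)
  newX <- list(); newY <- list()
  withSeed(seed, {
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need == 0) next
      idx <- which(y == cl)
      Xc <- X[idx, , drop = FALSE]
      D <- as.matrix(stats::dist(Xc))
      diag(D) <- Inf
      nn <- t(apply(D, 1, function(r) order(r)[seq_len(k)]))
      base <- sample(seq_len(nrow(Xc)), need, replace = TRUE)
      pick <- nn[cbind(base, sample(seq_len(k), need, replace = TRUE))]
      u <- runif(need)
      synth <- Xc[base, , drop = FALSE] +
        u * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
      newX[[cl]] <- synth
      newY[[cl]] <- rep(y[idx[1]], need)
    }
  })
  if (length(newX)) {
    Xs <- do.call(rbind, newX)
    list(X = rbind(X, Xs), y = c(y, unlist(newY, use.names = FALSE)),
         synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(Xs))))
  } else {
    list(X = X, y = y, synthetic = rep(FALSE, nrow(X)))
  }
}

#' Stratified fold assignment
#'
#' Round-robin assignment within each shuffled class so per-fold class
#' proportions stay within one sample of the global proportions.
#'
#' @param y Labels.
#' @param folds Fold count (>= 2).
#' @param seed Integer seed.
#' @return Integer fold id (1..folds) per sample.
#' @export
stratifiedFolds <- function(y, folds = 5L, seed = 1L) {
  folds <- assertScalarCount(folds, "folds", 2L)
  assign <- integer(length(y))
  withSeed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Sinusoidal time embedding
#'
#' Fixed embedding of a scalar `t` in `[0,1]`: first half
#' `sin(omega_i t)`, second half `cos(omega_i t)` at geometric frequencies
#' `omega_i = 10000^(-(i-1)/(d/2))` scaled by 2*pi... the frequencies span
#' `2*pi * 10000^0 .. 2*pi * 10000^(-1)` so t = 0 gives zeros then ones.
#'
#' @param t Scalar in `[0, 1]`.
#' @param dim Even embedding width.
#' @return Numeric vector of length `dim`.
#' @export
sinusoidalEmbedding <- function(t, dim = 32L) {
  stopifnot(dim %% 2L == 0L)
  half <- dim %/% 2L
  freq <- 2 * pi * 10000^(-(seq_len(half) - 1) / half)
  c(sin(freq * t), cos(freq * t))
}

initClassifierParams <- function(cfg, seed) {
  d <- cfg$hidden; C <- cfg$channels
  W <- cfg$nComponents %/% C
  withSeed(seed, {
    gl <- function(a, b) matrix(rnorm(a * b, sd = sqrt(2 / (a + b))), a, b)
    p <- list(
      projW = gl(cfg$nComponents, d), projB = numeric(d),
      condEmb = matrix(rnorm((cfg$nClasses + 1L) * d, sd = 0.05),
                       cfg$nClasses + 1L, d),
      timeW = gl(cfg$timeDim, d), timeB = numeric(d),
      bbW1 = gl(d, d), bbB1 = numeric(d),
      bbW2 = matrix(0, d, d), bbB2 = numeric(d),
      branchW = rep(0.1, length(cfg$branchKernels)),
      headW = gl(d, cfg$nClasses), headB = numeric(cfg$nClasses))
    for (i in seq_along(cfg$branchKernels)) {
      kk <- cfg$branchKernels[i]
      p[[paste0("branchK", i)]] <- array(rnorm(kk, sd = sqrt(1 / kk)), c(1, 1, kk))
    }
    mecs <- mecsInit(C, C, C, seed = childSeed(seed, 17L))
    for (nm in names(mecs)) p[[paste0("mecs.", nm)]] <- mecs[[nm]]
    p
  })
}

mecsSubParams <- function(pn) {
  out <- list()
  for (nm in names(pn)) if (startsWith(nm, "mecs."))
    out[[substring(nm, 6L)]] <- pn[[nm]]
  out
}

#' Noise conditioning
#'
#' Elementwise sum of the projected features, the condition embedding of
#' the cancer-type label (a dedicated learned null row when the label is
#' `NA`), and the linearly projected sinusoidal embedding of the stochastic
#' time scalar `t`.
#'
#' @param xProj Matrix `(B, d)` of projected features.
#' @param label Integer labels 0..8, or `NA` for the null condition
#'   (recycled to B).
#' @param t Scalar in `[0, 1]`.
#' @param params List with `condEmb` (`(10, d)`), `timeW`
#'   (`(timeDim, d)`), `timeB` (`d`).
#' @return Matrix `(B, d)`.
#' @export
noiseCondition <- function(xProj, label, t, params) {
  xProj <- as.matrix(xProj)
  d <- ncol(xProj)
  nRows <- nrow(params$condEmb)
  idx <- ifelse(is.na(label), nRows, as.integer(label) + 1L)
  idx <- rep_len(idx, nrow(xProj))
  if (any(idx < 1L | idx > nRows)) stop("label outside 0..8", call. = FALSE)
  temb <- sinusoidalEmbedding(t, nrow(params$timeW))
  tvec <- as.numeric(temb %*% params$timeW) + params$timeB
  xProj + params$condEmb[idx, , drop = FALSE] +
    matrix(tvec, nrow(xProj), d, byrow = TRUE)
}

backboneGraph <- function(tape, x, pn, cfg) {
  # y = F(x) + sum_i w_i G_i(x); F is a residual MLP (identity when its
  # second layer is zero), G_i are single-channel convolutions along the
  # feature axis.
  h <- adGelu(tape, adLinear(tape, x, pn$bbW1, pn$bbB1))
  f <- adAdd(tape, x, adLinear(tape, h, pn$bbW2, pn$bbB2))
  d <- ncol(x$value)
  xg <- adReshape(tape, x, c(nrow(x$value), 1L, 1L, d))
  out <- f
  for (i in seq_along(cfg$branchKernels)) {
    gi <- adConvW(tape, xg, pn[[paste0("branchK", i)]])
    gi <- adReshape(tape, gi, c(nrow(x$value), d))
    out <- adAdd(tape, out, adScaleByElement(tape, gi, pn$branchW, i))
  }
  out
}

#' Multiscale residual backbone
#'
#' `y = F(x) + sum_i w_i G_i(x)`: a residual MLP backbone plus parallel
#' convolutional branches at distinct kernel sizes fused by learnable
#' scalar weights. With all `w_i = 0` the output is exactly `F(x)`.
#'
#' @param x Matrix `(B, d)`.
#' @param params Parameter list holding `bbW1`, `bbB1`, `bbW2`, `bbB2`,
#'   `branchK1..`, `branchW`.
#' @param config A [classifierConfig()] (kernel sizes are read from it).
#' @return Matrix `(B, d)`.
#' @export
multiscaleResidualForward <- function(x, params, config = classifierConfig()) {
  tape <- adTape()
  pn <- adWrapParams(tape, params)
  backboneGraph(tape, adConst(tape, as.matrix(x)), pn, config)$value
}

classifierLogitsGraph <- function(tape, X, condIdx, t, pn, cfg) {
  B <- nrow(X)
  xg <- adConst(tape, gridFromFeatures(X, cfg$channels))
  enc <- mecsGraph(tape, xg, mecsSubParams(pn))
  flat <- adReshape(tape, enc, c(B, length(enc$value) / B))
  xproj <- adLinear(tape, flat, pn$projW, pn$projB)
  cproj <- adRows(tape, pn$condEmb, condIdx)
  temb <- adConst(tape, matrix(sinusoidalEmbedding(t, cfg$timeDim), 1))
  tproj <- adReshape(tape, adMatmul(tape, temb, pn$timeW), cfg$hidden)
  tproj <- adNode(tape, tproj$value + pn$timeB$value, list(tproj, pn$timeB),
                  function(g) list(g, g))
  xcond <- adBiasRow(tape, adAdd(tape, xproj, cproj), tproj)
  y <- backboneGraph(tape, xcond, pn, cfg)
  adLinear(tape, y, pn$headW, pn$headB)
}

softmaxRows <- function(Z) {
  Zs <- Z - apply(Z, 1, max)
  P <- exp(Zs)
  P / rowSums(P)
}

classifierProbs <- function(params, cfg, Xred, condIdx = NULL, t = 0) {
  tape <- adTape()
  pn <- adWrapParams(tape, params)
  if (is.null(condIdx)) condIdx <- rep(cfg$nClasses + 1L, nrow(Xred))
  Z <- classifierLogitsGraph(tape, as.matrix(Xred), condIdx, t, pn, cfg)$value
  softmaxRows(Z)
}

trainFold <- function(Xtr, ytr, Xval, yval, cfg, foldSeed) {
  params <- initClassifierParams(cfg, foldSeed)
  state <- adamInit(params)
  counts <- table(factor(ytr, levels = 0:(cfg$nClasses - 1L)))
  w <- if (cfg$classWeights == "inverse-frequency") {
    wc <- ifelse(counts > 0, 1 / pmax(counts, 1), 0)
    wc * sum(counts > 0) / sum(wc[counts > 0])
  } else rep(1, cfg$nClasses)
  bal <- smoteOversample(Xtr, ytr, k = min(cfg$smoteK, min(counts[counts > 0]) - 1L),
                         seed = childSeed(foldSeed, 101L))
  Xb <- bal$X; yb <- as.integer(bal$y)
  n <- nrow(Xb)
  lossHist <- numeric(0)
  bestF1 <- -Inf; bestEpoch <- 0L; bestParams <- params
  withSeed(childSeed(foldSeed, 202L), {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(n)
      epochLoss <- 0; nb <- 0L
      for (start in seq(1L, n, by = cfg$batchSize)) {
        idx <- ord[start:min(start + cfg$batchSize - 1L, n)]
        t <- runif(1)
        drop <- runif(length(idx)) < cfg$conditionDropout
        condIdx <- ifelse(drop, cfg$nClasses + 1L, yb[idx] + 1L)
        tape <- adTape()
        pn <- adWrapParams(tape, params)
        logits <- classifierLogitsGraph(tape, Xb[idx, , drop = FALSE],
                                        condIdx, t, pn, cfg)
        loss <- adSoftmaxCE(tape, logits, yb[idx] + 1L, w[yb[idx] + 1L])
        if (!is.finite(loss$value))
          stop(sprintf("non-finite training loss at epoch %d", epoch), call. = FALSE)
        adBackward(tape, loss)
        upd <- adamStep(params, adCollectGrads(pn, params), state, lr = cfg$lr)
        params <- upd$params; state <- upd$state
        epochLoss <- epochLoss + loss$value; nb <- nb + 1L
      }
      lossHist <- c(lossHist, epochLoss / nb)
      valProbs <- classifierProbs(params, cfg, Xval)
      f1 <- macroF1(yval, max.col(valProbs, ties.method = "first") - 1L,
                    cfg$nClasses)
      if (f1 > bestF1 + 1e-9) {
        bestF1 <- f1; bestEpoch <- epoch; bestParams <- params
      } else if (epoch - bestEpoch >= cfg$patience) break
    }
  })
  list(params = bestParams, valF1 = bestF1, lossHistory = lossHist,
       bestEpoch = bestEpoch)
}

macroF1 <- function(yTrue, yPred, nClasses) {
  present <- sort(unique(yTrue))
  mean(vapply(present, function(k) {
    tp <- sum(yTrue == k & yPred == k)
    fp <- sum(yTrue != k & yPred == k)
    fn <- sum(yTrue == k & yPred != k)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1)))
}

#' Train the noise-conditioned classifier
#'
#' Stratified K-fold training: per fold the standardize+PCA reduction is
#' fitted on the training split only, the reduced training features are
#' SMOTE-balanced, and the network is trained with class-weighted
#' cross-entropy (weights inversely proportional to the pre-balancing class
#' frequencies, normalized to mean 1), early-stopping on validation
#' macro-F1. The parameters of the best-validation fold are retained.
#'
#' @param x A labelled [PeptideSet-class].
#' @param config A [classifierConfig()].
#' @param backend Embedding backend (default [kmerBackend()]).
#' @return An object of class `acpClassifier` with elements `params`,
#'   `reduction`, `config`, `backend`, `foldF1`, `bestFold`,
#'   `lossHistory`.
#' @export
trainClassifier <- function(x, config = classifierConfig(),
                            backend = kmerBackend()) {
  stopifnot(is(x, "PeptideSet"))
  y <- peptideLabels(x)
  if (any(is.na(y))) stop("all training peptides must be labelled", call. = FALSE)
  if (length(unique(y)) < 2L) stop("need at least 2 classes to train", call. = FALSE)
  if (any(table(y) < 2L)) stop("every class needs at least 2 samples", call. = FALSE)
  cfg <- config
  Xfused <- featurizePeptides(x, backend)
  foldId <- stratifiedFolds(y, cfg$folds, childSeed(cfg$seed, 7L))
  fits <- vector("list", cfg$folds)
  reducs <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    tr <- foldId != f; va <- !tr
    red <- fitReduction(Xfused[tr, , drop = FALSE], cfg$nComponents)
    fits[[f]] <- trainFold(applyReduction(red, Xfused[tr, , drop = FALSE]), y[tr],
                           applyReduction(red, Xfused[va, , drop = FALSE]), y[va],
                           cfg, childSeed(cfg$seed, 1000L + f))
    reducs[[f]] <- red
  }
  valF1 <- vapply(fits, `[[`, numeric(1), "valF1")
  best <- which.max(valF1)
  structure(list(params = fits[[best]]$params, reduction = reducs[[best]],
                 config = cfg, backend = backend, foldF1 = valF1,
                 bestFold = best,
                 lossHistory = lapply(fits, `[[`, "lossHistory")),
            class = "acpClassifier")
}

#' @export
print.acpClassifier <- function(x, ...) {
  cat(sprintf("acpClassifier: %d classes, best fold %d (val macro-F1 %.3f)\n",
              x$config$nClasses, x$bestFold, max(x$foldF1)))
  invisible(x)
}

#' Predict class probabilities
#'
#' Deterministic inference: the time scalar is fixed at 0 and the learned
#' null-condition embedding is used (the cancer type is unknown at
#' prediction time).
#'
#' @param object An `acpClassifier` from [trainClassifier()].
#' @param newdata A [PeptideSet-class] or character vector of sequences.
#' @param ... Unused.
#' @return Matrix `n x 9` of class probabilities (rows sum to 1); the
#'   predicted label is the argmax minus 1.
#' @export
predict.acpClassifier <- function(object, newdata, ...) {
  ps <- if (is(newdata, "PeptideSet")) newdata else PeptideSet(sequence = newdata)
  Xf <- featurizePeptides(ps, object$backend)
  Xr <- applyReduction(object$reduction, Xf)
  probs <- classifierProbs(object$params, object$config, Xr)
  rownames(probs) <- peptideIds(ps)
  colnames(probs) <- 0:8
  probs
}

#' @rdname predict.acpClassifier
#' @param model An `acpClassifier`.
#' @export
predictClassifier <- function(model, newdata) predict.acpClassifier(model, newdata)
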