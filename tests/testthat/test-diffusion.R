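smallDiffCfg <- function(...) diffusionConfig(channels = 4L, timeDim = 8L, ...)

test_that("the linear schedule matches its closed forms and product oracle", {
  sch <- makeSchedule(1000L)
  ab <- scheduleAlphaBar(sch)
  expect_equal(ab[1], 1 - 1e-4)
  expect_true(all(diff(ab) < 0))
  # independent cumulative product
  expect_equal(ab, cumprod(1 - scheduleBeta(sch)), tolerance = 1e-12)
  expect_true(all(ab > 0 & ab <= 1))
  for (T in c(2L, 17L, 250L)) {
    s <- makeSchedule(T)
    expect_true(all(diff(scheduleAlphaBar(s)) < 0))
  }
  expect_error(makeSchedule(1L), ">= 2")
})

test_that("the forward draw follows x_t = sqrt(ab) x0 + sqrt(1-ab) eps", {
  # custom schedule with alphaBar[1] = 0.25
  sch <- new("DiffusionSchedule", steps = 2L, beta = c(0.75, 0.5),
             alpha = c(0.25, 0.5), alphaBar = c(0.25, 0.125))
  expect_equal(qSample(1, 1L, 1, sch), 0.5 + sqrt(0.75))   # 1.3660...
  # near-clean and near-noise limits
  lim <- makeSchedule(5000L)
  set.seed(99)
  x0 <- rnorm(4); eps <- rnorm(4)
  expect_equal(qSample(x0, 1L, eps, lim), x0, tolerance = 0.05)
  expect_equal(qSample(x0, 5000L, eps, lim), eps, tolerance = 0.05)
  expect_error(qSample(x0, 0L, eps, lim), "out of")
})

test_that("BFM is a residual sum of parallel convolution branches", {
  pf <- asNamespace("pepForge")
  cfg <- smallDiffCfg()
  p <- pf$initDenoiserParams(10L, 9L, cfg, 1L)
  x <- array(rnorm(2 * 4 * 1 * 10), c(2, 4, 1, 10))
  zero <- matrix(0, 2, 4)
  pz <- p
  for (k in cfg$bfmKernels) { pz[[paste0("bfm", k)]][] <- 0; pz[[paste0("bfmB", k)]][] <- 0 }
  expect_equal(bfmForward(x, zero, pz, cfg), x)               # zero kernels
  pd <- pz
  for (k in cfg$bfmKernels) {
    a <- pd[[paste0("bfm", k)]]
    mid <- (dim(a)[3] + 1) %/% 2
    for (i in 1:4) a[i, i, mid] <- 1
    pd[[paste0("bfm", k)]] <- a
  }
  expect_equal(bfmForward(x, zero, pd, cfg), 4 * x)           # three identities
  # random instance vs naive branch-by-branch convolution
  out <- bfmForward(x, zero, p, cfg)
  manual <- x
  for (k in cfg$bfmKernels)
    manual <- manual + naiveConvW(x, p[[paste0("bfm", k)]]) +
      rep(p[[paste0("bfmB", k)]], each = 2)
  expect_equal(out, manual, tolerance = 1e-6)
})

test_that("TFAM conserves beta_1 + beta_2 = 4 and matches its degenerate case", {
  pf <- asNamespace("pepForge")
  cfg <- smallDiffCfg()
  for (s in 1:3) {
    p <- pf$initDenoiserParams(12L, 9L, cfg, 100L + s)
    t1 <- array(rnorm(2 * 4 * 1 * 12, sd = 2), c(2, 4, 1, 12))
    t2 <- array(rnorm(96, sd = 2), c(2, 4, 1, 12))
    r <- tfamForward(t1, t2, p, cfg)
    # softmax pairs each sum to one, for any input and parameters
    expect_equal(r$alphaC1 + r$alphaC2, matrix(1, 2, 4))
    expect_equal(max(abs(r$alphaS1 + r$alphaS2 - 1)), 0, tolerance = 1e-12)
    expect_true(all(r$alphaC1 > 0 & r$alphaC1 < 1))
    expect_true(all(r$alphaS1 > 0 & r$alphaS1 < 1))
    # beta-weighted fusion identity, reassembled from the reported parts
    beta1 <- 1 + as.vector(r$alphaC1)
    manual <- r$t1hat + as.vector(r$alphaC1) * r$t1hat +
      r$t2hat + as.vector(r$alphaC2) * r$t2hat
    for (cc in 1:4) {
      manual[, cc, , ] <- manual[, cc, , ] +
        r$alphaS1[, 1, , ] * r$t1hat[, cc, , ] +
        r$alphaS2[, 1, , ] * r$t2hat[, cc, , ]
    }
    expect_equal(r$fused, manual, tolerance = 1e-9)
  }
  # zero attention convolutions + identity hats on an all-ones input
  p0 <- pf$initDenoiserParams(6L, 9L, cfg, 5L)
  for (nm in c("chA1", "chA1b", "chA2", "chA2b", "spA1", "spA1b", "spA2", "spA2b"))
    p0[[nm]][] <- 0
  for (i in 1:2) for (k in cfg$tfamKernels) {
    a <- p0[[paste0("tfam", i, "k", k)]] * 0
    if (k == 3) for (cc in 1:4) a[cc, cc, 2] <- 1    # T-hat = ReLU(x) = x here
    p0[[paste0("tfam", i, "k", k)]] <- a
    p0[[paste0("tfam", i, "b", k)]][] <- 0
  }
  ones <- array(1, c(1, 4, 1, 6))
  r0 <- tfamForward(ones, ones, p0, cfg)
  expect_equal(r0$alphaC1, matrix(0.5, 1, 4))
  expect_equal(r0$fused, 4 * ones)
})

test_that("denoiser training starts at the analytic loss level and descends", {
  mix <- generateFeatureMixture(matrix(c(1, -2), 1), counts = 200L, seed = 6L)
  cfg <- smallDiffCfg(trainSteps = 200L, seed = 6L)
  m <- trainDenoiser(mix$X, NULL, makeSchedule(500L), cfg)
  # untrained predictor outputs ~0, so the first MSE sits near E[eps^2] = 1
  expect_lt(abs(m$lossHistory[1] - 1), 0.35)
  expect_lt(mean(tail(m$lossHistory, 20)), m$lossHistory[1])
  m2 <- trainDenoiser(mix$X, NULL, makeSchedule(500L), cfg)
  expect_identical(m$lossHistory, m2$lossHistory)
})

test_that("the ODE sampler is exact for a point mass and stable in step count", {
  sch <- makeSchedule(1000L)
  ab <- scheduleAlphaBar(sch)
  x0 <- c(1.5, -2, 0.25)
  oracle <- function(x, tau) {
    i <- min(1000L, max(1L, round(tau * 1000)))
    sweep(x, 2, sqrt(ab[i]) * x0) / sqrt(1 - ab[i])
  }
  set.seed(7)
  z <- matrix(rnorm(15), 5, 3)
  r25 <- dpmSolverSample(z, oracle, sch, steps = 25L)
  expect_lt(max(abs(sweep(r25, 2, x0))), 1e-6)    # regardless of z
  rT <- dpmSolverSample(z, oracle, sch, steps = 250L)
  expect_lt(max(abs(r25 - rT)), 1e-4)
  expect_error(dpmSolverSample(z, oracle, sch, steps = 2000L), "exceeds")
})

test_that("a trained two-component mixture is recovered in proportion", {
  mix <- generateFeatureMixture(rbind(c(-4, 0), c(4, 0)),
                                counts = c(250L, 250L), seed = 11L)
  m <- trainDenoiser(mix$X, NULL, makeSchedule(), diffusionConfig(seed = 11L))
  set.seed(42)
  z <- matrix(rnorm(1000 * 2), 1000, 2)
  x0 <- dpmSolverSample(z, m, steps = 25L)
  xs <- sweep(sweep(x0, 2, m$scale, "*"), 2, m$center, "+")
  expect_lt(abs(mean(xs[, 1] > 0) - 0.5), 0.1)
})

test_that("the Markov decoder honours length, alphabet and determinism", {
  set.seed(12)
  z0 <- matrix(runif(6 * 420), 6, 420)
  g <- decodeToSequences(z0, seed = 3L)
  lens <- nchar(peptideSequences(g))
  expect_true(all(lens >= 8L & lens <= 50L))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", peptideSequences(g))))
  expect_identical(peptideSequences(decodeToSequences(z0, seed = 3L)),
                   peptideSequences(g))
  # deterministic A->C->A cycle dominates the smoothing mass
  zc <- rep(0, 420)
  zc[1] <- 1                                   # composition: start at A
  zc[20 + 2] <- 1e3                            # A -> C (row-major dipeptide)
  zc[20 + 21] <- 1e3                           # C -> A
  s <- peptideSequences(decodeToSequences(rbind(zc), seed = 4L))
  expect_match(s, "^(AC)+A?$")
  expect_warning(
    expect_warning(decodeToSequences(matrix(0, 1, 420), seed = 5L),
                   "composition"),
    "dipeptide")
})

test_that("generation tags labels, groups exports, and avoids training copies", {
  ps <- generatePeptideDataset(syntheticSpec(counts = rep(6L, 9L), seed = 13L,
                                             lengthRange = c(8L, 20L)))
  m <- trainGenerator(ps, smallDiffCfg(trainSteps = 8L, batchSize = 16L, seed = 13L))
  g7 <- generatePeptides(m, 7L, 10L, seed = 3L)
  expect_length(g7, 10L)
  expect_true(all(peptideLabels(g7) == 7L))
  expect_true(all(nchar(peptideSequences(g7)) >= 8L &
                  nchar(peptideSequences(g7)) <= 50L))
  expect_identical(peptideSequences(generatePeptides(m, 7L, 10L, seed = 3L)),
                   peptideSequences(g7))
  expect_error(generatePeptides(m, 11L, 5L), "unknown label")
  g1 <- generatePeptides(m, 1L, 5L, seed = 4L)
  both <- PeptideSet(id = c(peptideIds(g7), paste0("b", peptideIds(g1))),
                     sequence = c(peptideSequences(g7), peptideSequences(g1)),
                     label = c(peptideLabels(g7), peptideLabels(g1)))
  dir <- file.path(tempfile(), "gen")
  exportGeneration(both, dir)
  expect_true(file.exists(file.path(dir, "generated_label7.fasta")))
  expect_true(file.exists(file.path(dir, "generated_label1.fasta")))
  man <- read.csv(file.path(dir, "generation_manifest.csv"))
  expect_equal(nrow(man), 15L)
  f7 <- readPeptides(file.path(dir, "generated_label7.fasta"))
  expect_length(f7, 10L)
  # Markov decoding of freshly sampled latents does not copy training rows
  expect_false(any(peptideSequences(g7) %in% peptideSequences(ps)))
})
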