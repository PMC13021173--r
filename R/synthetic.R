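# Synthetic fixture generators: class-structured imbalanced peptide
# datasets (composition-biased, learnably separable) and labelled Gaussian
# feature mixtures for exercising the classifier and diffusion stacks
# without any external download.

# The default per-class counts scale the published nine-class sample sizes
# (110, 368, 231, 227, 105, 112, 288, 127, 171) by one half, preserving the
# >3:1 majority-to-minority imbalance profile at test-friendly size.
DEFAULT_CLASS_COUNTS <- c(55L, 184L, 116L, 114L, 53L, 56L, 144L, 64L, 86L)

#' Specification for a synthetic peptide dataset
#'
#' Each class draws residues i.i.d. from its own composition bias: a pair
#' of signature residues carries `biasMass` of the probability, the rest is
#' uniform; `separability` in `[0,1]` linearly mixes that bias with the
#' uniform distribution (1 = full bias). Lengths are uniform in
#' `lengthRange`.
#'
#' @param nClasses Number of classes (default 9).
#' @param counts Per-class record counts (default: half the published
#'   nine-class sizes, keeping the imbalance profile).
#' @param lengthRange Sequence length bounds (default 8..50).
#' @param biasMass Probability mass on the two signature residues
#'   (default 0.55).
#' @param separability Bias mixing knob in `[0,1]` (default 1).
#' @param seed Integer seed.
#' @return List of class `SyntheticSpec` (includes the per-class bias
#'   matrix `bias`, classes in rows).
#' @export
syntheticSpec <- function(nClasses = 9L, counts = NULL,
                          lengthRange = c(8L, 50L), biasMass = 0.55,
                          separability = 1, seed = 1L) {
  nClasses <- assertScalarCount(nClasses, "nClasses")
  if (is.null(counts))
    counts <- rep_len(DEFAULT_CLASS_COUNTS, nClasses)
  counts <- as.integer(counts)
  if (length(counts) != nClasses || any(counts < 2L))
    stop("need one count >= 2 per class", call. = FALSE)
  if (separability < 0 || separability > 1) stop("separability must be in [0,1]", call. = FALSE)
  sig <- t(vapply(seq_len(nClasses), function(k) {
    i <- ((k - 1L) * 2L) %% 20L
    AA_ALPHABET_20[c(i + 1L, (i + 1L) %% 20L + 1L)]
  }, character(2)))
  bias <- matrix(0, nClasses, 20L, dimnames = list(NULL, AA_ALPHABET_20))
  for (k in seq_len(nClasses)) {
    p <- rep((1 - biasMass) / 18, 20)
    p[match(sig[k, ], AA_ALPHABET_20)] <- biasMass / 2
    p <- separability * p + (1 - separability) * rep(1 / 20, 20)
    bias[k, ] <- p / sum(p)
  }
  structure(list(nClasses = nClasses, counts = counts,
                 lengthRange = as.integer(lengthRange), bias = bias,
                 signature = sig, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' @export
print.SyntheticSpec <- function(x, ...) {
  cat(sprintf("SyntheticSpec: %d classes, n=%d, lengths %d-%d\n",
              x$nClasses, sum(x$counts), x$lengthRange[1], x$lengthRange[2]))
  invisible(x)
}

#' Generate a synthetic labelled peptide dataset
#'
#' Sequences are drawn i.i.d. per class from the class bias distribution
#' with uniform lengths; per-class counts match the spec exactly and the
#' draw is deterministic given the seed.
#'
#' @param spec A [syntheticSpec()].
#' @return A labelled [PeptideSet-class] (labels 0-based, class order).
#' @export
generatePeptideDataset <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (any(abs(rowSums(spec$bias) - 1) > 1e-9) || any(spec$bias < 0))
    stop("bias rows must be probability distributions", call. = FALSE)
  seqs <- character(sum(spec$counts))
  labs <- integer(sum(spec$counts))
  at <- 0L
  withSeed(spec$seed, {
    for (k in seq_len(spec$nClasses)) {
      for (r in seq_len(spec$counts[k])) {
        at <- at + 1L
        L <- sample(spec$lengthRange[1]:spec$lengthRange[2], 1L)
        seqs[at] <- paste(sample(AA_ALPHABET_20, L, replace = TRUE,
                                 prob = spec$bias[k, ]), collapse = "")
        labs[at] <- k - 1L
      }
    }
  })
  PeptideSet(id = sprintf("syn%04d", seq_along(seqs)), sequence = seqs,
             label = labs, source = rep("synthetic", length(seqs)))
}

#' Generate a labelled Gaussian feature mixture
#'
#' Deterministic (seeded) draws from a Gaussian mixture, as a test harness
#' for the classifier and diffusion stacks.
#'
#' @param means Matrix, one component mean per row.
#' @param covariances List of covariance matrices (a single matrix is
#'   recycled; defaults to identity).
#' @param counts Samples per component.
#' @param seed Integer seed.
#' @return List with `X` (feature matrix) and `y` (0-based component
#'   labels).
#' @export
generateFeatureMixture <- function(means, covariances = NULL, counts,
                                   seed = 1L) {
  means <- as.matrix(means)
  k <- nrow(means); d <- ncol(means)
  counts <- as.integer(rep_len(counts, k))
  if (is.null(covariances)) covariances <- list(diag(d))
  if (is.matrix(covariances)) covariances <- list(covariances)
  covariances <- rep_len(covariances, k)
  chols <- lapply(covariances, function(S) {
    S <- as.matrix(S)
    ch <- tryCatch(chol(S), error = function(e)
      stop("covariance not positive definite", call. = FALSE))
    ch
  })
  X <- matrix(0, sum(counts), d); y <- integer(sum(counts)); at <- 0L
  withSeed(seed, {
    for (j in seq_len(k)) {
      Z <- matrix(rnorm(counts[j] * d), counts[j], d)
      X[at + seq_len(counts[j]), ] <- Z %*% chols[[j]] +
        matrix(means[j, ], counts[j], d, byrow = TRUE)
      y[at + seq_len(counts[j])] <- j - 1L
      at <- at + counts[j]
    }
  })
  list(X = X, y = y)
}
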