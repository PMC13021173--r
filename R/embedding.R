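# Sequence embeddings, feature fusion and PCA reduction.
#
# Two embedding backends share one contract: 1024 finite numbers per
# sequence, deterministic for deterministic backends. The default backend
# hashes overlapping 3-mers into 4096 buckets and projects them through a
# fixed-seed Gaussian matrix, then L2-normalises; it needs no model download
# and is bit-reproducible. A ProtBERT adapter slot exists for environments
# where the pretrained model is available.

EMBED_DIM <- 1024L
HASH_BUCKETS <- 4096L

.pkgCache <- new.env(parent = emptyenv())

#' k-mer hashing embedding backend
#'
#' Deterministic 1024-dimensional embedding: overlapping 3-mers are hashed
#' into 4096 count buckets, projected through a fixed-seed N(0, 1/4096)
#' matrix and L2-normalised.
#'
#' @param seed Integer seed fixing the projection matrix (default 1).
#' @return An `EmbeddingBackend` object.
#' @export
kmerBackend <- function(seed = 1L) {
  structure(list(name = "kmer-hash", dimension = EMBED_DIM,
                 deterministic = TRUE, seed = as.integer(seed)),
            class = "EmbeddingBackend")
}

#' ProtBERT adapter backend
#'
#' Placeholder for the mean-pooled last-hidden-state embedding of the
#' pretrained ProtBERT model. The pretrained weights are not bundled; calling
#' [embedSequence()] with this backend raises an explicit error directing to
#' [kmerBackend()] rather than silently substituting.
#'
#' @return An `EmbeddingBackend` object.
#' @export
protBertBackend <- function() {
  structure(list(name = "protbert", dimension = EMBED_DIM,
                 deterministic = TRUE, seed = NA_integer_),
            class = "EmbeddingBackend")
}

#' @export
print.EmbeddingBackend <- function(x, ...) {
  cat(sprintf("EmbeddingBackend '%s' (%d-dim, %s)\n", x$name, x$dimension,
              if (isTRUE(x$deterministic)) "deterministic" else "stochastic"))
  invisible(x)
}

projectionMatrix <- function(seed) {
  key <- paste0("proj", seed)
  if (is.null(.pkgCache[[key]])) {
    .pkgCache[[key]] <- withSeed(seed, matrix(
      rnorm(HASH_BUCKETS * EMBED_DIM, sd = 1 / sqrt(HASH_BUCKETS)),
      nrow = HASH_BUCKETS))
  }
  .pkgCache[[key]]
}

kmerCounts <- function(seq) {
  ch <- seqChars(seq)
  v <- numeric(HASH_BUCKETS)
  L <- length(ch)
  if (L >= 3) {
    idx <- match(ch, AA_ALPHABET_20) - 1L
    code <- (idx[1:(L - 2)] * 20L + idx[2:(L - 1)]) * 20L + idx[3:L]
    tb <- table(code %% HASH_BUCKETS)
    v[as.integer(names(tb)) + 1L] <- as.numeric(tb)
  }
  v
}

#' Embed a sequence
#'
#' @param seq Peptide sequence.
#' @param backend An `EmbeddingBackend` (default [kmerBackend()]).
#' @return Numeric vector of length 1024.
#' @export
embedSequence <- function(seq, backend = kmerBackend()) {
  stopifnot(inherits(backend, "EmbeddingBackend"))
  if (backend$name == "protbert")
    stop(paste("ProtBERT weights are not available in this installation;",
               "use kmerBackend() instead"), call. = FALSE)
  v <- as.numeric(kmerCounts(seq) %*% projectionMatrix(backend$seed))
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Embed a peptide set
#'
#' @param x A [PeptideSet-class] or character vector of sequences.
#' @inheritParams embedSequence
#' @return Numeric matrix `n x 1024` with rows named by peptide id.
#' @export
embedPeptides <- function(x, backend = kmerBackend()) {
  stopifnot(inherits(backend, "EmbeddingBackend"))
  if (backend$name == "protbert")
    stop(paste("ProtBERT weights are not available in this installation;",
               "use kmerBackend() instead"), call. = FALSE)
  seqs <- if (is(x, "PeptideSet")) peptideSequences(x) else as.character(x)
  cnt <- t(vapply(seqs, kmerCounts, numeric(HASH_BUCKETS)))
  m <- cnt %*% projectionMatrix(backend$seed)
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m <- m / nrm
  rownames(m) <- if (is(x, "PeptideSet")) peptideIds(x) else names(seqs)
  m
}

#' Fuse embedding with descriptors
#'
#' Concatenates a 1024-dimensional embedding with a 430-dimensional
#' descriptor vector (embedding first) into the 1454-dimensional fused
#' representation. Also accepts matrices with matching row counts.
#'
#' @param embedding Numeric vector of length 1024 or matrix `n x 1024`.
#' @param descriptors Numeric vector of length 430 or matrix `n x 430`.
#' @return Fused vector of length 1454 or matrix `n x 1454`.
#' @export
fuseFeatures <- function(embedding, descriptors) {
  if (is.matrix(embedding) || is.matrix(descriptors)) {
    embedding <- as.matrix(embedding); descriptors <- as.matrix(descriptors)
    if (ncol(embedding) != EMBED_DIM || ncol(descriptors) != 430L ||
        nrow(embedding) != nrow(descriptors))
      stop("dimension mismatch: need n x 1024 and n x 430", call. = FALSE)
    return(cbind(embedding, descriptors))
  }
  if (length(embedding) != EMBED_DIM || length(descriptors) != 430L)
    stop("dimension mismatch: need 1024-dim embedding and 430-dim descriptors",
         call. = FALSE)
  c(as.numeric(embedding), as.numeric(descriptors))
}

#' Featurize a peptide set
#'
#' Convenience wrapper: embeddings plus descriptors, fused to `n x 1454`.
#'
#' @param x A [PeptideSet-class].
#' @inheritParams embedSequence
#' @return Numeric matrix `n x 1454`.
#' @export
featurizePeptides <- function(x, backend = kmerBackend()) {
  fuseFeatures(embedPeptides(x, backend), descriptorMatrix(x))
}

#' Fit the standardize-then-PCA reduction
#'
#' Columns are z-scored (zero-variance columns get unit scale), then
#' principal components of the standardized matrix are extracted by exact
#' SVD, without whitening. Component signs are fixed by making the
#' largest-magnitude loading positive. Fit on training partitions only and
#' apply to held-out data with [applyReduction()].
#'
#' @param X Numeric matrix, samples in rows (needs more rows than
#'   `nComponents`).
#' @param nComponents Number of components to keep (default 200).
#' @return A `ReductionModel` with elements `center`, `scale`, `rotation`
#'   (`ncol(X) x nComponents`), `varianceRatio`, and `formatVersion`.
#' @export
fitReduction <- function(X, nComponents = 200L) {
  X <- as.matrix(X)
  nComponents <- assertScalarCount(nComponents, "nComponents")
  if (nrow(X) < nComponents + 1L)
    stop(sprintf("need at least %d samples to fit %d components",
                 nComponents + 1L, nComponents), call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  sv <- svd(Z, nu = 0, nv = min(dim(Z)))
  totVar <- sum(sv$d^2)
  keep <- seq_len(min(nComponents, length(sv$d)))
  rot <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude loading of each component positive
  for (j in seq_along(keep)) {
    m <- which.max(abs(rot[, j]))
    if (rot[m, j] < 0) rot[, j] <- -rot[, j]
  }
  if (length(keep) < nComponents) {
    # rank-deficient input: pad with zero loadings so output stays nComponents
    rot <- cbind(rot, matrix(0, nrow(rot), nComponents - length(keep)))
  }
  vr <- (sv$d^2 / totVar)[seq_len(min(nComponents, length(sv$d)))]
  if (length(vr) < nComponents) vr <- c(vr, rep(0, nComponents - length(vr)))
  structure(list(center = ctr, scale = scl, rotation = rot,
                 varianceRatio = vr, formatVersion = 1L),
            class = "ReductionModel")
}

#' @export
print.ReductionModel <- function(x, ...) {
  cat(sprintf("ReductionModel: %d -> %d dims, cumulative variance %.3f\n",
              length(x$center), ncol(x$rotation), sum(x$varianceRatio)))
  invisible(x)
}

#' Apply a fitted reduction
#'
#' Standardizes with the fitted center/scale and projects onto the stored
#' components. Deterministic.
#'
#' @param model A `ReductionModel` from [fitReduction()].
#' @param x Numeric vector of raw fused features, or matrix with samples in
#'   rows.
#' @return Reduced vector / matrix with `ncol(rotation)` columns.
#' @export
applyReduction <- function(model, x) {
  stopifnot(inherits(model, "ReductionModel"))
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != length(model$center))
    stop(sprintf("expected %d columns, got %d (already reduced?)",
                 length(model$center), ncol(X)), call. = FALSE)
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  Y <- Z %*% model$rotation
  if (vec) as.numeric(Y) else Y
}

#' Serialize / restore a reduction model
#'
#' Plain-text JSON archive carrying center, scale, components and variance
#' ratios with a format-version field.
#'
#' @param model A `ReductionModel`.
#' @param path Output path.
#' @return `path` (write) or the restored model (read).
#' @export
writeReduction <- function(model, path) {
  stopifnot(inherits(model, "ReductionModel"))
  obj <- list(formatVersion = model$formatVersion, center = model$center,
              scale = model$scale, rotation = as.numeric(model$rotation),
              dims = dim(model$rotation), varianceRatio = model$varianceRatio)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeReduction
#' @export
readReduction <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(center = obj$center, scale = obj$scale,
                 rotation = matrix(obj$rotation, obj$dims[1], obj$dims[2]),
                 varianceRatio = obj$varianceRatio,
                 formatVersion = as.integer(obj$formatVersion)),
            class = "ReductionModel")
}
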