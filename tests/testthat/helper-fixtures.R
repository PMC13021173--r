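# Shared fixtures and independent oracles used across the suite.

# Brute-force local alignment oracle: enumerate every monotone set of
# substitution columns; residues between consecutive columns cost one
# affine gap run per sequence (gapOpen + gapExtend per residue). Optimal
# local alignments never start or end with gap columns, so this sweep is
# exhaustive for short sequences.
bruteLocalAlign <- function(a, b, mat, gapOpen, gapExtend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  best <- 0
  for (k in seq_len(min(n, m))) {
    ia <- utils::combn(n, k, simplify = FALSE)
    ib <- utils::combn(m, k, simplify = FALSE)
    for (A in ia) for (B in ib) {
      sc <- sum(mat[cbind(ca[A], cb[B])])
      if (k > 1) {
        da <- diff(A) - 1L; db <- diff(B) - 1L
        sc <- sc - sum(ifelse(da > 0, gapOpen + gapExtend * da, 0)) -
          sum(ifelse(db > 0, gapOpen + gapExtend * db, 0))
      }
      if (sc > best) best <- sc
    }
  }
  best
}

# Plain 1-D "same"-padded channel-mixing convolution, written directly from
# the definition, as an independent check of the optimized implementation.
naiveConvW <- function(X, K) {
  d <- dim(X); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  O <- dim(K)[1]; kw <- dim(K)[3]; off <- (kw - 1) %/% 2
  out <- array(0, c(B, O, H, W))
  for (b in seq_len(B)) for (o in seq_len(O)) for (h in seq_len(H))
    for (w in seq_len(W)) {
      acc <- 0
      for (cc in seq_len(C)) for (tap in seq_len(kw)) {
        ws <- w + tap - 1L - off
        if (ws >= 1 && ws <= W) acc <- acc + K[o, cc, tap] * X[b, cc, h, ws]
      }
      out[b, o, h, w] <- acc
    }
  out
}

# Small labelled peptide fixture.
tinyPeptides <- function() {
  PeptideSet(id = c("p1", "p2", "p3"),
             sequence = c("LQENDRAT", "ITFIQFRMIH", "PTARVIVWVYRCI"),
             label = c(1L, 0L, 1L),
             source = c("ref", NA, "ref"))
}

# Pairwise-count AUC oracle: P(score_pos > score_neg) + 0.5 P(tie), by
# direct enumeration of all positive/negative pairs.
pairwiseAucOracle <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (s in sp) tot <- tot + sum(s > sn) + 0.5 * sum(s == sn)
  tot / (length(sp) * length(sn))
}
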