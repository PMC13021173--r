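# Post-generation screening: local alignment novelty scan, motif summary,
# helical-wheel projection.

#' BLOSUM62 substitution matrix
#'
#' The classic protein substitution matrix, taken from Biostrings' shipped
#' copy and restricted to the 20 canonical residues.
#'
#' @return Integer 20x20 matrix.
#' @export
blosum62 <- function() {
  if (is.null(.pkgCache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkgCache$blosum62 <- e$BLOSUM62[AA_ALPHABET_20, AA_ALPHABET_20]
  }
  .pkgCache$blosum62
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment under the Gotoh recurrences. A gap of length L
#' costs `gapOpen + L * gapExtend`. Traceback reports one optimal alignment
#' with deterministic tie-breaking (diagonal over up over left, and the
#' highest-scoring cell closest to the origin). Identity, positive and gap
#' percentages are computed over aligned columns including gaps
#' (denominator = alignment length).
#'
#' @param a,b Peptide sequences.
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gapOpen,gapExtend Positive gap penalties (defaults 11 and 1).
#' @return List of class `AlignmentResult`: `score`, `startA`/`endA`,
#'   `startB`/`endB` (1-based inclusive; 0 for an empty alignment),
#'   `alignedA`, `alignedB` (gapped strings), `identity`, `positive`,
#'   `gaps` (percentages), `length`.
#' @export
smithWaterman <- function(a, b, matrix = blosum62(), gapOpen = 11,
                          gapExtend = 1) {
  if (gapOpen <= 0 || gapExtend <= 0) stop("gap penalties must be positive", call. = FALSE)
  emptyRes <- structure(list(score = 0, startA = 0L, endA = 0L, startB = 0L,
                             endB = 0L, alignedA = "", alignedB = "",
                             identity = NA_real_, positive = NA_real_,
                             gaps = NA_real_, length = 0L),
                        class = "AlignmentResult")
  if (!nzchar(gsub("[[:space:]]", "", a)) || !nzchar(gsub("[[:space:]]", "", b)))
    return(emptyRes)
  ca <- seqChars(a); cb <- seqChars(b)
  n <- length(ca); m <- length(cb)
  S <- matrix[ca, cb, drop = FALSE]            # n x m substitution scores
  H <- matrix(0, n + 1, m + 1)                 # best local score ending at (i,j)
  E <- matrix(-Inf, n + 1, m + 1)              # gap in a (left moves)
  Fm <- matrix(-Inf, n + 1, m + 1)             # gap in b (up moves)
  for (j in 2:(m + 1)) {
    Hprev <- H[, j - 1]
    for (i in 2:(n + 1)) {
      E[i, j] <- max(Hprev[i] - gapOpen - gapExtend, E[i, j - 1] - gapExtend)
      Fm[i, j] <- max(H[i - 1, j] - gapOpen - gapExtend, Fm[i - 1, j] - gapExtend)
      H[i, j] <- max(0, Hprev[i - 1] + S[i - 1, j - 1], Fm[i, j], E[i, j])
    }
  }
  best <- max(H)
  if (best <= 0) return(emptyRes)
  hits <- which(H == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- hits[1, 1]; j <- hits[1, 2]
  endA <- i - 1L; endB <- j - 1L
  alnA <- character(0); alnB <- character(0)
  state <- "H"
  while (TRUE) {
    if (state == "H") {
      if (H[i, j] == 0) break
      diag <- H[i - 1, j - 1] + S[i - 1, j - 1]
      if (H[i, j] == diag) {
        alnA <- c(ca[i - 1], alnA); alnB <- c(cb[j - 1], alnB)
        i <- i - 1L; j <- j - 1L
      } else if (H[i, j] == Fm[i, j]) state <- "F"
      else state <- "E"
    } else if (state == "F") {        # gap in b: consume a
      alnA <- c(ca[i - 1], alnA); alnB <- c("-", alnB)
      cur <- Fm[i, j]
      i <- i - 1L
      if (cur == H[i, j] - gapOpen - gapExtend) state <- "H"  # gap opened here
    } else {                          # gap in a: consume b
      alnA <- c("-", alnA); alnB <- c(cb[j - 1], alnB)
      cur <- E[i, j]
      j <- j - 1L
      if (cur == H[i, j] - gapOpen - gapExtend) state <- "H"
    }
  }
  L <- length(alnA)
  ident <- sum(alnA == alnB & alnA != "-")
  ng <- alnA != "-" & alnB != "-"
  posit <- if (any(ng)) sum(matrix[cbind(alnA[ng], alnB[ng])] > 0) else 0L
  gapc <- sum(alnA == "-" | alnB == "-")
  structure(list(score = best, startA = i, endA = endA, startB = j,
                 endB = endB, alignedA = paste(alnA, collapse = ""),
                 alignedB = paste(alnB, collapse = ""),
                 identity = 100 * ident / L, positive = 100 * posit / L,
                 gaps = 100 * gapc / L, length = L),
            class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("AlignmentResult: score %.1f, a[%d-%d] vs b[%d-%d]\n",
              x$score, x$startA, x$endA, x$startB, x$endB))
  if (x$length) {
    cat("  ", x$alignedA, "\n  ", x$alignedB, "\n", sep = "")
    cat(sprintf("  identity %.1f%%, positive %.1f%%, gaps %.1f%%\n",
                x$identity, x$positive, x$gaps))
  }
  invisible(x)
}

#' Novelty scan against a reference set
#'
#' For each candidate, the maximum-scoring local alignment over all
#' references. Candidates whose identity over the aligned region reaches
#' 90% (inclusive) AND whose alignment covers the full candidate length are
#' flagged as near-duplicates; shorter high-identity local hits are
#' reported but not flagged.
#'
#' @param candidates,reference [PeptideSet-class] objects or character
#'   vectors.
#' @inheritParams smithWaterman
#' @param flagIdentity Near-duplicate threshold in percent (default 90,
#'   boundary inclusive).
#' @return data.frame with one row per candidate: `candidate_id`,
#'   `best_hit`, `score`, `identity`, `positive`, `gaps`, `flagged`.
#' @export
noveltyScan <- function(candidates, reference, matrix = blosum62(),
                        gapOpen = 11, gapExtend = 1, flagIdentity = 90) {
  cs <- if (is(candidates, "PeptideSet")) peptideSequences(candidates) else as.character(candidates)
  cid <- if (is(candidates, "PeptideSet")) peptideIds(candidates) else
    (names(candidates) %||% sprintf("cand%d", seq_along(cs)))
  rs <- if (is(reference, "PeptideSet")) peptideSequences(reference) else as.character(reference)
  rid <- if (is(reference, "PeptideSet")) peptideIds(reference) else
    (names(reference) %||% sprintf("ref%d", seq_along(rs)))
  if (!length(rs)) stop("reference set is empty", call. = FALSE)
  rows <- lapply(seq_along(cs), function(i) {
    bestScore <- -Inf; best <- NULL; bestRef <- NA_character_
    for (r in seq_along(rs)) {
      al <- smithWaterman(cs[i], rs[r], matrix, gapOpen, gapExtend)
      if (al$score > bestScore) { bestScore <- al$score; best <- al; bestRef <- rid[r] }
    }
    covered <- best$length > 0 && (best$endA - best$startA + 1L) == nchar(cs[i]) &&
      best$gaps == 0
    flagged <- covered && !is.na(best$identity) && best$identity >= flagIdentity
    data.frame(candidate_id = cid[i], best_hit = bestRef, score = best$score,
               identity = best$identity, positive = best$positive,
               gaps = best$gaps, flagged = flagged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Motif summary
#'
#' Counts of basic (K/R) and aromatic (W/F/Y) residues, the qualitative
#' aromatic-basic proximity call (`strong` when at least two
#' aromatic-basic pairs lie within 3 positions, `present` for one,
#' `absent` otherwise), and the amphipathic moment: the maximum helical
#' hydrophobic moment over all 11-residue windows (whole sequence when
#' shorter).
#'
#' @param seq Peptide sequence.
#' @param scale Hydrophobicity table for the moment (default Eisenberg).
#' @return List of class `MotifSummary`: `basic_count`,
#'   `basic_breakdown`, `aromatic_count`, `aromatic_breakdown`,
#'   `proximity`, `amphipathic_moment`.
#' @export
motifSummary <- function(seq, scale = EISENBERG_SCALE) {
  ch <- seqChars(seq)
  L <- length(ch)
  bas <- table(factor(ch[ch %in% c("K", "R")], levels = c("K", "R")))
  aro <- table(factor(ch[ch %in% c("W", "F", "Y")], levels = c("W", "F", "Y")))
  np <- aromaticBasicPairs(ch)
  win <- min(11L, L)
  s <- validateSequence(seq)
  moments <- vapply(seq_len(L - win + 1L), function(k)
    hydrophobicMoment(substr(s, k, k + win - 1L), scale), numeric(1))
  structure(list(
    basic_count = sum(bas), basic_breakdown = c(bas),
    aromatic_count = sum(aro), aromatic_breakdown = c(aro),
    proximity = if (np >= 2L) "strong" else if (np >= 1L) "present" else "absent",
    amphipathic_moment = max(moments)), class = "MotifSummary")
}

#' @export
print.MotifSummary <- function(x, ...) {
  bb <- x$basic_breakdown[x$basic_breakdown > 0]
  ab <- x$aromatic_breakdown[x$aromatic_breakdown > 0]
  fmt <- function(v) if (length(v)) paste0(" (", paste0(names(v), v, collapse = ", "), ")") else ""
  cat(sprintf("MotifSummary: basic %d%s, aromatic %d%s, proximity %s, muH(best window) %.2f\n",
              x$basic_count, fmt(bb), x$aromatic_count, fmt(ab),
              x$proximity, x$amphipathic_moment))
  invisible(x)
}

#' Motif table for a peptide set
#'
#' One row per peptide in the reporting layout (peptide, length, basic and
#' aromatic counts with breakdowns, proximity call, best-window moment).
#'
#' @param x A [PeptideSet-class] or character vector.
#' @inheritParams motifSummary
#' @return data.frame.
#' @export
motifTable <- function(x, scale = EISENBERG_SCALE) {
  seqs <- if (is(x, "PeptideSet")) peptideSequences(x) else as.character(x)
  ids <- if (is(x, "PeptideSet")) peptideIds(x) else
    (names(seqs) %||% sprintf("pep%d", seq_along(seqs)))
  rows <- lapply(seq_along(seqs), function(i) {
    ms <- motifSummary(seqs[i], scale)
    bb <- ms$basic_breakdown[ms$basic_breakdown > 0]
    ab <- ms$aromatic_breakdown[ms$aromatic_breakdown > 0]
    fmt <- function(v) if (length(v)) paste0(names(v), v, collapse = " ") else ""
    data.frame(peptide = ids[i], length = nchar(seqs[i]),
               basic = ms$basic_count, basic_breakdown = fmt(bb),
               aromatic = ms$aromatic_count, aromatic_breakdown = fmt(ab),
               proximity = ms$proximity,
               amphipathic_moment = round(ms$amphipathic_moment, 3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Helical wheel projection
#'
#' Places residue k (0-based) at `(100 k) mod 360` degrees and annotates
#' each with its hydrophobicity and residue class (hydrophobic, basic,
#' acidic, polar) — a plot-ready table for amphipathicity inspection.
#'
#' @param seq Peptide sequence.
#' @param scale Hydrophobicity table (default Eisenberg).
#' @return data.frame with columns `position`, `residue`, `angle`
#'   (degrees), `hydrophobicity`, `class`.
#' @export
helicalWheel <- function(seq, scale = EISENBERG_SCALE) {
  ch <- seqChars(seq)
  cls <- ifelse(ch %in% c("A", "C", "F", "I", "L", "M", "V", "W", "Y"), "hydrophobic",
         ifelse(ch %in% c("K", "R", "H"), "basic",
         ifelse(ch %in% c("D", "E"), "acidic", "polar")))
  data.frame(position = seq_along(ch), residue = ch,
             angle = (100 * (seq_along(ch) - 1L)) %% 360,
             hydrophobicity = as.numeric(scale[ch]), class = cls,
             stringsAsFactors = FALSE)
}
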