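# The 430-dimensional physicochemical descriptor block and the standalone
# global properties used when profiling candidate peptides.
#
# Layout of a descriptor vector: 20 amino-acid composition entries, 400
# dipeptide frequencies (row-major over the fixed alphabet), then 10 global
# properties. All sequence-level statistics use the alphabetical residue
# order from aminoAcidAlphabet().

#' Default ionization constants
#'
#' Side-chain pKa values for D, E, C, Y, H, K, R plus the free terminal
#' alpha-amino and alpha-carboxyl groups, in pH units. This set reproduces
#' the published net charges of the reference peptides to two decimals.
#'
#' @return Named list with entries `nterm`, `cterm`, `D`, `E`, `C`, `Y`,
#'   `H`, `K`, `R`.
#' @export
defaultPKaSet <- function() {
  list(nterm = 8.0, cterm = 3.1, D = 3.65, E = 4.25, C = 8.3,
       H = 6.0, Y = 10.07, K = 10.5, R = 12.5)
}

checkPKaSet <- function(pka) {
  need <- c("nterm", "cterm", "D", "E", "C", "Y", "H", "K", "R")
  if (!all(need %in% names(pka))) stop("incomplete pKa set", call. = FALSE)
  v <- unlist(pka[need])
  if (any(v <= 0) || any(v >= 14)) stop("pKa values must lie in (0, 14)", call. = FALSE)
  pka
}

seqChars <- function(seq) strsplit(validateSequence(seq), "", fixed = TRUE)[[1]]

#' Amino-acid composition
#'
#' Fraction of each of the 20 canonical residues, in fixed alphabetical
#' order; entries sum to one.
#'
#' @param seq Peptide sequence.
#' @return Named numeric vector of length 20.
#' @examples
#' aminoAcidComposition("ACAC")
#' @export
aminoAcidComposition <- function(seq) {
  ch <- seqChars(seq)
  tab <- table(factor(ch, levels = AA_ALPHABET_20))
  as.numeric(tab) / length(ch) -> v
  names(v) <- AA_ALPHABET_20
  v
}

#' Dipeptide frequency
#'
#' Frequency of each ordered residue pair among adjacent positions,
#' normalised by (length - 1); row-major over the fixed alphabet (all AX
#' pairs first). A length-1 sequence yields the all-zero vector.
#'
#' @param seq Peptide sequence.
#' @return Named numeric vector of length 400.
#' @export
dipeptideFrequency <- function(seq) {
  ch <- seqChars(seq)
  nm <- as.vector(t(outer(AA_ALPHABET_20, AA_ALPHABET_20, paste0)))
  v <- stats::setNames(numeric(400), nm)
  L <- length(ch)
  if (L >= 2) {
    pairs <- paste0(ch[-L], ch[-1])
    tb <- table(pairs)
    v[names(tb)] <- as.numeric(tb) / (L - 1)
  }
  v
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch sum: each basic group (N-terminus, H, K, R)
#' contributes `1/(1+10^(pH-pKa))`, each acidic group (C-terminus, D, E, C,
#' Y) contributes `-1/(1+10^(pKa-pH))`.
#'
#' @param seq Peptide sequence.
#' @param pH pH at which to evaluate the charge (default 7.0).
#' @param pka Ionization constants, see [defaultPKaSet()].
#' @return Net charge in elementary charge units.
#' @examples
#' netCharge("LQENDRAT")   # about -1.09
#' @export
netCharge <- function(seq, pH = 7.0, pka = defaultPKaSet()) {
  if (!is.numeric(pH) || pH <= 0 || pH >= 14) stop("pH must lie in (0, 14)", call. = FALSE)
  pka <- checkPKaSet(pka)
  ch <- seqChars(seq)
  basic <- function(p) 1 / (1 + 10^(pH - p))
  acidic <- function(p) 1 / (1 + 10^(p - pH))
  pos <- basic(pka$nterm) +
    sum(ch == "H") * basic(pka$H) +
    sum(ch == "K") * basic(pka$K) +
    sum(ch == "R") * basic(pka$R)
  neg <- acidic(pka$cterm) +
    sum(ch == "D") * acidic(pka$D) +
    sum(ch == "E") * acidic(pka$E) +
    sum(ch == "C") * acidic(pka$C) +
    sum(ch == "Y") * acidic(pka$Y)
  pos - neg
}

#' Isoelectric point
#'
#' pH at which the net charge crosses zero, located by bisection on (0, 14).
#' The Henderson-Hasselbalch charge is strictly decreasing in pH and the two
#' termini guarantee a sign change, so the root is unique.
#'
#' @inheritParams netCharge
#' @param tol Bisection stops once `|charge| < tol` (default 1e-4).
#' @return pI in pH units.
#' @export
isoelectricPoint <- function(seq, pka = defaultPKaSet(), tol = 1e-4) {
  lo <- 1e-6; hi <- 14 - 1e-6
  f <- function(p) netCharge(seq, p, pka)
  # bisect the pH interval down to 1e-7 (not just the charge residual: the
  # charge curve can be nearly flat near the root, so a loose residual stop
  # would leave the pH itself imprecise)
  while (hi - lo > 1e-7) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  if (abs(f(mid)) >= tol)
    warning("charge residual at pI exceeds tolerance", call. = FALSE)
  mid
}

#' Hydrophobic moment
#'
#' First-moment amphipathicity measure: residues are placed on a helix at
#' `angle` degrees per step (100 for an alpha helix) and their scale values
#' summed as unit vectors; the norm is divided by the length.
#'
#' @param seq Peptide sequence.
#' @param scale Named hydrophobicity table (default Eisenberg consensus).
#' @param angle Rotation per residue in degrees (default 100).
#' @return Non-negative moment in scale units.
#' @export
hydrophobicMoment <- function(seq, scale = EISENBERG_SCALE, angle = 100) {
  ch <- seqChars(seq)
  if (any(!(ch %in% names(scale)))) stop("residue missing from hydrophobicity scale", call. = FALSE)
  h <- scale[ch]
  k <- seq_along(ch)          # angle k*delta for residue k, matching the
  delta <- angle * pi / 180   # one-term |h| norm for a single residue
  sqrt(sum(h * cos(k * delta))^2 + sum(h * sin(k * delta))^2) / length(ch)
}

#' Instability index
#'
#' Guruprasad dipeptide-weight statistic `(10/L) * sum DIWV(s_k, s_{k+1})`.
#' Length-1 sequences score 0.
#'
#' @param seq Peptide sequence.
#' @return Dimensionless instability index.
#' @export
instabilityIndex <- function(seq) {
  ch <- seqChars(seq)
  L <- length(ch)
  if (L < 2) return(0)
  (10 / L) * sum(DIWV_TABLE[cbind(ch[-L], ch[-1])])
}

aromaticBasicPairs <- function(ch, window = 3L) {
  arom <- which(ch %in% c("W", "F", "Y"))
  bas <- which(ch %in% c("K", "R"))
  if (!length(arom) || !length(bas)) return(0L)
  sum(abs(outer(arom, bas, "-")) <= window)
}

#' Global physicochemical properties
#'
#' The scalar properties used when profiling peptides: length, monoisotopic
#' molecular weight (sum of free amino-acid masses minus one water per
#' bond), net charge at the stated pH, isoelectric point, mean
#' hydrophobicity (GRAVY-style over the chosen scale), helical hydrophobic
#' moment, Guruprasad instability index and aromaticity (fraction of
#' F/W/Y).
#'
#' @inheritParams netCharge
#' @param scale Hydrophobicity table (default Eisenberg consensus).
#' @return Named list of class `GlobalProperties`.
#' @export
globalProperties <- function(seq, pH = 7.0, pka = defaultPKaSet(),
                             scale = EISENBERG_SCALE) {
  ch <- seqChars(seq)
  L <- length(ch)
  out <- list(
    length = L,
    molecular_weight = sum(AA_MONO_MASS[ch]) - (L - 1) * WATER_MONO_MASS,
    net_charge = netCharge(seq, pH, pka),
    isoelectric_point = isoelectricPoint(seq, pka),
    gravy = mean(scale[ch]),
    hydrophobic_moment = hydrophobicMoment(seq, scale),
    instability_index = instabilityIndex(seq),
    aromaticity = mean(ch %in% c("F", "W", "Y")))
  class(out) <- "GlobalProperties"
  out
}

#' @export
print.GlobalProperties <- function(x, ...) {
  cat(sprintf(paste0("GlobalProperties: L=%d MW=%.2f charge=%.2f pI=%.2f ",
                     "H=%.2f muH=%.2f II=%.1f arom=%.2f\n"),
              x$length, x$molecular_weight, x$net_charge, x$isoelectric_point,
              x$gravy, x$hydrophobic_moment, x$instability_index, x$aromaticity))
  invisible(x)
}

#' Full 430-dimensional descriptor vector
#'
#' Concatenation `[composition(20) | dipeptide(400) | global(10)]`. The
#' global segment is (length, molecular weight, net charge at pH 7,
#' isoelectric point, mean hydrophobicity, hydrophobic moment, instability
#' index, aromaticity, basic-residue fraction, aromatic-basic proximity
#' count within 3 positions).
#'
#' @inheritParams globalProperties
#' @return Named numeric vector of length 430.
#' @export
physchemVector <- function(seq, pka = defaultPKaSet(), scale = EISENBERG_SCALE) {
  ch <- seqChars(seq)
  gp <- globalProperties(seq, 7.0, pka, scale)
  glob <- c(length = gp$length, molecular_weight = gp$molecular_weight,
            net_charge = gp$net_charge, isoelectric_point = gp$isoelectric_point,
            gravy = gp$gravy, hydrophobic_moment = gp$hydrophobic_moment,
            instability_index = gp$instability_index, aromaticity = gp$aromaticity,
            basic_fraction = mean(ch %in% c("K", "R")),
            aromatic_basic_pairs = aromaticBasicPairs(ch))
  c(aminoAcidComposition(seq), dipeptideFrequency(seq), glob)
}

#' Descriptor matrix for a peptide set
#'
#' One 430-column row per peptide; rows keep the input order and are named
#' by peptide id.
#'
#' @param x A [PeptideSet-class] or character vector of sequences.
#' @inheritParams physchemVector
#' @return Numeric matrix `n x 430`.
#' @export
descriptorMatrix <- function(x, pka = defaultPKaSet(), scale = EISENBERG_SCALE) {
  seqs <- if (is(x, "PeptideSet")) peptideSequences(x) else as.character(x)
  ids <- if (is(x, "PeptideSet")) peptideIds(x) else names(seqs)
  m <- t(vapply(seqs, physchemVector, numeric(430), pka = pka, scale = scale))
  rownames(m) <- ids
  m
}

#' Profile peptides in the reporting layout
#'
#' Per-peptide report with columns Sequence, Length, Charge (pH 7, rounded
#' half-away-from-zero to 2 decimals), H (mean hydrophobicity) and muH
#' (helical hydrophobic moment).
#'
#' @inheritParams descriptorMatrix
#' @return A data.frame, one row per peptide.
#' @export
profilePeptides <- function(x, pka = defaultPKaSet(), scale = EISENBERG_SCALE) {
  seqs <- if (is(x, "PeptideSet")) peptideSequences(x) else as.character(x)
  roundAway <- function(v, d = 2) sign(v) * floor(abs(v) * 10^d + 0.5) / 10^d
  rows <- lapply(seqs, function(s) {
    gp <- globalProperties(s, 7.0, pka, scale)
    data.frame(Sequence = s, Length = gp$length,
               Charge = roundAway(gp$net_charge),
               H = round(gp$gravy, 2), muH = round(gp$hydrophobic_moment, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
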