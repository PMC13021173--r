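# Physicochemical reference tables used across the descriptor module.
# All tables are keyed by the 20 canonical residues in fixed alphabetical
# order; every descriptor vector in the package uses this ordering.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical residues in the fixed alphabetical order used by every
#' descriptor layout in the package (`ACDEFGHIKLMNPQRSTVWY`).
#'
#' @return Character vector of length 20.
#' @export
aminoAcidAlphabet <- function() AA_ALPHABET_20

AA_ALPHABET_20 <- c("A","C","D","E","F","G","H","I","K","L",
                    "M","N","P","Q","R","S","T","V","W","Y")

# Monoisotopic masses of the free amino acids (Da); peptide mass is the sum
# of free masses minus one water per peptide bond.
AA_MONO_MASS <- c(
  A = 89.04768, C = 121.01975, D = 133.03751, E = 147.05316, F = 165.07898,
  G = 75.03203, H = 155.06948, I = 131.09463, K = 146.10553, L = 131.09463,
  M = 149.05105, N = 132.05349, P = 115.06333, Q = 146.06914, R = 174.11168,
  S = 105.04259, T = 119.05824, V = 117.07898, W = 204.08988, Y = 181.07389)

WATER_MONO_MASS <- 18.010565

# Eisenberg consensus hydrophobicity scale (default for GRAVY-style means,
# hydrophobic moments and helical wheels).
EISENBERG_SCALE <- c(
  A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
  G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
  M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
  S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26)

# Kyte-Doolittle scale, offered as an alternative hydrophobicity table.
KYTE_DOOLITTLE_SCALE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

#' Hydrophobicity scales
#'
#' Named per-residue hydrophobicity tables. `"eisenberg"` (the consensus
#' scale, default everywhere in the package) and `"kyte-doolittle"` are
#' provided; any named numeric vector covering the 20 canonical residues can
#' be passed wherever a scale is accepted.
#'
#' @param name One of `"eisenberg"`, `"kyte-doolittle"`.
#' @return Named numeric vector of length 20.
#' @export
hydrophobicityScale <- function(name = c("eisenberg", "kyte-doolittle")) {
  name <- match.arg(name)
  switch(name, eisenberg = EISENBERG_SCALE, `kyte-doolittle` = KYTE_DOOLITTLE_SCALE)
}

# Guruprasad dipeptide instability weights (DIWV). Rows: first residue,
# columns: second residue, alphabetical order. Pairs not singled out by the
# published table carry weight 1.
DIWV_TABLE <- local({
  rows <- list(
    A = c(1,44.94,-7.49,1,1,1,-7.49,1,1,1,1,1,20.26,1,1,1,1,1,1,1),
    C = c(1,1,20.26,1,1,1,33.6,1,1,20.26,33.6,1,20.26,-6.54,1,1,33.6,-6.54,24.68,1),
    D = c(1,1,1,1,-6.54,1,1,1,-7.49,1,1,1,1,1,-6.54,20.26,-14.03,1,1,1),
    E = c(1,44.94,20.26,33.6,1,1,-6.54,20.26,1,1,1,1,20.26,20.26,1,20.26,1,1,-14.03,1),
    F = c(1,1,13.34,1,1,1,1,1,-14.03,1,1,1,20.26,1,1,1,1,1,1,33.601),
    G = c(-7.49,1,1,-6.54,1,13.34,1,-7.49,-7.49,1,1,-7.49,1,1,1,1,-7.49,1,13.34,-7.49),
    H = c(1,1,1,1,-9.37,-9.37,1,44.94,24.68,1,1,24.68,-1.88,1,1,1,-6.54,1,-1.88,44.94),
    I = c(1,1,1,44.94,1,1,13.34,1,-7.49,20.26,1,1,-1.88,1,1,1,1,-7.49,1,1),
    K = c(1,1,1,1,1,-7.49,1,-7.49,1,-7.49,33.6,1,-6.54,24.64,33.6,1,1,-7.49,1,1),
    L = c(1,1,1,1,1,1,1,1,-7.49,1,1,1,20.26,33.6,20.26,1,1,1,24.68,1),
    M = c(13.34,1,1,1,1,1,58.28,1,1,1,-1.88,1,44.94,-6.54,-6.54,44.94,-1.88,1,1,24.68),
    N = c(1,-1.88,1,1,-14.03,-14.03,1,44.94,24.68,1,1,1,-1.88,-6.54,1,1,-7.49,1,-9.37,1),
    P = c(20.26,-6.54,-6.54,18.38,20.26,1,1,1,1,1,-6.54,1,20.26,20.26,-6.54,20.26,1,20.26,-1.88,1),
    Q = c(1,-6.54,20.26,20.26,-6.54,1,1,1,1,1,1,1,20.26,20.26,1,44.94,1,-6.54,1,-6.54),
    R = c(1,1,1,1,1,-7.49,20.26,1,1,1,1,13.34,20.26,20.26,58.28,44.94,1,1,58.28,-6.54),
    S = c(1,33.6,1,20.26,1,1,1,1,1,1,1,1,44.94,20.26,20.26,20.26,1,1,1,1),
    T = c(1,1,1,20.26,13.34,-7.49,1,1,1,1,1,-14.03,1,-6.54,1,1,1,1,-14.03,1),
    V = c(1,1,-14.03,1,1,-7.49,1,1,-1.88,1,1,1,20.26,1,1,1,-7.49,1,1,-6.54),
    W = c(-14.03,1,1,1,1,-9.37,24.68,1,1,13.34,24.68,13.34,1,1,1,1,-14.03,-7.49,1,1),
    Y = c(24.68,1,24.68,-6.54,1,-7.49,13.34,1,1,1,44.94,1,13.34,1,-15.91,1,-7.49,1,-9.37,13.34))
  m <- do.call(rbind, rows)
  dimnames(m) <- list(AA_ALPHABET_20, AA_ALPHABET_20)
  m
})
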