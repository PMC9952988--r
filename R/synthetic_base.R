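# Synthetic base model used by the data generator.
#
# Exchangeabilities are derived from Grantham's (1974) amino-acid
# difference formula on side-chain composition (c), polarity (p) and
# volume (v):
#   d_ij = sqrt(a*(c_i-c_j)^2 + b*(p_i-p_j)^2 + g*(v_i-v_j)^2)
# with the standard weights a = 1.833, b = 0.1018, g = 0.000399.
# Setting r_ij = exp(-d_ij / scale) gives the canonical pattern of real
# replacement matrices: chemically conservative pairs exchange fast,
# radical pairs slowly.
#
# Equilibrium frequencies are derived from the standard genetic code at a
# given genomic GC content: each sense codon gets probability
# prod(base probabilities) with P(G) = P(C) = gc/2 and P(A) = P(T) =
# (1-gc)/2, and a residue's frequency is the sum over its codons
# (renormalized over the 61 sense codons). This reproduces the well-known
# enrichment of GARP residues (GC-rich codons) and depletion of FYMINK
# residues (GC-poor codons) as GC rises.

# Grantham (1974) side-chain composition, polarity, volume,
# in the canonical residue order A R N D C Q E G H I L K M F P S T W Y V.
.GRANTHAM_PROPS <- matrix(c(
  # c      p      v
  0.00,  8.1,  31,   # A
  0.65, 10.5, 124,   # R
  1.33, 11.6,  56,   # N
  1.38, 13.0,  54,   # D
  2.75,  5.5,  55,   # C
  0.89, 10.5,  85,   # Q
  0.92, 12.3,  83,   # E
  0.74,  9.0,   3,   # G
  0.58, 10.4,  96,   # H
  0.00,  5.2, 111,   # I
  0.00,  4.9, 111,   # L
  0.33, 11.3, 119,   # K
  0.00,  5.7, 105,   # M
  0.00,  5.2, 132,   # F
  0.39,  8.0,  32.5, # P
  1.42,  9.2,  32,   # S
  0.71,  8.6,  61,   # T
  0.13,  5.4, 170,   # W
  0.20,  6.2, 136,   # Y
  0.00,  5.9,  84    # V
), ncol = 3, byrow = TRUE,
  dimnames = list(AA_ALPHABET, c("c", "p", "v")))

#' Chemistry-based synthetic exchangeabilities
#'
#' Builds a plausible base exchangeability vector from Grantham's
#' physicochemical distance between residues: `r_ij = exp(-d_ij / scale)`,
#' so conservative substitutions get large relative exchangeabilities and
#' radical ones small, as in empirically trained replacement matrices.
#'
#' @param scale decay scale in Grantham-distance units (default 60).
#' @return Named exchangeability vector of length 190, normalized to sum 1.
#' @export
#' @examples
#' R <- grantham_exchangeabilities()
#' which.max(R)  # a chemically conservative pair
grantham_exchangeabilities <- function(scale = 60) {
  P <- .GRANTHAM_PROPS
  idx <- .pair_indices()
  d <- sqrt(1.833 * (P[idx[, 1], "c"] - P[idx[, 2], "c"])^2 +
            0.1018 * (P[idx[, 1], "p"] - P[idx[, 2], "p"])^2 +
            0.000399 * (P[idx[, 1], "v"] - P[idx[, 2], "v"])^2)
  normalize_exchangeabilities(exp(-d / scale))
}

# codons of each residue in the standard genetic code
.CODON_TABLE <- list(
  A = c("GCT", "GCC", "GCA", "GCG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  N = c("AAT", "AAC"),
  D = c("GAT", "GAC"),
  C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"),
  E = c("GAA", "GAG"),
  G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  K = c("AAA", "AAG"),
  M = "ATG",
  F = c("TTT", "TTC"),
  P = c("CCT", "CCC", "CCA", "CCG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"),
  W = "TGG",
  Y = c("TAT", "TAC"),
  V = c("GTT", "GTC", "GTA", "GTG")
)

#' Codon-composition frequencies at a given genomic GC content
#'
#' Amino-acid equilibrium frequencies implied by the standard genetic code
#' when every base is drawn independently with `P(G) = P(C) = gc/2`. Used
#' by the synthetic-data generator so that clade frequency vectors carry a
#' realistic GC signal (GARP residues rise with GC, FYMINK residues fall).
#'
#' @param gc genomic GC content as a fraction in (0, 1).
#' @return Named frequency vector of length 20 (sums to 1).
#' @export
#' @examples
#' codon_frequencies(0.65)["A"] > codon_frequencies(0.35)["A"]
codon_frequencies <- function(gc) {
  if (!is.finite(gc) || gc <= 0 || gc >= 1)
    stop("gc must lie strictly between 0 and 1")
  pbase <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  f <- vapply(.CODON_TABLE, function(codons) {
    sum(vapply(codons, function(cd) {
      prod(pbase[strsplit(cd, "")[[1]]])
    }, numeric(1)))
  }, numeric(1))
  f <- f / sum(f)  # renormalize over sense codons
  names(f) <- names(.CODON_TABLE)
  f[AA_ALPHABET]
}

#' Default synthetic base model
#'
#' Combines [grantham_exchangeabilities()] with [codon_frequencies()] into
#' the base substitution model from which the synthetic-data generator
#' derives clade-specific models by perturbation.
#'
#' @param gc genomic GC content used for the frequencies.
#' @param alpha gamma shape attached to the model.
#' @param name model name.
#' @return A [substitution_model()].
#' @export
synthetic_base_model <- function(gc = 0.5, alpha = 0.8,
                                 name = sprintf("base_gc%02.0f", 100 * gc)) {
  substitution_model(name, grantham_exchangeabilities(),
                     codon_frequencies(gc), alpha = alpha)
}
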