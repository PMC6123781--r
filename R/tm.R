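# Nearest-neighbor DNA duplex melting temperature (unified dH/dS parameter
# set with a monovalent-salt entropy correction), used to size the two
# annealing halves of LCR bridging oligos against the 70 degC target.

# Unified nearest-neighbor parameters: dH in kcal/mol, dS in cal/(mol K),
# for each dinucleotide step read 5'->3' on the top strand.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# Duplex initiation with a terminal G.C pair vs a terminal A.T pair.
INIT_DH <- c(GC = 0.1, AT = 2.3)
INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Reverse complement of a DNA string
#'
#' @param x DNA string (A/C/G/T).
#' @return The reverse complement, same case convention (upper).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

#' Nearest-neighbor melting temperature
#'
#' Predicts the duplex melting temperature of a short oligonucleotide
#' against its perfect complement by summing unified nearest-neighbor
#' dH/dS terms plus duplex-initiation terms, with the monovalent-salt
#' entropy correction 0.368 * (N - 1) * ln[Na+] (N = oligo length) and the
#' two-state formula Tm = dH / (dS + R ln(CT/4)) for non-self-complementary
#' duplexes at total strand concentration CT.
#'
#' @param sequence DNA string, length >= 2, alphabet A/C/G/T (ambiguity
#'   codes are an error).
#' @param Na Monovalent cation concentration in mol/L (default 0.05).
#' @param conc Total oligo concentration in mol/L (default 250e-9).
#' @return Tm in degrees Celsius.
#' @examples
#' tm_nn("AGCTTGCCATTGCAGGATCC")
#' @export
tm_nn <- function(sequence, Na = 0.05, conc = 250e-9) {
  s <- toupper(as.character(sequence))
  if (nchar(s) < 2L) stop("sequence must be at least 2 nt")
  if (grepl("[^ACGT]", s)) {
    stop("ambiguous or non-DNA base in sequence: Tm is defined for A/C/G/T only")
  }
  n <- nchar(s)
  steps <- substring(s, seq_len(n - 1L), seq(2L, n))
  dh <- sum(NN_DH[steps])
  ds <- sum(NN_DS[steps])
  for (term in c(substr(s, 1L, 1L), substr(s, n, n))) {
    cls <- if (term %in% c("G", "C")) "GC" else "AT"
    dh <- dh + INIT_DH[[cls]]
    ds <- ds + INIT_DS[[cls]]
  }
  ds <- ds + 0.368 * (n - 1L) * log(Na)
  R <- 1.987
  dh * 1000 / (ds + R * log(conc / 4)) - 273.15
}
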