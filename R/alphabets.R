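# Residue alphabets and the Kyte-Doolittle hydropathy scale.

#' Amino-acid alphabet (20 standard residues)
#'
#' @format Character vector of the 20 standard one-letter amino-acid codes,
#'   alphabetical.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Kyte-Doolittle hydropathy indices
#'
#' Per-residue hydropathy values used by [hydropathy_profile()]. Positive
#' values are hydrophobic; a 19-residue window mean above ~1.6 is the
#' classical indication of a candidate transmembrane helix.
#'
#' @format Named numeric vector over [AA_ALPHABET].
#' @references Kyte J, Doolittle RF (1982) J Mol Biol 157:105-132.
#' @export
KYTE_DOOLITTLE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
  G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
  M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

DNA_ALPHABET <- c("A", "C", "G", "T")

# Valid residue regexes per declared alphabet; X/N pass as unknowns.
.alphabet_regex <- list(
  protein = "[^ACDEFGHIKLMNPQRSTVWYX]",
  dna     = "[^ACGTN]"
)

# Integer-encode a protein string; masked positions (X or lower-case) -> NA.
encode_protein <- function(residues) {
  match(strsplit(toupper(residues), "", fixed = TRUE)[[1]], AA_ALPHABET)
}
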