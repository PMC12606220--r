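# Monoisotopic mass arithmetic for tryptic collagen peptides.

#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic masses (Da) of the 20 standard amino-acid
#' residues (i.e. the mass contributed by each residue inside a peptide
#' chain; a free amino acid is the residue mass plus one water).
#'
#' @format Named numeric vector of length 20, names are 1-letter codes.
#' @export
AA_MONO <- c(
  G =  57.021464, A =  71.037114, S =  87.032028, P =  97.052764,
  V =  99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

MASS_WATER   <- 18.010565
MASS_PROTON  <-  1.007276
MASS_HYDROXYL <- 15.994915  # +O: proline/lysine hydroxylation
MASS_DEAMID  <-  0.984016   # N->D / Q->E


AA_ALPHABET <- c(names(AA_MONO), "X")

# PAML/phangorn state order used by the substitution models
AA_STATES <- strsplit("ARNDCQEGHILKMFPSTWYV", "", fixed = TRUE)[[1L]]
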