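# Monoisotopic mass arithmetic for tryptic collagen peptides.

#' Neutral monoisotopic mass of a peptide
#'
#' Computes the neutral monoisotopic mass of a peptide as the sum of residue
#' masses plus one water, plus optional collagen post-translational
#' modifications: hydroxylation (+15.994915 Da each, on Pro or Lys) and
#' deamidation (+0.984016 Da each, on Asn or Gln).
#'
#' @param sequence Peptide string in 1-letter codes (no `X`).
#' @param n_hydroxylations Number of hydroxylations; must not exceed the
#'   number of P plus K residues.
#' @param n_deamidations Number of deamidations; must not exceed the number
#'   of N plus Q residues.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("GR")  # 231.1331
#' @export
peptide_mass <- function(sequence, n_hydroxylations = 0L, n_deamidations = 0L) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a single non-empty string")
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!res %in% names(AA_MONO))
  if (length(bad)) {
    if (any(res[bad] == "X"))
      stop("peptide mass undefined: sequence contains 'X' at position ",
           bad[match(TRUE, res[bad] == "X")])
    stop("invalid residue '", res[bad[1L]], "' at position ", bad[1L])
  }
  n_oh_sites <- sum(res %in% c("P", "K"))
  n_dm_sites <- sum(res %in% c("N", "Q"))
  if (n_hydroxylations < 0L || n_hydroxylations > n_oh_sites)
    stop("n_hydroxylations (", n_hydroxylations, ") exceeds available P/K sites (",
         n_oh_sites, ")")
  if (n_deamidations < 0L || n_deamidations > n_dm_sites)
    stop("n_deamidations (", n_deamidations, ") exceeds available N/Q sites (",
         n_dm_sites, ")")
  sum(AA_MONO[res]) + MASS_WATER +
    n_hydroxylations * MASS_HYDROXYL + n_deamidations * MASS_DEAMID
}

#' m/z of a protonated peptide
#'
#' Converts a neutral monoisotopic mass to m/z for a given positive charge
#' state. MALDI spectra are dominated by singly protonated ions, so the
#' default charge is 1.
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @return m/z value, `(neutral_mass + charge * 1.007276) / charge`.
#' @examples
#' peptide_mz(peptide_mass("GR"), 1)
#' @export
peptide_mz <- function(neutral_mass, charge = 1L) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge))
    stop("'charge' must be a positive integer")
  (neutral_mass + charge * MASS_PROTON) / charge
}
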