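# Type I collagen sequences, in-silico tryptic digestion and theoretical
# peptide mass fingerprints.

validate_chain <- function(chain, what = "chain") {
  if (!is.character(chain) || length(chain) != 1L || !nzchar(chain))
    stop("'", what, "' must be a single non-empty string")
  res <- strsplit(toupper(chain), "", fixed = TRUE)[[1L]]
  bad <- which(!res %in% AA_ALPHABET)
  if (length(bad))
    stop("invalid character '", res[bad[1L]], "' at position ", bad[1L],
         " of ", what)
  paste(res, collapse = "")
}

#' Type I collagen sequence for one taxon
#'
#' Bundles the mature COL1A1 and COL1A2 chains of a taxon. Peptide positions
#' are 1-based on each chain; the concatenated COL1A1+COL1A2 string (with the
#' recorded boundary offset) is the coordinate frame used for alignment
#' assembly.
#'
#' @param taxon_id Taxon label.
#' @param chain_a1,chain_a2 Amino-acid strings (1-letter codes; `X` allowed
#'   for unknown residues).
#' @return An object of class `collagen_sequence` with elements `taxon_id`,
#'   `chain_a1`, `chain_a2`, `concatenated` and `boundary` (1-based position
#'   of the first COL1A2 residue in the concatenated frame).
#' @export
collagen_sequence <- function(taxon_id, chain_a1, chain_a2 = "") {
  if (!is.character(taxon_id) || length(taxon_id) != 1L || !nzchar(taxon_id))
    stop("'taxon_id' must be a non-empty string")
  chain_a1 <- validate_chain(chain_a1, "chain_a1")
  chain_a2 <- if (nzchar(chain_a2)) validate_chain(chain_a2, "chain_a2") else ""
  structure(list(
    taxon_id = taxon_id,
    chain_a1 = chain_a1,
    chain_a2 = chain_a2,
    concatenated = paste0(chain_a1, chain_a2),
    boundary = nchar(chain_a1) + 1L
  ), class = "collagen_sequence")
}

#' @export
print.collagen_sequence <- function(x, ...) {
  cat("Type I collagen sequence:", x$taxon_id, "\n")
  cat("  COL1A1:", nchar(x$chain_a1), "aa;  COL1A2:", nchar(x$chain_a2),
      "aa;  COL1A2 offset:", x$boundary, "\n")
  nx <- sum(strsplit(x$concatenated, "")[[1L]] == "X")
  cat("  unknown residues (X):", nx, "\n")
  invisible(x)
}

#' Read collagen chains from FASTA
#'
#' Expects headers of the form `taxon|chain` with chain `A1` or `A2`
#' (`COL1A1`/`COL1A2` also accepted). Taxa with only an A1 record get an
#' empty A2 chain.
#'
#' @param path FASTA file.
#' @return Named list of [collagen_sequence()] objects.
#' @export
read_collagen_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  hdr <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(hdr) < 2L))
    stop("FASTA headers must be of the form 'taxon|chain'")
  taxon <- vapply(hdr, `[[`, "", 1L)
  chain <- toupper(vapply(hdr, `[[`, "", 2L))
  chain[chain %in% c("COL1A1", "A1")] <- "A1"
  chain[chain %in% c("COL1A2", "A2")] <- "A2"
  if (!all(chain %in% c("A1", "A2")))
    stop("unrecognized chain label; use A1/A2 or COL1A1/COL1A2")
  out <- lapply(unique(taxon), function(tx) {
    a1 <- which(taxon == tx & chain == "A1")
    a2 <- which(taxon == tx & chain == "A2")
    if (length(a1) != 1L) stop("taxon ", tx, " must have exactly one A1 record")
    collagen_sequence(tx, as.character(seqs[[a1]]),
                      if (length(a2)) as.character(seqs[[a2[1L]]]) else "")
  })
  names(out) <- unique(taxon)
  out
}

#' Write collagen chains to FASTA
#'
#' @param seqs List of [collagen_sequence()] objects.
#' @param path Output file.
#' @export
write_collagen_fasta <- function(seqs, path) {
  if (inherits(seqs, "collagen_sequence")) seqs <- list(seqs)
  recs <- character(0)
  for (s in seqs) {
    recs[paste0(s$taxon_id, "|A1")] <- s$chain_a1
    if (nzchar(s$chain_a2)) recs[paste0(s$taxon_id, "|A2")] <- s$chain_a2
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(recs), path)
  invisible(path)
}

# Cleavage sites of trypsin on one chain: after K or R unless followed by P.
trypsin_sites <- function(res) {
  n <- length(res)
  if (n < 2L) return(integer(0))
  k <- which(res[-n] %in% c("K", "R"))
  k[res[k + 1L] != "P"]
}

#' In-silico tryptic digestion
#'
#' Cuts a sequence C-terminal to K or R, suppressed when the following
#' residue is P (the classic Keil rule used by standard search engines), and
#' returns all peptides with up to `max_missed` internal missed cleavages.
#' With `max_missed = 0` the peptides partition the input.
#'
#' @param seq A [collagen_sequence()] (both chains digested, chain-local
#'   coordinates reported) or a plain amino-acid string (reported as chain
#'   `A1`).
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @return A data frame with columns `sequence`, `chain`, `start`, `end`
#'   (1-based inclusive, chain-local) and `missed_cleavages`.
#' @examples
#' tryptic_digest("GKGR", max_missed = 1)
#' @export
tryptic_digest <- function(seq, max_missed = 1L) {
  if (!is.numeric(max_missed) || max_missed < 0L)
    stop("'max_missed' must be >= 0")
  max_missed <- as.integer(max_missed)
  if (is.character(seq)) seq <- collagen_sequence("unnamed", seq)
  if (!inherits(seq, "collagen_sequence"))
    stop("'seq' must be a collagen_sequence or an amino-acid string")
  digest_chain <- function(chain, label) {
    if (!nzchar(chain)) return(NULL)
    res <- strsplit(chain, "", fixed = TRUE)[[1L]]
    ends <- c(trypsin_sites(res), length(res))
    starts <- c(1L, ends[-length(ends)] + 1L)
    out <- list()
    for (i in seq_along(starts)) {
      for (m in 0:min(max_missed, length(ends) - i)) {
        s <- starts[i]; e <- ends[i + m]
        out[[length(out) + 1L]] <- data.frame(
          sequence = substr(chain, s, e), chain = label,
          start = s, end = e, missed_cleavages = m,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }
  out <- rbind(digest_chain(seq$chain_a1, "A1"), digest_chain(seq$chain_a2, "A2"))
  rownames(out) <- NULL
  out
}

#' Theoretical peptide mass fingerprint
#'
#' Enumerates modified variants (hydroxylations on P, optionally also K;
#' deamidations on N/Q) of every tryptic peptide, computes singly protonated
#' m/z by default, and keeps variants inside an m/z window. Peptides
#' containing `X` have undefined mass and are skipped.
#'
#' @param seq [collagen_sequence()] or amino-acid string.
#' @param max_missed Missed cleavages passed to [tryptic_digest()].
#' @param max_hydroxylations Per-peptide cap on hydroxylation count (bounds
#'   the combinatorics; collagen Gly-X-Y chemistry rarely exceeds a few
#'   hydroxyprolines per tryptic peptide).
#' @param hydroxylate_lysine If `TRUE`, K counts as a hydroxylation site in
#'   addition to P.
#' @param max_deamidations Per-peptide cap on deamidations; default all N+Q.
#' @param mass_window Numeric `c(min_mz, max_mz)` window.
#' @param charge Charge state for m/z.
#' @return Data frame sorted by `mz` with peptide columns plus `n_oh`,
#'   `n_deam`, `neutral_mass`, `mz`; unique by (sequence, n_oh, n_deam).
#' @export
theoretical_fingerprint <- function(seq, max_missed = 1L,
                                    max_hydroxylations = 6L,
                                    hydroxylate_lysine = FALSE,
                                    max_deamidations = NULL,
                                    mass_window = c(800, 3600),
                                    charge = 1L) {
  if (length(mass_window) != 2L || mass_window[1L] >= mass_window[2L])
    stop("'mass_window' must be c(min, max) with min < max")
  pep <- tryptic_digest(seq, max_missed)
  pep <- pep[!duplicated(pep$sequence), , drop = FALSE]
  rows <- vector("list", nrow(pep))
  for (i in seq_len(nrow(pep))) {
    p <- pep[i, ]
    res <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
    if (any(res == "X")) next
    oh_sites <- sum(res == "P") + if (hydroxylate_lysine) sum(res == "K") else 0L
    dm_sites <- sum(res %in% c("N", "Q"))
    n_oh_max <- min(oh_sites, max_hydroxylations)
    n_dm_max <- if (is.null(max_deamidations)) dm_sites else
      min(dm_sites, max_deamidations)
    base <- peptide_mass(p$sequence)
    grid <- expand.grid(n_oh = 0:n_oh_max, n_deam = 0:n_dm_max)
    mass <- base + grid$n_oh * MASS_HYDROXYL + grid$n_deam * MASS_DEAMID
    mz <- peptide_mz(mass, charge)
    keep <- mz >= mass_window[1L] & mz <= mass_window[2L]
    if (!any(keep)) next
    rows[[i]] <- data.frame(
      p[rep(1L, sum(keep)), , drop = FALSE],
      n_oh = grid$n_oh[keep], n_deam = grid$n_deam[keep],
      neutral_mass = mass[keep], mz = mz[keep],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sequence = character(), chain = character(),
                      start = integer(), end = integer(),
                      missed_cleavages = integer(), n_oh = integer(),
                      n_deam = integer(), neutral_mass = numeric(),
                      mz = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a theoretical fingerprint as TSV
#'
#' @param fingerprint Data frame from [theoretical_fingerprint()].
#' @param path Output file.
#' @export
write_fingerprint <- function(fingerprint, path) {
  utils::write.table(fingerprint, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
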