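# Assembly of per-taxon recovered peptides into a positional amino-acid
# alignment on a reference collagen coordinate frame, with 'X' for unknowns.

#' Recovered peptide set for one taxon
#'
#' Peptide sequences recovered by LC-MS/MS for a taxon, each with its chain
#' (A1/A2) and 1-based inclusive chain-local span.
#'
#' @param taxon_id Taxon label.
#' @param peptides Data frame with columns `sequence`, `chain`, `start`,
#'   `end`.
#' @return Object of class `recovered_peptides`.
#' @export
recovered_peptides <- function(taxon_id, peptides) {
  need <- c("sequence", "chain", "start", "end")
  if (!all(need %in% names(peptides)))
    stop("'peptides' needs columns: ", paste(need, collapse = ", "))
  if (any(peptides$end - peptides$start + 1L != nchar(peptides$sequence)))
    stop("span length disagrees with sequence length")
  if (!all(peptides$chain %in% c("A1", "A2")))
    stop("chain must be 'A1' or 'A2'")
  structure(list(taxon_id = taxon_id, peptides = peptides),
            class = "recovered_peptides")
}

#' Read recovered peptides from TSV
#'
#' Columns: `taxon`, `sequence`, `chain`, `start`, `end`.
#'
#' @param path TSV file.
#' @return List of [recovered_peptides()], one per taxon.
#' @export
read_recovered_peptides <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"taxon" %in% names(tab)) stop("TSV needs a 'taxon' column")
  lapply(split(tab, tab$taxon), function(d)
    recovered_peptides(d$taxon[1L], d[, c("sequence", "chain", "start", "end")]))
}

#' Positional amino-acid alignment
#'
#' Character matrix (taxa x columns) over the 20 residues plus `X` for
#' unknown. Columns are the concatenated COL1A1+COL1A2 coordinate frame of a
#' reference taxon; collagen chains are treated as indel-free across taxa so
#' positional homology is given by the coordinate, not by a gap-admitting
#' aligner.
#'
#' @param mat Character matrix with taxon row names.
#' @param boundary 1-based concatenated position of the first COL1A2 column
#'   (`NA` when unknown).
#' @return Object of class `aa_alignment` (a matrix with attributes).
#' @export
aa_alignment <- function(mat, boundary = NA_integer_) {
  if (!is.matrix(mat) || !is.character(mat)) stop("'mat' must be a character matrix")
  if (is.null(rownames(mat))) stop("matrix needs taxon row names")
  bad <- !mat %in% AA_ALPHABET
  if (any(bad)) stop("invalid alignment character '", mat[bad][1L], "'")
  structure(mat, boundary = boundary, class = c("aa_alignment", "matrix"))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Amino-acid alignment:", nrow(x), "taxa x", ncol(x), "columns\n")
  cov <- round(100 * rowMeans(unclass(x) != "X"), 1)
  for (tx in rownames(x)) cat(sprintf("  %-20s %5.1f%% coverage\n", tx, cov[tx]))
  invisible(x)
}

#' Assemble recovered peptides into an alignment
#'
#' Places each taxon's peptides at their reference coordinates; positions not
#' covered by any peptide become `X`. Overlapping peptides that agree are
#' merged; where they disagree, the residue supported by more peptides wins
#' and ties fall back to `X`. All conflicts are recorded in the `"conflicts"`
#' attribute.
#'
#' @param sets List of [recovered_peptides()].
#' @param reference A [collagen_sequence()] defining the coordinate frame;
#'   included as a full-coverage row when `include_reference = TRUE`.
#' @param include_reference Add the reference taxon's own row.
#' @return An [aa_alignment()] with attribute `conflicts` (data frame).
#' @export
assemble_alignment <- function(sets, reference, include_reference = TRUE) {
  if (inherits(sets, "recovered_peptides")) sets <- list(sets)
  L1 <- nchar(reference$chain_a1); L2 <- nchar(reference$chain_a2)
  L <- L1 + L2
  taxa <- vapply(sets, `[[`, "", "taxon_id")
  mat <- matrix("X", nrow = length(sets), ncol = L,
                dimnames = list(taxa, NULL))
  conflicts <- list()
  for (i in seq_along(sets)) {
    counts <- vector("list", L)  # position -> table of supported residues
    for (j in seq_len(nrow(sets[[i]]$peptides))) {
      p <- sets[[i]]$peptides[j, ]
      off <- if (p$chain == "A1") 0L else L1
      if (p$chain == "A2" && L2 == 0L)
        stop("peptide on chain A2 but reference has no A2 chain")
      if (p$end > (if (p$chain == "A1") L1 else L2))
        stop("peptide span ", p$start, "-", p$end, " exceeds reference ",
             p$chain, " length")
      res <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
      pos <- (p$start:p$end) + off
      for (k in seq_along(pos)) {
        cl <- counts[[pos[k]]]
        counts[[pos[k]]] <- c(cl, res[k])
      }
    }
    for (pos in which(lengths(counts) > 0L)) {
      tab <- table(counts[[pos]])
      tab <- tab[names(tab) != "X"]
      if (!length(tab)) next
      best <- names(tab)[tab == max(tab)]
      if (length(tab) > 1L)
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          taxon = taxa[i], position = pos,
          residues = paste(names(tab), collapse = ","),
          resolved = if (length(best) == 1L) best else "X",
          stringsAsFactors = FALSE)
      mat[i, pos] <- if (length(best) == 1L) best else "X"
    }
  }
  if (include_reference) {
    ref_row <- matrix(strsplit(reference$concatenated, "", fixed = TRUE)[[1L]],
                      nrow = 1L, dimnames = list(reference$taxon_id, NULL))
    mat <- rbind(ref_row, mat)
  }
  out <- aa_alignment(mat, boundary = reference$boundary)
  attr(out, "conflicts") <- if (length(conflicts)) do.call(rbind, conflicts)
    else data.frame(taxon = character(), position = integer(),
                    residues = character(), resolved = character())
  out
}

#' Coverage and variability statistics of an alignment
#'
#' @param aln An [aa_alignment()].
#' @return List with `coverage` (per-taxon % of non-X columns, one decimal),
#'   `occupancy` (per-column count of non-X cells) and `n_variable`
#'   (columns with at least two distinct non-X residues).
#' @export
coverage_stats <- function(aln) {
  if (!nrow(aln) || !ncol(aln)) stop("empty alignment")
  m <- unclass(aln)
  known <- m != "X"
  coverage <- round(100 * rowMeans(known), 1)
  occupancy <- colSums(known)
  n_variable <- sum(apply(m, 2L, function(col) {
    r <- unique(col[col != "X"]); length(r) >= 2L
  }))
  list(coverage = coverage, occupancy = occupancy, n_variable = n_variable)
}

#' Write an alignment to FASTA or NEXUS
#'
#' Lossless round-trip with [read_alignment()]; `X` is preserved in both
#' formats.
#'
#' @param aln An [aa_alignment()].
#' @param path Output file.
#' @param format `"fasta"` or `"nexus"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "nexus")) {
  format <- match.arg(format)
  if (!nrow(aln) || !ncol(aln)) stop("empty alignment")
  m <- unclass(aln)
  if (format == "fasta") {
    seqs <- apply(m, 1L, paste, collapse = "")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  } else {
    rows <- lapply(seq_len(nrow(m)), function(i) m[i, ])
    names(rows) <- rownames(m)
    ape::write.nexus.data(rows, path, format = "protein", missing = "X",
                          interleaved = FALSE)
  }
  invisible(path)
}

#' Read an alignment written by [write_alignment()]
#'
#' @param path Input file.
#' @param format `"fasta"` or `"nexus"` (default by extension).
#' @return An [aa_alignment()].
#' @export
read_alignment <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, fa = "fasta", fasta = "fasta", nex = "nexus",
                     nexus = "nexus",
                     stop("cannot infer alignment format from '", ext, "'"))
  }
  format <- match.arg(format, c("fasta", "nexus"))
  if (format == "fasta") {
    seqs <- Biostrings::readAAStringSet(path)
    mat <- do.call(rbind, lapply(as.character(seqs), function(s)
      strsplit(s, "", fixed = TRUE)[[1L]]))
    rownames(mat) <- names(seqs)
  } else {
    rows <- ape::read.nexus.data(path)
    mat <- do.call(rbind, rows)
    mat <- toupper(mat)
    mat[mat == "?"] <- "X"
    rownames(mat) <- names(rows)
  }
  aa_alignment(mat)
}
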