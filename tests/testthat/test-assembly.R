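ref <- collagen_sequence("ref", "GPAGKAAGLR", "GDRGE")

test_that("assemble_alignment places peptides on reference coordinates", {
  rp <- recovered_peptides("tax1", data.frame(
    sequence = c("GPAGK", "GDR"), chain = c("A1", "A2"),
    start = c(1L, 1L), end = c(5L, 3L), stringsAsFactors = FALSE))
  aln <- assemble_alignment(list(rp), ref)
  expect_s3_class(aln, "aa_alignment")
  expect_equal(rownames(aln), c("ref", "tax1"))
  expect_equal(ncol(aln), 15L)
  expect_equal(paste(unclass(aln)["tax1", ], collapse = ""),
               "GPAGKXXXXXGDRXX")
  expect_equal(paste(unclass(aln)["ref", ], collapse = ""), "GPAGKAAGLRGDRGE")
  expect_equal(attr(aln, "boundary"), 11L)
})

test_that("overlap conflicts resolve by majority with ties becoming X", {
  rp <- recovered_peptides("tax1", data.frame(
    sequence = c("GPAGK", "SPAGK"), chain = "A1",
    start = 1L, end = 5L, stringsAsFactors = FALSE))
  aln <- assemble_alignment(list(rp), ref, include_reference = FALSE)
  row <- unname(unclass(aln)["tax1", ])
  expect_equal(row[1L], "X")          # G vs S is a tie -> X
  expect_equal(row[2L:5L], c("P", "A", "G", "K"))
  conf <- attr(aln, "conflicts")
  expect_true(nrow(conf) >= 1L)
  expect_true(all(conf$taxon == "tax1"))
})

test_that("majority wins at contested positions", {
  rp <- recovered_peptides("t", data.frame(
    sequence = c("GPAGK", "SPAGK", "SPAGK"), chain = "A1",
    start = 1L, end = 5L, stringsAsFactors = FALSE))
  aln <- assemble_alignment(list(rp), ref, include_reference = FALSE)
  expect_equal(unname(unclass(aln)["t", 1L]), "S")
  conf <- attr(aln, "conflicts")
  expect_equal(conf$resolved[conf$position == 1L], "S")
})

test_that("assembly validates spans and chains", {
  expect_error(recovered_peptides("t", data.frame(
    sequence = "GPA", chain = "A1", start = 1L, end = 5L)),
    "span length")
  expect_error(recovered_peptides("t", data.frame(
    sequence = "GPA", chain = "A9", start = 1L, end = 3L)),
    "'A1' or 'A2'")
  rp <- recovered_peptides("t", data.frame(
    sequence = "GPAGKAAGLRG", chain = "A1", start = 1L, end = 11L,
    stringsAsFactors = FALSE))
  expect_error(assemble_alignment(list(rp), ref), "exceeds reference")
  rp2 <- recovered_peptides("t", data.frame(
    sequence = "GDR", chain = "A2", start = 1L, end = 3L,
    stringsAsFactors = FALSE))
  ref_a1 <- collagen_sequence("r", "GPAGK")
  expect_error(assemble_alignment(list(rp2), ref_a1), "no A2 chain")
})

test_that("recovered peptides read from TSV grouped by taxon", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(c("taxon\tsequence\tchain\tstart\tend",
               "a\tGPAGK\tA1\t1\t5", "b\tGDR\tA2\t1\t3"), tmp)
  sets <- read_recovered_peptides(tmp)
  expect_setequal(names(sets), c("a", "b"))
  expect_equal(sets$a$peptides$sequence, "GPAGK")
})

test_that("coverage_stats counts coverage, occupancy and variable columns", {
  m <- rbind(a = c("G", "P", "X", "A"), b = c("G", "S", "L", "X"))
  aln <- aa_alignment(m)
  st <- coverage_stats(aln)
  expect_equal(unname(st$coverage), c(75, 75))
  expect_equal(unname(st$occupancy), c(2, 2, 1, 1))
  expect_equal(st$n_variable, 1L)  # only column 2 has two distinct non-X
})

test_that("alignments round-trip through FASTA and NEXUS preserving X", {
  m <- rbind(tax_a = c("G", "P", "X", "A"), tax_b = c("G", "S", "L", "X"))
  aln <- aa_alignment(m)
  fa <- tempfile(fileext = ".fasta")
  nx <- tempfile(fileext = ".nex")
  on.exit(unlink(c(fa, nx)))
  write_alignment(aln, fa, "fasta")
  write_alignment(aln, nx, "nexus")
  expect_equal(unclass(read_alignment(fa))[, ], m)
  expect_equal(unclass(read_alignment(nx))[, ], m)
  expect_error(read_alignment("x.weird"), "cannot infer")
})

test_that("aa_alignment rejects malformed input", {
  expect_error(aa_alignment(matrix("G", 1, 1)), "row names")
  expect_error(aa_alignment(rbind(a = c("G", "-"))), "invalid alignment")
})
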