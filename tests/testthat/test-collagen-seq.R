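test_that("collagen_sequence records chains and the coordinate boundary", {
  s <- collagen_sequence("wombat", "GPAGK", "GLR")
  expect_s3_class(s, "collagen_sequence")
  expect_equal(s$concatenated, "GPAGKGLR")
  expect_equal(s$boundary, 6L)
  expect_error(collagen_sequence("", "GPA"), "non-empty")
  expect_error(collagen_sequence("t", "GP1"), "invalid character '1'")
})

test_that("trypsin cleaves after K/R except before proline (Keil rule)", {
  d0 <- tryptic_digest("GKGR", max_missed = 0L)
  expect_equal(d0$sequence, c("GK", "GR"))
  expect_equal(d0$start, c(1L, 3L))
  expect_equal(d0$end, c(2L, 4L))
  # K followed by P is not cleaved
  dkp <- tryptic_digest("AKPGR", max_missed = 0L)
  expect_equal(dkp$sequence, "AKPGR")
  # missed cleavages enumerate contiguous joins
  d1 <- tryptic_digest("GKGRAA", max_missed = 1L)
  expect_setequal(d1$sequence, c("GK", "GKGR", "GR", "GRAA", "AA"))
  expect_equal(d1$missed_cleavages[d1$sequence == "GKGR"], 1L)
  expect_error(tryptic_digest("GKGR", max_missed = -1), ">= 0")
})

test_that("zero-missed digestion partitions every chain", {
  set.seed(7)
  for (i in 1:20) {
    chain <- paste(sample(names(zoomsphylo::AA_MONO), 60, replace = TRUE),
                   collapse = "")
    d <- tryptic_digest(chain, max_missed = 0L)
    expect_equal(paste(d$sequence, collapse = ""), chain)
    expect_equal(d$start[1L], 1L)
    expect_equal(d$end[nrow(d)], nchar(chain))
    expect_true(all(d$start[-1L] == d$end[-nrow(d)] + 1L))
  }
})

test_that("digestion covers both chains with chain-local coordinates", {
  s <- collagen_sequence("t", "GKAAR", "PPKGG")
  d <- tryptic_digest(s, max_missed = 0L)
  expect_setequal(unique(d$chain), c("A1", "A2"))
  a2 <- d[d$chain == "A2", ]
  expect_equal(a2$start[1L], 1L)  # chain-local, not concatenated
  expect_equal(paste(a2$sequence, collapse = ""), "PPKGG")
})

test_that("collagen FASTA round-trips taxon|chain records", {
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  seqs <- list(collagen_sequence("tax_a", "GPAGKXGLR", "GAR"),
               collagen_sequence("tax_b", "GPSGK"))
  write_collagen_fasta(seqs, tmp)
  back <- read_collagen_fasta(tmp)
  expect_equal(names(back), c("tax_a", "tax_b"))
  expect_equal(back$tax_a$chain_a1, "GPAGKXGLR")
  expect_equal(back$tax_a$chain_a2, "GAR")
  expect_equal(back$tax_b$chain_a2, "")
})

test_that("theoretical_fingerprint enumerates variants in-window, sorted", {
  fp <- theoretical_fingerprint("GPPGKAAANR", max_missed = 1L,
                                mass_window = c(300, 4000))
  expect_true(all(diff(fp$mz) >= 0))
  expect_true(all(fp$mz >= 300 & fp$mz <= 4000))
  expect_false(anyDuplicated(fp[, c("sequence", "n_oh", "n_deam")]) > 0)
  # the base GPPGK peptide has 2 prolines -> n_oh 0..2 present
  g <- fp[fp$sequence == "GPPGK", ]
  expect_setequal(g$n_oh, 0:2)
  expect_equal(g$neutral_mass[g$n_oh == 1] - g$neutral_mass[g$n_oh == 0],
               rep(15.994915, sum(g$n_oh == 1)), tolerance = 1e-9)
  # X-containing peptides are skipped
  fpx <- theoretical_fingerprint("GXPGKAAR", mass_window = c(1, 4000))
  expect_false(any(grepl("X", fpx$sequence)))
  expect_error(theoretical_fingerprint("GPK", mass_window = c(5, 2)),
               "min < max")
})

test_that("fingerprints export as readable TSV", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  fp <- theoretical_fingerprint("GPPGKAAANR", mass_window = c(300, 4000))
  write_fingerprint(fp, tmp)
  back <- read.delim(tmp)
  expect_equal(nrow(back), nrow(fp))
  expect_equal(back$mz, fp$mz, tolerance = 1e-8)
})
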