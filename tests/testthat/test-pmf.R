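test_that("peaklist validates and sorts peaks by m/z", {
  pl <- peaklist(c(1200, 900, 1500), c(10, 5, 2), sample_id = "s1")
  expect_equal(pl$peaks$mz, c(900, 1200, 1500))
  expect_equal(pl$peaks$intensity, c(5, 10, 2))
  expect_error(peaklist(1:3, 1:2), "equal length")
  expect_error(peaklist(c(1, NA), c(1, 1)), "non-finite")
  expect_error(peaklist(c(1, 2), c(1, -1)), "negative intensity")
})

test_that("TSV peak lists round-trip, with and without headers", {
  pl <- peaklist(c(900.1, 1105.58, 2869.41), c(50, 58, 20), "samp")
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_peaklist(pl, tmp)
  back <- read_peaklist(tmp)
  expect_equal(back$peaks, pl$peaks)
  expect_equal(back$sample_id, tools::file_path_sans_ext(basename(tmp)))
  # headerless two-column file
  tmp2 <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp2), add = TRUE)
  writeLines(c("900.1\t50", "1105.58\t58"), tmp2)
  back2 <- read_peaklist(tmp2, sample_id = "x")
  expect_equal(back2$peaks$mz, c(900.1, 1105.58))
  expect_error(read_peaklist(tempfile()), "file not found")
  tmp3 <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp3), add = TRUE)
  writeLines("only_one_column", tmp3)
  expect_error(read_peaklist(tmp3), "two columns|unparseable")
})

test_that("match_peaks is greedy, one-to-one and tolerance-bounded", {
  obs <- c(1000.00, 1000.15, 2000.0)
  theo <- c(1000.05, 2000.3)
  m <- match_peaks(obs, theo, tolerance = 0.2)
  # obs 1 is closer to theo 1 than obs 2 is; theo 2 is 0.3 away from obs 3
  expect_equal(m$obs_idx, 1L)
  expect_equal(m$theo_idx, 1L)
  expect_equal(m$delta_mz, -0.05, tolerance = 1e-12)
  m2 <- match_peaks(obs, theo, tolerance = 0.4)
  expect_equal(nrow(m2), 2L)
  expect_false(anyDuplicated(m2$obs_idx) > 0)
  expect_false(anyDuplicated(m2$theo_idx) > 0)
  expect_true(all(abs(m2$delta_mz) <= 0.4))
  expect_equal(nrow(match_peaks(numeric(0), theo)), 0L)
  expect_error(match_peaks(obs, theo, tolerance = 0), "> 0")
})

test_that("classify_taxon assigns winners, groups and indeterminates", {
  panel <- marker_panel(
    list(kang = c(1000, 1100, 1200), wall_a = c(1000, 1300, 1400),
         wall_b = c(1000, 1300, 1400)),
    ambiguity_groups = list(c("wall_a", "wall_b")))
  pk <- function(mz) peaklist(mz, rep(10, length(mz)), "s")
  expect_equal(classify_taxon(pk(c(1000, 1100, 1200)), panel)$assignment,
               "kang")
  # both wallabies tie on their shared markers -> ambiguity-group label
  expect_equal(classify_taxon(pk(c(1000, 1300, 1400)), panel)$assignment,
               "wall_a/wall_b")
  # too few markers
  expect_equal(classify_taxon(pk(1100), panel)$assignment, "indeterminate")
  # tie across unrelated taxa
  expect_equal(classify_taxon(pk(1000), panel, min_markers = 1L)$assignment,
               "indeterminate")
  expect_error(marker_panel(list(a = 1), list(c("a", "b"))), "missing")
  expect_error(marker_panel(list(a = 1, b = 2), list(c("a", "b"), c("b"))),
               "disjoint")
})

test_that("marker panels round-trip through TSV with groups", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(c("taxon\tmz\tgroup", "kang\t1000\t", "wall_a\t1300\tw",
               "wall_b\t1300\tw"), tmp)
  p <- read_marker_panel(tmp)
  expect_setequal(names(p$markers), c("kang", "wall_a", "wall_b"))
  expect_equal(p$ambiguity_groups, list(c("wall_a", "wall_b")))
})

test_that("preservation_class keys on the informative high-mass region", {
  good <- peaklist(c(1000, 2600, 3000), c(100, 30, 20), "g")
  expect_equal(preservation_class(good), "good")
  poor <- peaklist(c(1000, 2600, 3000), c(100, 3, 2), "p")
  expect_equal(preservation_class(poor), "poor")
  expect_equal(preservation_class(peaklist(numeric(0), numeric(0), "e")),
               "poor")
  expect_error(preservation_class(good, high_mz_threshold = -1), "positive")
})

test_that("deamidation_index reports the 1105:1106 ratio or a reason", {
  pl <- peaklist(c(1105.58, 1106.56), c(58, 100), "s")
  expect_equal(deamidation_index(pl), 0.58)
  miss <- peaklist(c(1106.56), c(100), "s")
  r <- deamidation_index(miss)
  expect_true(is.na(r))
  expect_equal(attr(r, "reason"), "reference peak absent")
  miss2 <- peaklist(c(1105.58), c(100), "s")
  expect_equal(attr(deamidation_index(miss2), "reason"),
               "deamidated peak absent")
})

test_that("screen_samples surveys a batch and survives bad samples", {
  panel <- marker_panel(list(a = c(1000, 1100), b = c(2000, 2100)))
  pls <- list(
    peaklist(c(1000, 1100, 1105.58, 1106.56, 2600, 2700),
             c(50, 40, 58, 100, 30, 30), "s1"),
    peaklist(numeric(0), numeric(0), "s2"))
  out <- screen_samples(pls, panel)
  expect_equal(nrow(out), 2L)
  expect_equal(out$assignment, c("a", "indeterminate"))
  expect_equal(out$deamidation_index[1L], 0.58)
  expect_true(is.na(out$deamidation_index[2L]))
  expect_equal(out$preservation, c("good", "poor"))
})
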