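test_that("pruning matches the exhaustive oracle on a fixed case", {
  case <- random_small_case(101)
  got <- site_log_likelihoods(case$tree, case$aln, case$model)
  want <- oracle_site_loglik(case$tree, case$aln, case$model)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("pruning matches phangorn::pml on mtMAM and mtMAM+F", {
  set.seed(5)
  tr <- ape::rtree(6, br = function(n) runif(n, 0.05, 0.6))
  tr$tip.label <- paste0("t", 1:6)
  m <- matrix(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]],
                     6 * 80, replace = TRUE), 6, 80,
              dimnames = list(tr$tip.label, NULL))
  aln <- aa_alignment(m)
  pd <- phangorn::phyDat(m, type = "AA")
  for (plus_f in c(FALSE, TRUE)) {
    model <- phylo_model("mtMAM",
                         frequencies = if (plus_f) "observed" else NULL,
                         aln = if (plus_f) aln else NULL)
    want <- phangorn::pml(tr, pd, model = "mtmam",
                          bf = if (plus_f) unname(model$pi) else NULL)$logLik
    got <- sum(site_log_likelihoods(tr, aln, model))
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("X columns are fully marginalized", {
  case <- random_small_case(77)
  m <- unclass(case$aln)
  m[, 1L] <- "X"                      # an all-missing column
  aln <- aa_alignment(m)
  ll <- site_log_likelihoods(case$tree, aln, case$model)
  expect_equal(ll[1L], 0, tolerance = 1e-12)
  # masking one taxon's residue can only raise that site's likelihood
  m2 <- unclass(case$aln)
  before <- site_log_likelihoods(case$tree, case$aln, case$model)
  m2[1L, 2L] <- "X"
  after <- site_log_likelihoods(case$tree, aa_alignment(m2), case$model)
  expect_gte(after[2L] + 1e-12, before[2L])
  expect_equal(after[-2L], before[-2L], tolerance = 1e-12)
})

test_that("pattern compression leaves per-site values intact", {
  case <- random_small_case(31)
  m <- unclass(case$aln)
  m2 <- cbind(m, m[, 1:5])            # duplicate columns
  ll <- site_log_likelihoods(case$tree, aa_alignment(m2), case$model)
  expect_equal(ll[ncol(m) + 1:5], ll[1:5], tolerance = 0)
})

test_that("fit_ml improves the likelihood and validates input", {
  case <- random_small_case(12)
  start <- case$tree
  start$edge.length <- rep(0.5, nrow(start$edge))
  ll0 <- sum(site_log_likelihoods(start, case$aln, case$model))
  fit <- fit_ml(case$aln, start, case$model)
  expect_s3_class(fit, "collagen_ml")
  expect_gte(fit$logL, ll0)
  expect_equal(fit$logL, sum(site_log_likelihoods(fit$tree, case$aln,
                                                  fit$model)),
               tolerance = 1e-9)
  expect_equal(logLik(fit), fit$logL, ignore_attr = TRUE)
  bad <- case$tree
  bad$tip.label[1L] <- "missing_taxon"
  expect_error(fit_ml(case$aln, bad, case$model), "taxon mismatch")
  neg <- case$tree
  neg$edge.length[1L] <- -0.1
  expect_error(site_log_likelihoods(neg, case$aln, case$model),
               "negative branch length")
  nobl <- case$tree
  nobl$edge.length <- NULL
  expect_error(site_log_likelihoods(nobl, case$aln, case$model),
               "no branch lengths")
})

test_that("likelihood is invariant to the root placement", {
  case <- random_small_case(63)
  tr <- case$tree
  if (!ape::is.rooted(tr)) tr <- ape::root(tr, 1, resolve.root = TRUE)
  ll1 <- sum(site_log_likelihoods(tr, case$aln, case$model))
  tr2 <- ape::root(ape::unroot(tr), 2, resolve.root = TRUE)
  ll2 <- sum(site_log_likelihoods(tr2, case$aln, case$model))
  expect_equal(ll1, ll2, tolerance = 1e-9)
})
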