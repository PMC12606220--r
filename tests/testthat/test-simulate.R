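cfg <- sim_config(n_taxa = 5L, seq_length = 300L, seed = 21L)

test_that("simulated trees are dated, ultrametric and reproducible", {
  tr <- simulate_tree(cfg)
  expect_equal(length(tr$tip.label), 5L)
  depths <- ape::node.depth.edgelength(tr)[1:5]
  expect_equal(depths, rep(cfg$root_age, 5L), tolerance = 1e-8)
  expect_identical(ape::write.tree(tr), ape::write.tree(simulate_tree(cfg)))
  expect_error(simulate_tree(sim_config(n_taxa = 2L)), "at least 3")
  expect_error(simulate_tree(sim_config(birth = 0.1, death = 0.2)),
               "infeasible")
})

test_that("alignment simulation follows the model and the seed", {
  tr <- simulate_tree(cfg)
  model <- phylo_model("mtMAM", p_inv = 0.5)
  a1 <- simulate_alignment(tr, model, 300L, clock_mean = 0.002, seed = 5L)
  a2 <- simulate_alignment(tr, model, 300L, clock_mean = 0.002, seed = 5L)
  expect_identical(unclass(a1)[, ], unclass(a2)[, ])
  expect_equal(dim(a1), c(5L, 300L))
  # invariant-class sites are constant across taxa
  cat <- attr(a1, "site_category")
  inv <- which(cat == 0L)
  expect_gt(length(inv), 50L)
  expect_true(all(apply(unclass(a1)[, inv, drop = FALSE], 2L,
                        function(col) length(unique(col)) == 1L)))
  tt <- attr(a1, "true_tree")
  expect_equal(nrow(tt$edge), nrow(tr$edge))
  expect_true(all(tt$edge.length > 0))
})

test_that("coverage masking hits the target X fraction exactly", {
  tr <- simulate_tree(cfg)
  model <- phylo_model("mtMAM")
  aln <- simulate_alignment(tr, model, 300L, seed = 2L)
  masked <- mask_coverage(aln, fraction = c(0, 0.2, 0.25, 0.3, 0.5),
                          seed = 3L)
  xfrac <- rowMeans(unclass(masked) == "X")
  expect_equal(unname(xfrac), c(0, 0.2, 0.25, 0.3, 0.5), tolerance = 1e-9)
  expect_error(mask_coverage(aln, 1.2), "in \\[0, 1\\]")
})

test_that("deamidation ratio decays with age inside the configured range", {
  ages <- seq(0, 300, by = 10)
  r <- vapply(ages, function(a)
    zoomsphylo:::deamidation_ratio_for_age(cfg, a), numeric(1L))
  expect_true(all(diff(r) < 0))
  expect_true(all(r >= cfg$deam_range[1L] & r <= cfg$deam_range[2L]))
})

test_that("simulated spectra carry the injected reporter pair", {
  s <- collagen_sequence("t", paste(rep("GPAGKAAGLRGDRGESGPAGK", 8),
                                    collapse = ""))
  pl <- simulate_spectrum(s, cfg, sample_age = 150, seed = 4L,
                          sample_id = "spec")
  expect_s3_class(pl, "peaklist")
  di <- deamidation_index(pl)
  expect_false(is.na(di))
  expect_equal(di, attr(pl, "true_ratio"), tolerance = 0.05)
  # old sample: ratio near the degraded end
  expect_lt(di, 0.65)
})

test_that("end-to-end bundles are reproducible and internally consistent", {
  b1 <- simulate_dataset(cfg)
  b2 <- simulate_dataset(cfg)
  expect_identical(unclass(b1$alignment)[, ], unclass(b2$alignment)[, ])
  expect_identical(b1$manifest, b2$manifest)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))
  # manifest coverage equals the masked alignment's realized coverage
  cov <- 1 - rowMeans(unclass(b1$masked_alignment) == "X")
  expect_equal(unname(cov[b1$manifest$taxon]),
               unname(b1$manifest$coverage), tolerance = 0.02)
  expect_true(all(abs(b1$manifest$coverage[-1L] -
                        b1$manifest$target_coverage[-1L]) < 0.05))
  # screening the bundle's spectra recovers the true taxa
  ids <- screen_samples(b1$spectra, b1$panel)
  expect_equal(ids$assignment, b1$manifest$taxon)
  expect_equal(ids$preservation[b1$manifest$poor], "poor")
})
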