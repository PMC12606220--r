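topo4 <- ape::read.tree(text = "((A:10,B:10):20,(C:15,D:15):15);")

test_that("calibrations resolve to stem or crown nodes and validate", {
  expect_error(calibration("A", 30, 20), "min_age < max_age")
  expect_error(calibration("A", -1, 20), "non-negative")
  crown_ab <- calibration(c("A", "B"), 20, 50, node = "crown")
  stem_ab <- calibration(c("A", "B"), 20, 50, node = "stem")
  expect_equal(zoomsphylo:::calibration_node(topo4, crown_ab),
               ape::getMRCA(topo4, c("A", "B")))
  expect_equal(zoomsphylo:::calibration_node(topo4, stem_ab), 5L)  # root
  single_stem <- calibration("A", 20, 50, node = "stem")
  expect_equal(zoomsphylo:::calibration_node(topo4, single_stem),
               ape::getMRCA(topo4, c("A", "B")))
  expect_error(zoomsphylo:::calibration_node(
    topo4, calibration("A", 20, 50, node = "crown")), "resolves to a tip")
  expect_error(zoomsphylo:::calibration_node(
    topo4, calibration(c("A", "Z"), 20, 50)), "not in tree")
})

test_that("calibration tables round-trip through TSV", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(c("taxa\tmin_age\tmax_age\tnode",
               "A,B,C,D\t23.03\t54.6\tcrown",
               "A,B\t23.03\t54.6\tcrown"), tmp)
  cals <- read_calibrations(tmp)
  expect_length(cals, 2L)
  expect_equal(cals[[1L]]$taxa, c("A", "B", "C", "D"))
  expect_equal(cals[[2L]]$max_age, 54.6)
  expect_equal(cals[[1L]]$node, "crown")
})

test_that("dating state enforces a root calibration and consistency", {
  expect_error(zoomsphylo:::dating_state(
    topo4, list(calibration(c("A", "B"), 20, 50, "crown"))),
    "root must carry a calibration")
  expect_error(zoomsphylo:::dating_state(
    topo4, list(calibration(c("A", "B", "C", "D"), 10, 20, "crown"),
                calibration(c("A", "B"), 30, 50, "crown"))),
    "inconsistent calibrations")
  expect_error(zoomsphylo:::dating_state(
    topo4, list(calibration(c("A", "B", "C", "D"), 10, 60, "crown"),
                calibration(c("A", "B"), 20, 50, "stem"))),
    "same node")
})

test_that("hpd_interval is the shortest covering window", {
  expect_equal(hpd_interval(1:100, 0.95), c(1, 95))
  x <- c(rep(0, 90), seq(10, 100, length.out = 10))
  h <- hpd_interval(x, 0.90)
  expect_equal(h[1L], 0)
  expect_lt(h[2L] - h[1L], 100)
  expect_error(hpd_interval(1:10, 1.5), "in \\(0, 1\\)")
  expect_error(hpd_interval(1), "at least 2")
  # contains at least the nominal mass
  set.seed(2)
  y <- rnorm(2000)
  h2 <- hpd_interval(y, 0.95)
  expect_gte(mean(y >= h2[1L] & y <= h2[2L]), 0.95)
})

test_that("ess flags degenerate and anti-correlated traces", {
  expect_error(ess(1:5), "at least 10")
  d <- ess(rep(3, 50))
  expect_equal(as.numeric(d), 50)
  expect_true(attr(d, "degenerate"))
  alt <- rep(c(0, 1), 200)
  a <- ess(alt)
  expect_true(isTRUE(attr(a, "superefficient")))
  expect_gt(as.numeric(a), length(alt))
  set.seed(4)
  iid <- rnorm(4000)
  expect_gt(as.numeric(ess(iid)), 1500)
  # strongly autocorrelated chain has a much lower ESS
  ar <- as.numeric(stats::arima.sim(list(ar = 0.95), 4000))
  expect_lt(as.numeric(ess(ar)), as.numeric(ess(iid)) / 5)
})

test_that("prior-only MCMC respects bounds and node ordering", {
  model <- phylo_model("mtMAM")
  cals <- list(calibration(c("A", "B", "C", "D"), 60, 80, "crown"),
               calibration(c("A", "B"), 23.03, 54.6, "crown"))
  run <- mcmc_date(NULL, topo4, model, cals, chain_length = 4000L,
                   sample_every = 10L, n_chains = 2L, seed = 8L,
                   prior_only = TRUE)
  expect_s3_class(run, "dating_chains")
  expect_length(run$chains, 2L)
  d <- run$chains[[1L]]
  root_col <- paste0("age_", 5L)
  ab_col <- paste0("age_", ape::getMRCA(topo4, c("A", "B")))
  expect_true(all(d[[root_col]] >= 60 & d[[root_col]] <= 80))
  expect_true(all(d[[ab_col]] >= 23.03 & d[[ab_col]] <= 54.6))
  # every internal node is younger than its parent
  cd_col <- paste0("age_", ape::getMRCA(topo4, c("C", "D")))
  expect_true(all(d[[ab_col]] < d[[root_col]]))
  expect_true(all(d[[cd_col]] < d[[root_col]]))
  expect_true(all(d[[cd_col]] > 0))
  expect_error(mcmc_date(NULL, ape::unroot(topo4), model, cals,
                         prior_only = TRUE), "rooted")
  expect_error(mcmc_date(NULL, topo4, model, cals, chain_length = 5L,
                         sample_every = 10L), "chain_length")
})

test_that("posterior summaries produce a coherent dated tree", {
  sim <- simulate_dataset(sim_config(n_taxa = 5L, seq_length = 300L,
                                     seed = 3L))
  model <- phylo_model("mtMAM", frequencies = "observed",
                       aln = sim$alignment)
  cals <- list(calibration(rownames(sim$alignment), 23.03, 54.6, "crown"))
  run <- mcmc_date(sim$alignment, sim$tree, model, cals,
                   chain_length = 4000L, sample_every = 10L,
                   n_chains = 1L, seed = 2L,
                   clock_mean = sim$config$clock_mean)
  s <- summarize_dating(run)
  expect_s3_class(s, "dating_summary")
  expect_equal(nrow(s$nodes), sim$tree$Nnode)
  expect_true(all(s$nodes$hpd_low <= s$nodes$mean_age))
  expect_true(all(s$nodes$hpd_high >= s$nodes$mean_age))
  expect_true(all(s$params$parameter ==
                    c("clock_mean", "clock_sd", "birth", "death")))
  expect_true(all(s$tree$edge.length >= 0))
  # the summary tree's root depth equals the root's posterior mean age
  depth <- max(ape::node.depth.edgelength(s$tree))
  expect_equal(depth, s$nodes$mean_age[s$nodes$node == 6L],
               tolerance = 1e-6)
})
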