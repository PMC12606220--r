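# One-config orchestration of the analysis stages: PMF screening ->
# alignment assembly -> ML tree + bootstrap (+ topology tests) -> dating.

#' Run the collagen analysis pipeline
#'
#' Executes the requested stages in order, writes each stage's artifacts to
#' `out_dir`, and returns (and writes as JSON) a run report. Every random
#' step is driven by the single `seed` recorded in the report. A failing
#' sample during screening is logged and reported indeterminate rather than
#' aborting the batch.
#'
#' Configuration entries (in-memory objects or file paths):
#' \describe{
#'   \item{stages}{Subset of `"screen"`, `"assemble"`, `"ml"`, `"autest"`,
#'     `"date"`.}
#'   \item{peaklists, panel}{For screening: list of [peaklist()] (or a
#'     directory of TSV peak lists) and a [marker_panel()] (or panel TSV).}
#'   \item{peptide_sets, reference}{For assembly: list of
#'     [recovered_peptides()] (or TSV) and the reference
#'     [collagen_sequence()] (or FASTA).}
#'   \item{alignment}{Alignment used by `ml`/`date` when `assemble` is not
#'     run (path or [aa_alignment()]).}
#'   \item{model}{List passed to [phylo_model()]; default
#'     mtMAM+F+I+R2.}
#'   \item{bootstrap}{Bootstrap replicate count (0 disables).}
#'   \item{candidate_trees}{Newick path or `multiPhylo` for the AU test.}
#'   \item{calibrations}{List of [calibration()] or calibration TSV.}
#'   \item{chain_length, sample_every, n_chains}{MCMC settings.}
#' }
#'
#' @param config Named list (see details) or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @return List of class `run_report`; also written to
#'   `file.path(out_dir, "report.json")`.
#' @export
run_pipeline <- function(config, out_dir = "pipeline_out", seed = 1L) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the yaml package")
    config <- yaml::read_yaml(config)
  }
  stages <- config$stages %||% c("screen", "assemble", "ml", "date")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = seed, stages = stages, timings = list())
  aln <- NULL
  fit <- NULL

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- fun()
    report$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }

  if ("screen" %in% stages) {
    pls <- config$peaklists
    if (is.character(pls))
      pls <- lapply(list.files(pls, full.names = TRUE), read_peaklist)
    panel <- config$panel
    if (is.character(panel)) panel <- read_marker_panel(panel)
    if (is.null(pls) || is.null(panel))
      stop("screening needs 'peaklists' and 'panel'")
    ids <- run_stage("screen", function()
      screen_samples(pls, panel,
                     tolerance = config$tolerance %||% 0.2,
                     min_markers = config$min_markers %||% 2L))
    utils::write.table(ids, file.path(out_dir, "identifications.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$identifications <- ids
  }

  if ("assemble" %in% stages) {
    sets <- config$peptide_sets
    if (is.character(sets)) sets <- read_recovered_peptides(sets)
    ref <- config$reference
    if (is.character(ref)) ref <- read_collagen_fasta(ref)[[1L]]
    if (is.null(sets) || is.null(ref))
      stop("assembly needs 'peptide_sets' and 'reference'")
    aln <- run_stage("assemble", function()
      assemble_alignment(sets, ref))
    write_alignment(aln, file.path(out_dir, "alignment.fasta"), "fasta")
    stats <- coverage_stats(aln)
    report$coverage <- as.list(stats$coverage)
    report$n_variable_columns <- stats$n_variable
  }
  if (is.null(aln) && !is.null(config$alignment)) {
    aln <- config$alignment
    if (is.character(aln) && !is.matrix(aln)) aln <- read_alignment(aln)
  }

  if ("ml" %in% stages) {
    if (is.null(aln)) stop("ML stage needs an alignment")
    mspec <- config$model %||% list()
    model <- phylo_model(
      mspec$exchangeabilities %||% "mtMAM",
      frequencies = if (isTRUE(mspec$observed_freq %||% TRUE)) "observed",
      aln = aln,
      p_inv = mspec$p_inv %||% 0.2,
      rate_weights = mspec$rate_weights %||% c(0.5, 0.5),
      rates = mspec$rates %||% c(0.3, 1.7))
    fit <- run_stage("ml", function()
      nni_search(aln, model, seed = seed))
    ape::write.tree(fit$tree, file.path(out_dir, "ml_tree.nwk"))
    report$ml <- list(logL = fit$logL,
                      tree = ape::write.tree(fit$tree))
    nboot <- config$bootstrap %||% 0L
    if (nboot > 0L) {
      btree <- run_stage("bootstrap", function()
        bootstrap_support(aln, fit$model, fit$tree,
                          replicates = nboot, seed = seed))
      ape::write.tree(btree, file.path(out_dir, "ml_tree_support.nwk"))
      report$bootstrap <- list(replicates = nboot,
                               support = attr(btree, "support"))
    }
  }

  if ("autest" %in% stages) {
    trees <- config$candidate_trees
    if (is.character(trees)) trees <- ape::read.tree(trees)
    if (is.null(trees)) stop("AU test needs 'candidate_trees'")
    if (is.null(fit)) stop("AU test runs after the ML stage")
    res <- run_stage("autest", function()
      topology_test(aln, trees, fit$model,
                    B = config$au_B %||% 10000L, seed = seed))
    utils::write.table(res$table, file.path(out_dir, "au_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$au_test <- res$table
  }

  if ("date" %in% stages) {
    if (is.null(aln)) stop("dating needs an alignment")
    cals <- config$calibrations
    if (is.character(cals)) cals <- read_calibrations(cals)
    if (is.null(cals)) stop("dating needs 'calibrations'")
    topo <- config$dating_topology
    if (is.null(topo)) {
      if (is.null(fit)) stop("dating needs a topology (run ml or supply one)")
      topo <- ape::root(fit$tree, outgroup = fit$tree$tip.label[1L],
                        resolve.root = TRUE)
    }
    dmodel <- if (!is.null(fit)) fit$model else
      phylo_model("mtMAM", frequencies = "observed", aln = aln)
    run <- run_stage("date", function()
      mcmc_date(aln, topo, dmodel, cals,
                chain_length = config$chain_length %||% 200000L,
                sample_every = config$sample_every %||% 100L,
                n_chains = config$n_chains %||% 3L, seed = seed))
    summ <- summarize_dating(run)
    ape::write.tree(summ$tree, file.path(out_dir, "mcc_tree.nwk"))
    report$dating <- list(nodes = summ$nodes, params = summ$params)
  }

  arts <- list.files(out_dir, full.names = TRUE)
  arts <- arts[basename(arts) != "report.json"]
  report$artifacts <- as.list(tools::md5sum(arts))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  class(report) <- "run_report"
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (seed", x$seed, ")\n")
  cat("  stages:", paste(x$stages, collapse = ", "), "\n")
  for (nm in names(x$timings))
    cat(sprintf("  %-10s %8.2f s\n", nm, x$timings[[nm]]))
  invisible(x)
}
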