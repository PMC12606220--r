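# Tree search by NNI hill climbing, nonparametric bootstrap support, and
# likelihood-based model selection.

# Quick starting tree: NJ on Poisson-corrected amino-acid p-distances,
# X-aware (pairwise deletion).
starting_tree <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "X" & m[j, ] != "X"
    p <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
    D[i, j] <- D[j, i] <- -log(max(1 - p, 1e-3))
  }
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < BL_MIN] <- BL_MIN
  tr
}

# One branch-length-only fit used inside the search loops.
quick_fit <- function(aln, tree, model, tol = 1e-3, max_iter = 3L)
  fit_ml(aln, tree, model, optim_pinv = FALSE, optim_rates = FALSE,
         tol = tol, max_iter = max_iter)

#' Maximum-likelihood tree search by nearest-neighbour interchange
#'
#' Hill climbing over NNI rearrangements with branch-length re-optimization
#' at every step; model parameters are held fixed during the topology moves
#' and re-optimized on the final tree. With `restarts > 1` additional climbs
#' start from random topologies and the best result over all restarts is
#' returned. Deterministic given `seed`.
#'
#' @param aln An [aa_alignment()] with at least 4 taxa.
#' @param model A [phylo_model()].
#' @param start Optional starting `phylo` tree; default is a neighbour-joining
#'   tree on corrected p-distances.
#' @param restarts Number of independent climbs.
#' @param seed Integer seed.
#' @param final_full_fit Re-optimize model parameters on the best topology.
#' @param constraint Optional predicate `function(tree) TRUE/FALSE`; only
#'   topologies satisfying it are considered (e.g. a monophyly constraint
#'   built with [monophyly_constraint()]). The starting tree must satisfy it.
#' @return A `collagen_ml` fit on the best topology found.
#' @export
nni_search <- function(aln, model, start = NULL, restarts = 1L, seed = 1L,
                       final_full_fit = TRUE, constraint = NULL) {
  taxa <- rownames(aln)
  if (length(taxa) < 4L) stop("NNI search needs at least 4 taxa")
  ok <- function(tr) is.null(constraint) || isTRUE(constraint(tr))
  best_fit <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    tr <- if (r == 1L && !is.null(start)) start
          else if (r == 1L) starting_tree(aln)
          else ape::rtree(length(taxa), tip.label = sample(taxa),
                          br = function(n) stats::runif(n, 0.01, 0.2))
    tr <- ape::unroot(tr)
    if (!ok(tr)) {
      if (r == 1L)
        stop("the starting tree violates the topology constraint; ",
             "supply a compliant 'start' tree")
      next
    }
    fit <- quick_fit(aln, tr, model)
    repeat {
      nbrs <- phangorn::nni(fit$tree)
      improved <- FALSE
      cand_best <- fit
      for (j in seq_along(nbrs)) {
        nb <- nbrs[[j]]   # [[.multiPhylo restores compressed tip labels
        if (!ok(nb)) next
        if (is.null(nb$edge.length))
          nb$edge.length <- rep(0.05, nrow(nb$edge))
        nb$edge.length[nb$edge.length < BL_MIN] <- BL_MIN
        f <- quick_fit(aln, nb, fit$model)
        if (f$logL > cand_best$logL + 1e-8) {
          cand_best <- f
          improved <- TRUE
        }
      }
      if (!improved) break
      fit <- cand_best
    }
    if (is.null(best_fit) || fit$logL > best_fit$logL) best_fit <- fit
  }
  if (final_full_fit)
    best_fit <- fit_ml(aln, best_fit$tree, best_fit$model)
  best_fit
}

#' Monophyly constraint for topology searches
#'
#' Builds a predicate suitable for `nni_search(constraint = ...)` that is
#' `TRUE` when `taxa` form a monophyletic group. On unrooted trees
#' monophyly is assessed as a bipartition (the clade or its complement).
#'
#' @param taxa Character vector of tip labels (>= 2).
#' @return `function(tree) -> logical`.
#' @export
monophyly_constraint <- function(taxa) {
  if (length(taxa) < 2L) stop("a monophyly constraint needs >= 2 taxa")
  force(taxa)
  function(tree) {
    if (!all(taxa %in% tree$tip.label)) return(FALSE)
    isTRUE(ape::is.monophyletic(tree, taxa)) ||
      isTRUE(ape::is.monophyletic(tree, setdiff(tree$tip.label, taxa)))
  }
}

#' Nonparametric bootstrap support
#'
#' Resamples alignment columns with replacement; each replicate gets a
#' branch-length re-fit on the maximum-likelihood topology followed by a
#' cheap NNI re-search. Support of each internal branch of the ML tree is
#' the percentage of replicate trees containing that bipartition.
#'
#' @param aln An [aa_alignment()].
#' @param model A [phylo_model()] (typically from the ML fit).
#' @param best `phylo` tree or `collagen_ml` fit whose branches are scored.
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return The ML tree with `node.label` holding support percentages; the
#'   replicate trees are attached as attribute `"trees"`.
#' @export
bootstrap_support <- function(aln, model, best, replicates = 100L,
                              seed = 1L) {
  if (replicates < 1L) stop("'replicates' must be >= 1")
  if (inherits(best, "collagen_ml")) best <- best$tree
  m <- unclass(aln)
  set.seed(seed)
  reps <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    raln <- aa_alignment(m[, cols, drop = FALSE])
    fit <- quick_fit(raln, best, model)
    # one sweep of NNI moves
    repeat {
      nbrs <- phangorn::nni(fit$tree)
      cand <- fit
      for (j in seq_along(nbrs)) {
        nb <- nbrs[[j]]
        if (is.null(nb$edge.length))
          nb$edge.length <- rep(0.05, nrow(nb$edge))
        f <- quick_fit(raln, nb, model, max_iter = 1L)
        if (f$logL > cand$logL + 1e-8) cand <- f
      }
      if (cand$logL <= fit$logL + 1e-8) break
      fit <- cand
    }
    reps[[b]] <- fit$tree
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(best, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / replicates, 1)
  out <- best
  out$node.label <- as.character(support)
  attr(out, "support") <- support
  attr(out, "trees") <- reps
  out
}

#' Model selection by AIC/BIC over empirical-model variants
#'
#' Fits every combination of exchangeability table, frequency mode,
#' invariant-sites class and rate mixture on a fixed topology and ranks the
#' fits by the chosen criterion.
#'
#' @param aln An [aa_alignment()].
#' @param tree `phylo` topology used for every candidate.
#' @param exchangeabilities Character vector of tables to try.
#' @param criterion `"AIC"` or `"BIC"`.
#' @return Object of class `model_selection`: ranked data frame (`$table`)
#'   and the best fit (`$best`).
#' @export
model_select <- function(aln, tree, exchangeabilities = c("mtMAM", "mtREV"),
                         criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  grid <- expand.grid(ex = exchangeabilities, freq = c(FALSE, TRUE),
                      inv = c(FALSE, TRUE), r2 = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    mod <- phylo_model(g$ex,
                       frequencies = if (g$freq) "observed" else NULL,
                       aln = if (g$freq) aln else NULL,
                       p_inv = if (g$inv) 0.2 else 0,
                       rate_weights = if (g$r2) c(0.5, 0.5) else 1,
                       rates = if (g$r2) c(0.3, 1.7) else 1)
    fit <- fit_ml(aln, tree, mod, optim_pinv = g$inv, optim_rates = g$r2)
    n <- fit$n_sites
    name <- paste0(g$ex, if (g$freq) "+F", if (g$inv) "+I",
                   if (g$r2) "+R2")
    rows[[i]] <- data.frame(model = name, logL = fit$logL, df = fit$df,
                            AIC = -2 * fit$logL + 2 * fit$df,
                            BIC = -2 * fit$logL + log(n) * fit$df,
                            stringsAsFactors = FALSE)
    fits[[i]] <- fit
  }
  tab <- do.call(rbind, rows)
  o <- order(tab[[criterion]])
  structure(list(table = tab[o, ], best = fits[[o[1L]]],
                 criterion = criterion),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Substitution-model selection (ranked by", x$criterion, ")\n")
  print(x$table, row.names = FALSE, digits = 6)
  invisible(x)
}
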