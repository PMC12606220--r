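# Phylogenetic likelihood under phylo_model: Felsenstein pruning (C++ core)
# with X as fully missing data, an invariant-sites class and free-rate
# mixture categories; maximum-likelihood fitting by coordinate ascent.

BL_MIN <- 1e-8
BL_MAX <- 10
RATE_MIN <- 1e-4
RATE_MAX <- 100

# Compress an alignment to site patterns in the row order of `taxa`.
aln_patterns <- function(aln, taxa) {
  m <- unclass(aln)
  if (!all(taxa %in% rownames(m)))
    stop("alignment is missing taxa: ",
         paste(setdiff(taxa, rownames(m)), collapse = ", "))
  m <- m[taxa, , drop = FALSE]
  states <- match(m, AA_STATES)        # NA for X
  states[is.na(states)] <- 0L
  dim(states) <- dim(m)
  key <- apply(states, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(states = t(states[, first, drop = FALSE]),   # pattern x taxon
       weights = as.numeric(tabulate(idx, nbins = sum(first))),
       site_index = idx)
}

# Pattern log-likelihoods under the full mixture (invariant + free rates).
pattern_loglik <- function(states, tree_post, model) {
  edge <- tree_post$edge
  root <- edge[nrow(edge), 1L]   # postorder: last edge's parent is basal
  ll_cat <- pruning_loglik_cpp(edge, length(tree_post$tip.label), states,
                               tree_post$edge.length, model$eig$U,
                               model$eig$Uinv, model$eig$values, model$pi,
                               model$rates, root)
  w <- model$weights
  M <- apply(ll_cat, 1L, max)
  var_term <- M + log(as.vector(exp(ll_cat - M) %*% w))
  if (model$p_inv > 0) {
    inv_lik <- apply(states, 1L, function(s) {
      obs <- s[s > 0L]
      if (!length(obs)) return(1)
      if (all(obs == obs[1L])) model$pi[obs[1L]] else 0
    })
    t1 <- ifelse(inv_lik > 0, log(model$p_inv * inv_lik), -Inf)
    t2 <- log1p(-model$p_inv) + var_term
    hi <- pmax(t1, t2)
    hi + log(exp(t1 - hi) + exp(t2 - hi))
  } else {
    var_term
  }
}

check_tree_aln <- function(tree, aln) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape phylo tree")
  if (length(tree$tip.label) < 2L)
    stop("tree has no tip labels (a compressed multiPhylo element?)")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (!all(tree$tip.label %in% rownames(aln)))
    stop("taxon mismatch between tree and alignment: ",
         paste(setdiff(tree$tip.label, rownames(aln)), collapse = ", "))
  invisible(TRUE)
}

#' Per-site log-likelihoods of an alignment on a tree
#'
#' Felsenstein pruning under a [phylo_model()]; `X` cells are treated as
#' fully missing (partial likelihood one for every state). The site
#' likelihood mixes the invariant class and the free-rate categories:
#' `L = p_inv * [constant-site term] + (1 - p_inv) * sum_k w_k L(r_k)`.
#'
#' @param tree `phylo` tree (rooted or unrooted) with branch lengths in
#'   substitutions/site.
#' @param aln An [aa_alignment()].
#' @param model A [phylo_model()].
#' @return Numeric vector of per-column log-likelihoods.
#' @export
site_log_likelihoods <- function(tree, aln, model) {
  check_tree_aln(tree, aln)
  pat <- aln_patterns(aln, tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  ll <- pattern_loglik(pat$states, post, model)
  unname(ll[pat$site_index])
}

# Total log-likelihood on compressed patterns (internal fast path).
total_loglik <- function(pat, post, model)
  sum(pat$weights * pattern_loglik(pat$states, post, model))

#' Maximum-likelihood fit of branch lengths and model parameters
#'
#' Coordinate-ascent optimization: Brent line searches over each branch
#' length (bounds `[1e-8, 10]`), the invariant-sites proportion and the
#' free-rate mixture (first-category weight and rate; the remaining rate is
#' solved from the mean-rate constraint). The log-likelihood is
#' non-decreasing across sweeps and iteration stops when a full sweep gains
#' less than `tol`.
#'
#' @param aln An [aa_alignment()].
#' @param tree Starting `phylo` tree (its topology is kept fixed).
#' @param model Starting [phylo_model()].
#' @param optim_branches,optim_pinv,optim_rates Which parameter blocks to
#'   free.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Maximum number of sweeps.
#' @return Object of class `collagen_ml`: `tree` (optimized branch lengths),
#'   `model`, `logL`, `df`, plus the data used.
#' @export
fit_ml <- function(aln, tree, model, optim_branches = TRUE,
                   optim_pinv = TRUE, optim_rates = TRUE,
                   tol = 1e-6, max_iter = 50L) {
  check_tree_aln(tree, aln)
  post <- ape::reorder.phylo(tree, "postorder")
  post$edge.length <- pmin(pmax(post$edge.length, BL_MIN), BL_MAX)
  pat <- aln_patterns(aln, post$tip.label)
  model <- normalize_model(model)
  ll <- total_loglik(pat, post, model)
  if (!is.finite(ll)) {
    bad <- which(!is.finite(pattern_loglik(pat$states, post, model)))[1L]
    stop("non-finite likelihood at alignment pattern ", bad)
  }
  K <- length(model$rates)
  for (iter in seq_len(max_iter)) {
    ll_prev <- ll
    if (optim_branches) {
      for (e in seq_len(nrow(post$edge))) {
        f <- function(x) {
          post$edge.length[e] <- x
          total_loglik(pat, post, model)
        }
        opt <- stats::optimize(f, c(BL_MIN, BL_MAX), maximum = TRUE,
                               tol = 1e-6)
        if (opt$objective > ll) {
          post$edge.length[e] <- opt$maximum
          ll <- opt$objective
        }
      }
    }
    if (optim_pinv) {
      f <- function(p) {
        m2 <- model; m2$p_inv <- p
        total_loglik(pat, post, normalize_model(m2))
      }
      opt <- stats::optimize(f, c(0, 0.95), maximum = TRUE, tol = 1e-5)
      if (opt$objective > ll) {
        model$p_inv <- opt$maximum
        model <- normalize_model(model)
        ll <- opt$objective
      }
    }
    if (optim_rates && K == 2L) {
      # slow-category relative rate (ratio to the fast one), then weight
      f_r <- function(rel) {
        m2 <- model; m2$rates <- c(rel, 1)
        total_loglik(pat, post, normalize_model(m2))
      }
      opt <- stats::optimize(f_r, c(1e-3, 1), maximum = TRUE, tol = 1e-5)
      if (opt$objective > ll) {
        model$rates <- c(opt$maximum, 1)
        model <- normalize_model(model)
        ll <- opt$objective
      }
      f_w <- function(w1) {
        m2 <- model; m2$weights <- c(w1, 1 - w1)
        total_loglik(pat, post, normalize_model(m2))
      }
      opt <- stats::optimize(f_w, c(0.01, 0.99), maximum = TRUE, tol = 1e-5)
      if (opt$objective > ll) {
        model$weights <- c(opt$maximum, 1 - opt$maximum)
        model <- normalize_model(model)
        ll <- opt$objective
      }
    }
    if (ll - ll_prev < tol) break
  }
  structure(list(tree = post, model = model, logL = ll,
                 df = model_df(model, nrow(post$edge)),
                 n_sites = length(pat$site_index), pat = pat),
            class = "collagen_ml")
}

#' @export
logLik.collagen_ml <- function(object, ...)
  structure(object$logL, df = object$df, nobs = object$n_sites,
            class = "logLik")

#' @export
print.collagen_ml <- function(x, ...) {
  cat("Maximum-likelihood collagen phylogeny\n")
  cat("  taxa:", length(x$tree$tip.label), "  sites:", x$n_sites,
      "  log-likelihood:", sprintf("%.4f", x$logL), "\n")
  print(x$model)
  invisible(x)
}

#' @export
plot.collagen_ml <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  invisible(x)
}
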