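# Exhaustive-enumeration likelihood oracle, independent of the package's
# pruning path: the rate matrix is rebuilt from scratch, transition
# probabilities come from Matrix::expm (scaling-and-squaring, not the
# package's symmetrized eigen route), and internal-node states are summed by
# explicit enumeration (feasible for <= 4 taxa).

ORACLE_STATES <- strsplit("ARNDCQEGHILKMFPSTWYV", "", fixed = TRUE)[[1L]]

oracle_q <- function(model) {
  pi <- as.numeric(model$pi) / sum(model$pi)
  Q <- model$S * rep(pi, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

# Per-site log-likelihoods by brute force (invariant class + rate mixture).
oracle_site_loglik <- function(tree, aln, model) {
  post <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(post$tip.label)
  edge <- post$edge
  root <- edge[nrow(edge), 1L]
  internal <- sort(unique(edge[, 1L]))
  Q <- oracle_q(model)
  pi <- as.numeric(model$pi) / sum(model$pi)
  m <- unclass(aln)[post$tip.label, , drop = FALSE]
  tip_state <- matrix(match(m, ORACLE_STATES), nrow(m), ncol(m))  # NA = X
  A <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  icol <- function(node) match(node, internal)

  lik_rate <- function(rate) {
    P <- lapply(seq_len(nrow(edge)), function(e)
      as.matrix(Matrix::expm(Q * post$edge.length[e] * rate)))
    vapply(seq_len(ncol(m)), function(site) {
      f <- pi[A[, icol(root)]]
      for (e in seq_len(nrow(edge))) {
        par <- A[, icol(edge[e, 1L])]
        chi <- edge[e, 2L]
        if (chi <= n_tip) {
          s <- tip_state[chi, site]
          if (!is.na(s)) f <- f * P[[e]][cbind(par, s)]
          # X tip: sum_j P[par, j] = 1, no factor
        } else {
          f <- f * P[[e]][cbind(par, A[, icol(chi)])]
        }
      }
      sum(f)
    }, numeric(1L))
  }

  Lvar <- 0
  for (k in seq_along(model$rates))
    Lvar <- Lvar + model$weights[k] * lik_rate(model$rates[k])
  if (model$p_inv > 0) {
    Linv <- vapply(seq_len(ncol(m)), function(site) {
      obs <- tip_state[, site]
      obs <- obs[!is.na(obs)]
      if (!length(obs)) 1
      else if (all(obs == obs[1L])) pi[obs[1L]]
      else 0
    }, numeric(1L))
    log(model$p_inv * Linv + (1 - model$p_inv) * Lvar)
  } else {
    log(Lvar)
  }
}

# Random small instance (tree + alignment + model) for property tests.
random_small_case <- function(seed) {
  set.seed(seed)
  n <- sample(3:4, 1L)
  rooted <- n == 3L || stats::runif(1) < 0.5
  tr <- ape::rtree(n, rooted = rooted,
                   br = function(k) stats::runif(k, 0.02, 1.2))
  tr$tip.label <- paste0("t", seq_len(n))
  n_sites <- 25L
  m <- matrix(sample(ORACLE_STATES, n * n_sites, replace = TRUE),
              n, n_sites, dimnames = list(tr$tip.label, NULL))
  m[stats::runif(length(m)) < 0.1] <- "X"
  aln <- aa_alignment(m)
  pi <- if (stats::runif(1) < 0.5) NULL else {
    g <- stats::rgamma(20L, 2); g / sum(g)
  }
  two_rates <- stats::runif(1) < 0.6
  model <- phylo_model(
    sample(c("mtMAM", "mtREV"), 1L),
    frequencies = pi,
    p_inv = if (stats::runif(1) < 0.6) stats::runif(1, 0, 0.5) else 0,
    rate_weights = if (two_rates) stats::runif(2, 0.2, 1) else 1,
    rates = if (two_rates) sort(stats::runif(2, 0.1, 2)) else 1)
  list(tree = tr, aln = aln, model = model)
}

# Plain RELL bootstrap proportion, coded independently of au_test().
rell_bp <- function(site_ll, B, seed) {
  set.seed(seed)
  n <- ncol(site_ll)
  wins <- numeric(nrow(site_ll))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    s <- rowSums(site_ll[, idx, drop = FALSE])
    mx <- which(s == max(s))
    w <- if (length(mx) == 1L) mx else sample(mx, 1L)
    wins[w] <- wins[w] + 1
  }
  wins / B
}
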