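# Bayesian node dating on a fixed topology: uncorrelated lognormal relaxed
# clock, birth-death prior on node ages conditioned on the root age,
# uniform fossil calibrations, Metropolis-Hastings sampling, and posterior
# summaries (HPD, ESS, MCC tree).

#' Fossil calibration on a clade age
#'
#' Uniform bound on the age (Ma) of the node from which a clade originates:
#' either the clade's own most recent common ancestor (`"crown"`) or its
#' parent node (`"stem"`). A calibration whose taxa cover the whole tree
#' always binds the root.
#'
#' @param taxa Character vector defining the clade.
#' @param min_age,max_age Uniform bounds in Ma, `min_age < max_age`.
#' @param node `"stem"` or `"crown"`.
#' @return Object of class `calibration`.
#' @export
calibration <- function(taxa, min_age, max_age, node = c("stem", "crown")) {
  node <- match.arg(node)
  if (!is.numeric(min_age) || !is.numeric(max_age) || min_age >= max_age)
    stop("calibration needs min_age < max_age")
  if (min_age < 0) stop("ages must be non-negative")
  structure(list(taxa = taxa, min_age = min_age, max_age = max_age,
                 node = node), class = "calibration")
}

#' Read a calibration table
#'
#' TSV columns: `taxa` (comma-separated tip labels), `min_age`, `max_age`,
#' optional `node` (stem/crown, default stem).
#'
#' @param path TSV file.
#' @return List of [calibration()] objects.
#' @export
read_calibrations <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    calibration(strsplit(tab$taxa[i], ",", fixed = TRUE)[[1L]],
                tab$min_age[i], tab$max_age[i],
                node = if ("node" %in% names(tab)) tab$node[i] else "stem"))
}

# Resolve a calibration to a node id on the tree.
calibration_node <- function(tree, cal) {
  taxa <- cal$taxa
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss))
    stop("calibrated clade member(s) not in tree: ", paste(miss, collapse = ", "))
  n_tip <- length(tree$tip.label)
  node <- if (length(taxa) == 1L) match(taxa, tree$tip.label)
          else ape::getMRCA(tree, taxa)
  root <- n_tip + 1L
  if (cal$node == "stem" && node != root) {
    node <- tree$edge[tree$edge[, 2L] == node, 1L]
  }
  if (node <= n_tip)
    stop("calibration resolves to a tip; use node = 'stem' for single taxa")
  node
}

# Unnormalized birth-death node-age kernel (complete sampling), and its
# normalizing integral on [0, t_root]. lambda > delta >= 0.
bd_log_kernel <- function(t, lambda, delta) {
  a <- lambda - delta
  2 * log(a) - a * t - 2 * log(lambda - delta * exp(-a * t))
}
bd_log_norm <- function(t_root, lambda, delta) {
  a <- lambda - delta
  if (delta < 1e-10)
    return(log((1 - exp(-a * t_root)) / a) + 2 * log(a) - 2 * log(lambda))
  u0 <- lambda - delta
  u1 <- lambda - delta * exp(-a * t_root)
  log(a / delta) + log(1 / u0 - 1 / u1)
}

# Internal bookkeeping for one dating run.
dating_state <- function(tree, calibrations) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  parent <- rep(NA_integer_, n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  cal_node <- vapply(calibrations, calibration_node, 0L, tree = tree)
  if (anyDuplicated(cal_node)) stop("two calibrations bind the same node")
  if (!root %in% cal_node)
    stop("the root must carry a calibration (uniform root bound)")
  bounds <- matrix(c(0, Inf), n_tip + tree$Nnode, 2L, byrow = TRUE)
  for (i in seq_along(calibrations))
    bounds[cal_node[i], ] <- c(calibrations[[i]]$min_age,
                               calibrations[[i]]$max_age)
  # consistency: a calibrated node's min must not exceed any ancestor's max
  for (nd in cal_node) {
    anc <- parent[nd]
    while (!is.na(anc)) {
      if (bounds[nd, 1L] > bounds[anc, 2L])
        stop("inconsistent calibrations: node bound [", bounds[nd, 1L], ", ",
             bounds[nd, 2L], "] exceeds ancestor maximum ", bounds[anc, 2L])
      anc <- parent[anc]
    }
  }
  list(n_tip = n_tip, root = root, internal = internal, parent = parent,
       children = children, cal_node = cal_node, bounds = bounds)
}

# Initial ages: tips at 0, each internal node above its children, calibrated
# nodes inside their bounds.
init_ages <- function(tree, st) {
  ages <- numeric(st$n_tip + tree$Nnode)
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1L]; chi <- post$edge[e, 2L]
    ages[par] <- max(ages[par], ages[chi])
  }
  # heights: assign each internal node halfway between child max and bound mid
  nodes_by_height <- unique(post$edge[, 1L])           # postorder parents
  for (nd in nodes_by_height) {
    lo <- max(ages[st$children[[as.character(nd)]]], st$bounds[nd, 1L])
    hi <- st$bounds[nd, 2L]
    if (!is.finite(hi)) hi <- lo * 1.5 + 1
    if (lo >= hi) stop("cannot initialize node ages inside calibration bounds")
    ages[nd] <- lo + 0.5 * (hi - lo)
  }
  ages
}

log_prior_ages <- function(ages, st, lambda, delta) {
  lp <- 0
  t_root <- ages[st$root]
  for (nd in st$internal) {
    kids <- st$children[[as.character(nd)]]
    if (ages[nd] <= max(ages[kids])) return(-Inf)
    if (ages[nd] < st$bounds[nd, 1L] || ages[nd] > st$bounds[nd, 2L])
      return(-Inf)
    if (nd == st$root) {
      lp <- lp - log(st$bounds[nd, 2L] - st$bounds[nd, 1L])
    } else if (nd %in% st$cal_node) {
      lp <- lp - log(st$bounds[nd, 2L] - st$bounds[nd, 1L])
    } else {
      lp <- lp + bd_log_kernel(ages[nd], lambda, delta) -
        bd_log_norm(t_root, lambda, delta)
    }
  }
  lp
}

#' Bayesian divergence dating by MCMC
#'
#' Samples node ages (Ma), per-branch lognormal rate multipliers, the mean
#' clock rate, the clock standard deviation and birth-death parameters on a
#' fixed rooted topology. Calibrated nodes take their uniform calibration
#' density; uncalibrated internal nodes follow the birth-death kernel
#' conditioned on the root age; the root requires a calibration. Proposals
#' are node-age slides (40%), rate-multiplier scalings (30%) and scalar
#' scalings (30%).
#'
#' @param aln An [aa_alignment()] (ignored when `prior_only = TRUE`).
#' @param topology Rooted binary `phylo` tree; branch lengths are ignored.
#' @param model A [phylo_model()].
#' @param calibrations List of [calibration()] objects; one must bind the
#'   root.
#' @param chain_length Proposals per chain.
#' @param sample_every Thinning interval.
#' @param n_chains Number of independent chains.
#' @param seed Integer seed (chain i uses `seed + i - 1`).
#' @param prior_only Switch the likelihood off (prior validation runs).
#' @param clock_mean,clock_sd,birth,death Initial values.
#' @return Object of class `dating_chains`: list of per-chain data frames
#'   (columns `age_<node>`, `clock_mean`, `clock_sd`, `birth`, `death`,
#'   `logL`, `logPrior`), plus the topology and run settings.
#' @export
mcmc_date <- function(aln, topology, model, calibrations,
                      chain_length = 200000L, sample_every = 100L,
                      n_chains = 3L, seed = 1L, prior_only = FALSE,
                      clock_mean = 0.005, clock_sd = 0.3,
                      birth = 0.1, death = 0.02) {
  if (chain_length < sample_every || chain_length < 1L)
    stop("'chain_length' must be >= 'sample_every' and positive")
  if (!ape::is.rooted(topology)) stop("'topology' must be rooted")
  st <- dating_state(topology, calibrations)
  post <- ape::reorder.phylo(topology, "postorder")
  pat <- if (!prior_only) aln_patterns(aln, post$tip.label) else NULL
  n_edge <- nrow(post$edge)
  edge_par <- post$edge[, 1L]; edge_chi <- post$edge[, 2L]

  loglik_fn <- function(ages, mult, mu) {
    if (prior_only) return(0)
    dur <- ages[edge_par] - ages[edge_chi]
    post$edge.length <- pmax(dur * mult * mu, 1e-12)
    total_loglik(pat, post, model)
  }
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    ages <- init_ages(topology, st)
    mult <- stats::rlnorm(n_edge, -clock_sd^2 / 2, clock_sd)
    mu <- clock_mean; sigma <- clock_sd; lam <- birth; del <- death
    lp_rates <- function(mult, sigma)
      sum(stats::dlnorm(mult, -sigma^2 / 2, sigma, log = TRUE)) +
        stats::dexp(sigma, 1, log = TRUE)
    lp_scalars <- function(mu, lam, del) {
      if (mu <= 1e-8 || mu > 10 || lam <= 1e-6 || lam > 5 ||
          del < 0 || del >= lam) return(-Inf)
      -log(mu)                      # log-uniform clock mean
    }
    lpa <- log_prior_ages(ages, st, lam, del)
    lpr <- lp_rates(mult, sigma)
    lps <- lp_scalars(mu, lam, del)
    ll <- loglik_fn(ages, mult, mu)
    n_samp <- floor(chain_length / sample_every)
    cols <- c(paste0("age_", st$internal), "clock_mean", "clock_sd",
              "birth", "death", "logL", "logPrior")
    out <- matrix(NA_real_, n_samp, length(cols),
                  dimnames = list(NULL, cols))
    srow <- 0L
    n_int <- length(st$internal)
    for (it in seq_len(chain_length)) {
      u <- stats::runif(1)
      if (u < 0.15) {                      # joint age/rate rescale
        # scales every internal age by f and the clock mean by 1/f; branch
        # durations * mu are unchanged, so the likelihood is invariant and
        # the move travels along the rate-time ridge
        f <- exp(stats::runif(1, -0.3, 0.3))
        prop <- ages
        prop[st$internal] <- ages[st$internal] * f
        mu2 <- mu / f
        lpa2 <- log_prior_ages(prop, st, lam, del)
        lps2 <- lp_scalars(mu2, lam, del)
        if (log(stats::runif(1)) <
            (lpa2 + lps2) - (lpa + lps) + (n_int - 1) * log(f)) {
          ages <- prop; mu <- mu2; lpa <- lpa2; lps <- lps2
        }
      } else if (u < 0.4) {                # node-age slide
        nd <- sample(st$internal, 1L)
        kids <- st$children[[as.character(nd)]]
        lo <- max(ages[kids], st$bounds[nd, 1L])
        hi <- min(if (is.na(st$parent[nd])) Inf else ages[st$parent[nd]],
                  st$bounds[nd, 2L])
        if (hi > lo) {
          prop <- ages; prop[nd] <- stats::runif(1, lo, hi)
          lpa2 <- log_prior_ages(prop, st, lam, del)
          ll2 <- loglik_fn(prop, mult, mu)
          if (log(stats::runif(1)) < (lpa2 + ll2) - (lpa + ll)) {
            ages <- prop; lpa <- lpa2; ll <- ll2
          }
        }
      } else if (u < 0.7) {                # rate-multiplier scale
        e <- sample.int(n_edge, 1L)
        f <- exp(stats::runif(1, -0.5, 0.5))
        m2 <- mult; m2[e] <- mult[e] * f
        lpr2 <- lp_rates(m2, sigma)
        ll2 <- loglik_fn(ages, m2, mu)
        if (log(stats::runif(1)) < (lpr2 + ll2) - (lpr + ll) + log(f)) {
          mult <- m2; lpr <- lpr2; ll <- ll2
        }
      } else {                             # scalar moves
        which_s <- sample(4L, 1L)
        f <- exp(stats::runif(1, -0.4, 0.4))
        if (which_s == 1L) {               # clock mean
          mu2 <- mu * f
          lps2 <- lp_scalars(mu2, lam, del)
          ll2 <- if (is.finite(lps2)) loglik_fn(ages, mult, mu2) else -Inf
          if (log(stats::runif(1)) < (lps2 + ll2) - (lps + ll) + log(f)) {
            mu <- mu2; lps <- lps2; ll <- ll2
          }
        } else if (which_s == 2L) {        # clock sd
          s2 <- sigma * f
          lpr2 <- lp_rates(mult, s2)
          if (log(stats::runif(1)) < lpr2 - lpr + log(f)) {
            sigma <- s2; lpr <- lpr2
          }
        } else if (which_s == 3L) {        # birth rate
          l2 <- lam * f
          lps2 <- lp_scalars(mu, l2, del)
          lpa2 <- if (is.finite(lps2)) log_prior_ages(ages, st, l2, del)
                  else -Inf
          if (log(stats::runif(1)) < (lps2 + lpa2) - (lps + lpa) + log(f)) {
            lam <- l2; lps <- lps2; lpa <- lpa2
          }
        } else {                           # death rate (slide in [0, birth))
          d2 <- del + stats::runif(1, -0.05, 0.05) * lam
          lps2 <- lp_scalars(mu, lam, d2)
          lpa2 <- if (is.finite(lps2)) log_prior_ages(ages, st, lam, d2)
                  else -Inf
          if (log(stats::runif(1)) < (lps2 + lpa2) - (lps + lpa)) {
            del <- d2; lps <- lps2; lpa <- lpa2
          }
        }
      }
      if (it %% sample_every == 0L) {
        srow <- srow + 1L
        out[srow, ] <- c(ages[st$internal], mu, sigma, lam, del, ll,
                         lpa + lpr + lps)
      }
    }
    chains[[ch]] <- as.data.frame(out)
  }
  structure(list(chains = chains, topology = topology, state = st,
                 sample_every = sample_every, prior_only = prior_only),
            class = "dating_chains")
}

#' @export
print.dating_chains <- function(x, ...) {
  cat("Relaxed-clock dating MCMC:", length(x$chains), "chain(s),",
      nrow(x$chains[[1L]]), "samples each",
      if (x$prior_only) "(prior only)", "\n")
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest interval containing `ceiling(mass * n)` of the sorted samples.
#'
#' @param samples Numeric vector (>= 2 values).
#' @param mass Probability mass in (0, 1).
#' @return `c(low, high)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (!is.numeric(mass) || mass <= 0 || mass >= 1)
    stop("'mass' must be in (0, 1)")
  x <- sort(samples)
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  k <- ceiling(mass * n)
  starts <- seq_len(n - k + 1L)
  widths <- x[starts + k - 1L] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + k - 1L])
}

#' Effective sample size of an MCMC trace
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated by the
#' initial-positive-sequence rule (stop at the first non-positive sum of an
#' even/odd lag pair). A constant trace returns `n` with a `degenerate`
#' attribute; anti-correlated traces can legitimately exceed `n` and are
#' flagged `superefficient`.
#'
#' @param samples Numeric vector (>= 10 values).
#' @return ESS (numeric scalar, possibly with flag attributes).
#' @export
ess <- function(samples) {
  n <- length(samples)
  if (n < 10L) stop("need at least 10 samples")
  if (stats::sd(samples) == 0)
    return(structure(as.numeric(n), degenerate = TRUE))
  rho <- stats::acf(samples, lag.max = min(n - 2L, 10000L), plot = FALSE,
                    demean = TRUE)$acf[-1L]
  s <- 0
  k <- 1L
  first <- TRUE
  while (k <= length(rho)) {
    pair <- rho[k] + if (k + 1L <= length(rho)) rho[k + 1L] else 0
    if (!first && pair <= 0) break
    s <- s + pair
    first <- FALSE
    if (pair <= 0) break
    k <- k + 2L
  }
  denom <- max(1 + 2 * s, 1e-8)
  out <- n / denom
  if (out > n) structure(out, superefficient = TRUE) else out
}

#' Summarize dating chains: MCC tree, mean ages and HPDs
#'
#' Discards the first `burnin_fraction` of every chain, pools the rest, and
#' annotates the (fixed) topology with posterior mean node ages and 95% HPD
#' intervals. With a fixed topology the maximum-clade-credibility tree is
#' the input topology; clade posterior frequencies are all 1.
#'
#' @param run A `dating_chains` object from [mcmc_date()].
#' @param burnin_fraction Fraction of each chain to discard.
#' @return Object of class `dating_summary`: `tree` (node ages as branch
#'   lengths, mean-age node labels), `nodes` (data frame: node, mean,
#'   hpd_low, hpd_high, ess), `params` (same for scalar parameters).
#' @export
summarize_dating <- function(run, burnin_fraction = 0.10) {
  pooled <- do.call(rbind, lapply(run$chains, function(d) {
    drop <- floor(nrow(d) * burnin_fraction)
    if (drop >= nrow(d)) stop("burn-in discards every sample")
    d[(drop + 1L):nrow(d), , drop = FALSE]
  }))
  st <- run$state
  age_cols <- paste0("age_", st$internal)
  node_rows <- lapply(seq_along(st$internal), function(i) {
    x <- pooled[[age_cols[i]]]
    h <- hpd_interval(x, 0.95)
    data.frame(node = st$internal[i], mean_age = mean(x),
               hpd_low = h[1L], hpd_high = h[2L], ess = as.numeric(ess(x)))
  })
  nodes <- do.call(rbind, node_rows)
  scalars <- c("clock_mean", "clock_sd", "birth", "death")
  params <- do.call(rbind, lapply(scalars, function(p) {
    x <- pooled[[p]]
    h <- hpd_interval(x, 0.95)
    data.frame(parameter = p, mean = mean(x), hpd_low = h[1L],
               hpd_high = h[2L], ess = as.numeric(ess(x)))
  }))
  tree <- run$topology
  ages <- numeric(st$n_tip + tree$Nnode)
  ages[st$internal] <- nodes$mean_age
  # enforce parent > child when rounding the means
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1L]; chi <- post$edge[e, 2L]
    ages[par] <- max(ages[par], ages[chi] + 1e-8)
  }
  tree$edge.length <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  tree$node.label <- sprintf("%.2f", ages[st$internal])
  structure(list(tree = tree, nodes = nodes, params = params,
                 n_samples = nrow(pooled)),
            class = "dating_summary")
}

#' @export
print.dating_summary <- function(x, ...) {
  cat("Dated-tree posterior summary (", x$n_samples, " pooled samples)\n",
      sep = "")
  cat("Node ages (Ma):\n")
  print(x$nodes, row.names = FALSE, digits = 4)
  cat("Scalar parameters:\n")
  print(x$params, row.names = FALSE, digits = 4)
  invisible(x)
}
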