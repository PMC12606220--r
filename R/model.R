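# Empirical amino-acid substitution models with invariant sites (+I) and a
# free-rate mixture (+R), in the parameterization used for collagen data:
# mtMAM or mtREV exchangeabilities, observed (+F) or model frequencies.

# Published empirical exchangeability tables, fetched from phangorn's
# namespace (lower triangle, column-major, PAML state order).
aa_exchangeabilities <- function(name = c("mtMAM", "mtREV")) {
  name <- match.arg(name)
  key <- switch(name, mtMAM = ".mtmam", mtREV = ".mtREV24")
  tab <- utils::getFromNamespace(key, "phangorn")
  S <- matrix(0, 20L, 20L, dimnames = list(AA_STATES, AA_STATES))
  S[lower.tri(S)] <- tab$Q
  S <- S + t(S)
  freq <- as.numeric(tab$bf)
  names(freq) <- AA_STATES
  list(S = S, freq = freq / sum(freq))
}

#' Amino-acid substitution model
#'
#' Reversible 20-state model `Q = S diag(pi)` built from an empirical
#' exchangeability table, with an optional proportion of invariant sites
#' (+I) and a free-rate mixture (+R) of `length(rate_weights)` categories.
#' Rates are rescaled so that the expected substitution rate over all
#' classes (invariant class included) is 1, i.e.
#' `(1 - p_inv) * sum(w * r) = 1`.
#'
#' @param exchangeabilities `"mtMAM"` or `"mtREV"`.
#' @param frequencies `NULL` for the table's own frequencies, `"observed"`
#'   plus `aln` for +F empirical frequencies, or a 20-vector.
#' @param aln Alignment used when `frequencies = "observed"`.
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @param rate_weights Mixture weights (will be normalized to sum 1).
#' @param rates Relative rates, one per weight; rescaled to satisfy the mean
#'   rate constraint.
#' @return Object of class `phylo_model`: `S`, `pi`, `p_inv`, `weights`,
#'   `rates`, `name`, plus the eigen-system of the scaled `Q`.
#' @export
phylo_model <- function(exchangeabilities = c("mtMAM", "mtREV"),
                        frequencies = NULL, aln = NULL,
                        p_inv = 0, rate_weights = 1, rates = 1) {
  exchangeabilities <- match.arg(exchangeabilities)
  ex <- aa_exchangeabilities(exchangeabilities)
  freq_mode <- "model"
  if (is.null(frequencies)) {
    pi <- ex$freq
  } else if (identical(frequencies, "observed")) {
    if (is.null(aln)) stop("frequencies = 'observed' needs 'aln'")
    pi <- observed_frequencies(aln)
    freq_mode <- "observed"
  } else {
    if (length(frequencies) != 20L) stop("'frequencies' must have length 20")
    pi <- as.numeric(frequencies) / sum(frequencies)
    names(pi) <- AA_STATES
    freq_mode <- "given"
  }
  if (p_inv < 0 || p_inv >= 1) stop("'p_inv' must be in [0, 1)")
  if (length(rates) != length(rate_weights))
    stop("'rates' and 'rate_weights' must have equal length")
  if (any(rates <= 0) || any(rate_weights <= 0))
    stop("rates and weights must be positive")
  w <- rate_weights / sum(rate_weights)
  m <- structure(list(S = ex$S, pi = pi, p_inv = p_inv,
                      weights = w, rates = rates,
                      name = exchangeabilities, freq_mode = freq_mode),
                 class = "phylo_model")
  normalize_model(m)
}

# Rescale rates for the mean-rate constraint and (re)build the eigen system.
normalize_model <- function(m) {
  mean_r <- sum(m$weights * m$rates)
  target <- 1 / (1 - m$p_inv)
  m$rates <- m$rates * target / mean_r
  m$eig <- q_eigen(m$S, m$pi)
  m
}

# Eigen system of Q = S diag(pi), rows summing to zero, scaled to one
# expected substitution per unit time, via the symmetric similarity
# transform B = D^(1/2) Q D^(-1/2), D = diag(pi).
q_eigen <- function(S, pi) {
  pi <- pi / sum(pi)
  Q <- S * rep(pi, each = nrow(S))       # Q_ij = S_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))             # B_ij = sqrt(pi_i) Q_ij / sqrt(pi_j)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- e$vectors / sq                    # rows scaled: U = D^(-1/2) V
  Uinv <- t(e$vectors * sq)              # V' D^(1/2)
  list(values = e$values, U = U, Uinv = Uinv, Q = Q)
}

#' Observed amino-acid frequencies of an alignment (+F)
#'
#' Counts over non-X cells, with a small pseudo-count so absent residues keep
#' positive frequency.
#'
#' @param aln An [aa_alignment()] or character matrix.
#' @return Named 20-vector summing to 1.
#' @export
observed_frequencies <- function(aln) {
  m <- unclass(aln)
  counts <- table(factor(m[m != "X"], levels = AA_STATES))
  freq <- (as.numeric(counts) + 0.5) / sum(counts + 0.5)
  names(freq) <- AA_STATES
  freq / sum(freq)
}

#' @export
print.phylo_model <- function(x, ...) {
  tag <- x$name
  if (x$freq_mode != "model") tag <- paste0(tag, "+F")
  if (x$p_inv > 0) tag <- paste0(tag, "+I")
  if (length(x$rates) > 1L) tag <- paste0(tag, "+R", length(x$rates))
  cat("Amino-acid substitution model:", tag, "\n")
  if (x$p_inv > 0) cat("  p_inv:", signif(x$p_inv, 4), "\n")
  if (length(x$rates) > 1L) {
    cat("  rate categories (weight, rate):\n")
    for (k in seq_along(x$rates))
      cat(sprintf("    %d: (%.4f, %.4f)\n", k, x$weights[k], x$rates[k]))
  }
  invisible(x)
}

# Number of free parameters a model variant estimates (for AIC/BIC).
model_df <- function(m, n_branches) {
  df <- n_branches
  if (m$freq_mode == "observed") df <- df + 19L
  if (m$p_inv > 0) df <- df + 1L
  K <- length(m$rates)
  if (K > 1L) df <- df + 2L * (K - 1L)   # free weights and rates
  df
}
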