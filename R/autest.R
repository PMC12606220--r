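# Approximately unbiased (AU) topology test by multiscale RELL bootstrap,
# and the topology-comparison driver that feeds it.

#' Approximately unbiased topology test
#'
#' Multiscale RELL bootstrap of per-site log-likelihood vectors. For each
#' scale `r`, `ceiling(r * n)` sites are resampled with replacement `B`
#' times (shared resamples across topologies) and `BP(r)` is the fraction of
#' replicates in which a topology attains the highest resampled
#' log-likelihood, ties broken at random. The signed distance `d` and
#' curvature `c` are then estimated by weighted least squares from
#' `qnorm(1 - BP(r)) = d * sqrt(r) + c / sqrt(r)` and the AU p-value is
#' `1 - pnorm(d - c)`. With a single scale the plain RELL bootstrap
#' proportion is returned instead.
#'
#' @param site_ll Matrix (topologies x sites) or list of equal-length
#'   per-site log-likelihood vectors.
#' @param scales Bootstrap scale factors.
#' @param B Replicates per scale.
#' @param seed Integer seed.
#' @return Object of class `au_test`: data frame with `logL`, `deltaL`,
#'   `p_au`, `bp_raw` (BP at the scale closest to 1), and a `degenerate`
#'   flag for topologies whose BP was 0 or 1 at every scale.
#' @export
au_test <- function(site_ll, scales = seq(0.5, 1.4, by = 0.1), B = 10000L,
                    seed = 1L) {
  if (is.list(site_ll)) {
    if (length(unique(lengths(site_ll))) != 1L)
      stop("site log-likelihood vectors must have equal length")
    site_ll <- do.call(rbind, site_ll)
  }
  Tn <- nrow(site_ll); n <- ncol(site_ll)
  if (is.null(Tn) || Tn < 2L) stop("need at least 2 topologies")
  set.seed(seed)
  BP <- matrix(0, Tn, length(scales))
  chunk <- max(1L, min(B, floor(2e7 / n)))
  for (si in seq_along(scales)) {
    nr <- ceiling(scales[si] * n)
    wins <- numeric(Tn)
    done <- 0L
    while (done < B) {
      nb <- min(chunk, B - done)
      counts <- stats::rmultinom(nb, nr, prob = rep(1 / n, n))
      sums <- site_ll %*% counts                    # Tn x nb
      for (b in seq_len(nb)) {
        mx <- which(sums[, b] == max(sums[, b]))
        w <- if (length(mx) == 1L) mx else sample(mx, 1L)
        wins[w] <- wins[w] + 1
      }
      done <- done + nb
    }
    BP[, si] <- wins / B
  }
  full <- rowSums(site_ll)
  deltaL <- max(full) - full
  degenerate <- apply(BP, 1L, function(x) all(x %in% c(0, 1)))
  raw_scale <- which.min(abs(scales - 1))
  if (length(scales) == 1L) {
    p <- BP[, 1L]
  } else {
    p <- numeric(Tn)
    for (t in seq_len(Tn)) {
      if (degenerate[t]) {
        p[t] <- if (all(BP[t, ] == 1)) 1 else 0
        next
      }
      bp <- pmin(pmax(BP[t, ], 1 / (2 * B)), 1 - 1 / (2 * B))
      z <- stats::qnorm(1 - bp)
      X <- cbind(sqrt(scales), 1 / sqrt(scales))
      w <- B * stats::dnorm(z)^2 / (bp * (1 - bp))
      fit <- stats::lm.wfit(X * sqrt(w), z * sqrt(w))
      d <- fit$coefficients[1L]; cc <- fit$coefficients[2L]
      p[t] <- 1 - stats::pnorm(d - cc)
    }
  }
  out <- data.frame(topology = seq_len(Tn), logL = full, deltaL = deltaL,
                    p_au = p, bp_raw = BP[, raw_scale],
                    degenerate = degenerate)
  structure(list(table = out, BP = BP, scales = scales, B = B),
            class = "au_test")
}

#' @export
print.au_test <- function(x, ...) {
  cat("Approximately unbiased topology test (",
      length(x$scales), " scales, B = ", x$B, ")\n", sep = "")
  print(x$table, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Compare candidate topologies by optimized likelihood and the AU test
#'
#' Optimizes branch lengths (and, optionally, model parameters) on each
#' candidate topology, reports the log-likelihood difference to the best
#' tree, and runs the AU test over the per-site log-likelihood vectors.
#'
#' @param aln An [aa_alignment()].
#' @param trees `multiPhylo` or list of `phylo` candidate topologies.
#' @param model A [phylo_model()].
#' @param optimize_model Free the model parameters per topology as well.
#' @param scales,B,seed Passed to [au_test()].
#' @return An `au_test` object whose table also carries tree names; the
#'   fitted trees are attached as attribute `"fits"`.
#' @export
topology_test <- function(aln, trees, model, optimize_model = TRUE,
                          scales = seq(0.5, 1.4, by = 0.1), B = 10000L,
                          seed = 1L) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  fits <- lapply(trees, function(tr) {
    if (is.null(tr$edge.length)) tr$edge.length <- rep(0.05, nrow(tr$edge))
    fit_ml(aln, tr, model, optim_pinv = optimize_model,
           optim_rates = optimize_model)
  })
  site_ll <- do.call(rbind, lapply(fits, function(f)
    site_log_likelihoods(f$tree, aln, f$model)))
  res <- au_test(site_ll, scales = scales, B = B, seed = seed)
  nm <- names(trees)
  if (!is.null(nm)) res$table$topology <- nm
  attr(res, "fits") <- fits
  res
}
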