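---
title: "Models and methods in zoomsphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in zoomsphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoomsphylo)
```

zoomsphylo implements a complete ZooMS-style workflow: in-silico collagen
digestion and peptide-mass fingerprinting, marker-panel taxon screening,
peptide-to-alignment assembly, maximum-likelihood (ML) phylogenetics on
amino-acid alignments, and Bayesian node dating. This vignette documents the
models, their parameters and defaults, the numerical choices, and the
modelling decisions the package takes where the underlying science leaves
room.

## 1. Peptide masses and modifications

Peptide monoisotopic masses are sums of residue monoisotopic masses
(`AA_MONO`, in Da, the standard 20 residues) plus one water
(18.010565 Da). Two collagen-relevant modifications are supported, each as a
count per peptide:

* hydroxylation (typically proline → hydroxyproline): **+15.994915 Da** per
  site;
* deamidation (N → D, Q → E): **+0.984016 Da** per site.

`peptide_mz(mass, z)` uses the proton mass 1.007276 Da:
$m/z = (M + z \cdot 1.007276)/z$. Example: the COL1A2 marker
`GLTGPIGPPGPAGPSGDKGESGPSGPAGPTGAR` with one hydroxylation has
$[M+H]^+ = 2869.41$.

```{r marker}
m <- peptide_mass("GLTGPIGPPGPAGPSGDKGESGPSGPAGPTGAR", n_hydroxylations = 1)
round(peptide_mz(m, 1), 2)
```

## 2. Tryptic digestion and theoretical fingerprints

`digest()` cleaves C-terminal to K or R, suppressed before P (the Keil
rule), and enumerates up to `missed_cleavages` missed sites (default 1).
Peptide coordinates are chain-local and 1-based. `theoretical_fingerprint()`
expands each peptide over hydroxylation counts 0..`max_oh` (bounded by the
number of P residues) and deamidation counts 0..`max_deam` (bounded by
N+Q), filters to an m/z window (default 800–3500, the usual MALDI-ToF
range), skips peptides containing unknown residues (`X`), and de-duplicates
identical masses.

## 3. Screening: matching, panels, preservation, deamidation

`match_peaks()` matches an observed peak list to theoretical masses
greedily by increasing |Δm/z| with one-to-one assignment, within a tolerance
(default 0.5 Da, typical for linear-mode MALDI). `classify_taxon()` counts
matched taxon-specific panel markers and assigns the taxon with the most
matches provided it exceeds `min_markers` (default 2) and strictly beats
all others; ties inside a declared ambiguity group yield a joined label
(e.g. `wall_a/wall_b`), anything else is `indeterminate`.

`preservation_class()` grades spectra as `good`/`fair`/`poor` from the
fraction of signal above a high-mass threshold (default 2500 Da), since
collagen degradation removes long peptides first. `deamidation_index()`
computes the intensity ratio of the 1105.58 peak to its +0.98 deamidated
partner at 1106.56: with intensities 58 and 100 it is exactly
`58/100 = 0.58` (this quotient is exact in binary floating point).

## 4. Assembly of peptide alignments

`assemble_sequences()` places recovered peptides onto a reference collagen
coordinate system; unobserved positions are `X`, and conflicting residue
calls at a position are recorded and masked to `X` unless one call has a
strict majority. `aa_alignment` objects are plain character matrices (rows
= taxa) with FASTA and NEXUS I/O (`read_alignment`, `write_alignment`)
that round-trip `X`.

## 5. Likelihood model: mtMAM/mtREV +F +I +R2

The substitution model is a general time-reversible amino-acid model
$Q = S\,\mathrm{diag}(\pi)$ with the empirical mtMAM or mtREV24
exchangeabilities (taken at runtime from phangorn's published PAML tables),
scaled so the expected rate is 1. Frequencies $\pi$ are the model's
empirical defaults, `"observed"` (counted from the alignment, +F), or user
supplied.

Rate heterogeneity is a mixture: a proportion `p_inv` of invariant sites
plus free-rate categories (`rates`, `weights`) normalised so
$(1-p_{inv})\sum_k w_k r_k = 1$; the default acceptance-grade configuration
is +I+R2. Because $Q$ is reversible it is diagonalised through the
symmetrized matrix $\mathrm{diag}(\pi)^{1/2} Q\, \mathrm{diag}(\pi)^{-1/2}$
(a real symmetric eigenproblem, numerically stable), giving
$P(t) = U e^{\Lambda t} U^{-1}$ in one decomposition for all branches.

Felsenstein pruning is implemented in C++ (RcppArmadillo) over compressed
site patterns with per-pattern rescaling to avoid underflow; `X` (missing)
tips contribute a partial likelihood of 1 in every state. Branch lengths
are floored at $10^{-8}$.

`fit_ml()` maximises the likelihood by coordinate ascent: Brent
optimisation of each branch length in turn, then optionally `p_inv` and the
free-rate parameters, iterated to convergence. `nni_search()` wraps this in
a nearest-neighbour-interchange hill climb; `constraint =
monophyly_constraint(taxa)` restricts the search to trees in which `taxa`
are monophyletic (checked unrooted, i.e. the clade or its complement).
`model_select()` compares fitted variants by AIC/BIC. `bootstrap_support()`
is the standard nonparametric bootstrap over sites.

## 6. AU test

`au_test()` takes the matrix of per-site log-likelihoods of the candidate
topologies and performs multiscale RELL resampling (Shimodaira's
approximately unbiased test): for each scale $r$ the sites are resampled
to length $rn$, bootstrap proportions $BP_r$ are recorded, and
$z_r = \Phi^{-1}(1 - BP_r)$ is regressed on $(\sqrt r, 1/\sqrt r)$ by
weighted least squares to estimate signed distance $d$ and curvature $c$;
$p_{AU} = 1 - \Phi(d - c)$. With a single scale $r = 1$ the fit is
degenerate and the implementation returns the plain RELL bootstrap
proportion, the correct single-scale limit.

## 7. Bayesian node dating

`mcmc_date()` holds the (rooted, ultrametric-to-be) topology fixed and
samples node ages, a lognormal relaxed clock, and tree-prior parameters by
Metropolis–Hastings. Topology co-estimation is deliberately out of scope:
the workflow dates the ML (or known) tree, which is standard node dating.

* **Clock:** each branch has an independent lognormal rate with mean
  `clock_mean` and log-sd `clock_sd`; branch expected substitutions =
  duration × rate.
* **Tree prior:** birth–death kernel on node ages conditioned on the root
  age, with priors on birth and death rates.
* **Calibrations:** uniform densities on clade ages, `crown` (MRCA of the
  taxa) or `stem` (parent of the MRCA). Calibrated nodes take the
  calibration density *in place of* the birth–death kernel
  (Yang–Rannala-style node dating). The root must carry a calibration. The
  default interpretation when unspecified is `stem`, matching how fossil
  first-appearances bound a lineage rather than its crown radiation.
* **Moves:** node-age slides respecting parent/child ordering, scale moves
  on rates and scalars, and a joint rescale move (all internal ages × f,
  clock mean ÷ f, with Jacobian $(n_{int}-1)\log f$). The joint move is
  likelihood-invariant and travels the rate–time ridge on which ages and
  the clock mean are nearly confounded; without it, chains of practical
  length under-cover true node ages.

`summarize_dating()` discards 10% burn-in, pools chains, and reports
posterior means, shortest 95% HPD intervals, and effective sample sizes
(initial-positive-sequence estimator); the maximum-clade-credibility
summary is the fixed input topology with posterior-mean node ages.

**Prior validation.** A correct sampler run without data (`prior_only =
TRUE`) must reproduce its prior. For calibrated nodes with uniform
calibrations the marginal is exactly uniform *only when calibrations are
not nested with overlapping bounds*: if an ancestor and descendant share
bounds, the order constraint truncates the joint density and the marginals
are provably non-uniform. The package's prior-validation checks therefore
use a design in which every internal node is calibrated and the root bound
lies strictly above the others (root uniform(60, 80), two cherries uniform
(23.03, 54.6)); in that configuration exact uniformity is mathematically
true and testable with a Kolmogorov–Smirnov test.

## 8. Forward simulator

`simulate_dataset(sim_config(...))` generates an end-to-end synthetic
bundle: a birth–death ultrametric tree, a collagen-like root chain pair,
alignment evolution under the chosen model (+I + free rates) with a relaxed
clock, per-taxon peptide coverage masking, tryptic spectra with noise peaks
and age-dependent deamidation (older samples show lower 1105.58:1106.56
ratios), a marker panel derived from the simulated fingerprints (unique
masses at 0.5 Da, up to 8 per taxon), and a truth manifest. One deliberately
degraded sample exercises the `poor`/`indeterminate` paths.

Scope and limits: the simulator is desk-scale (tens of taxa, hundreds of
sites) and is meant for validation, not for emulating instrument physics;
peak intensities, noise and coverage are simple parametric choices. Marker
uniqueness depends on how divergent the simulated sequences are, so
screening accuracy on simulated bundles is seed-dependent by nature.

## 9. Numerical and validation choices

* Matrix exponentials in the package go through the eigendecomposition;
  the independent test oracle instead uses `Matrix::expm` and exhaustive
  enumeration of internal-node states, because `ape::matexpo` is only
  accurate to ~1e-3 and cannot support the 1e-10 agreement tolerance the
  test suite imposes.
* Site log-likelihood agreement is measured relative to
  $\max(|\log L|, 1)$: all-missing columns have $\log L = 0$ up to float
  noise on both routes.
* Problem sizes in the test suite (chain lengths, 20 dating replicates,
  100 oracle instances, B = 10000 RELL draws) are the package's own
  desk-scale choices, sized to finish on one CPU within minutes while
  keeping Monte Carlo error well below the tested tolerances.
* All stochastic steps take explicit integer seeds (< 2^31) and are
  reproducible run-to-run.
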