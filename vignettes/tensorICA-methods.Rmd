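---
title: "Tensorial blind source separation for multi-omic tensors: methods and design"
author: "tensorICA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tensorICA methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensorICA)
```

# The model

Multi-omic studies that measure the same features (genes, CpGs) in the same
samples across several data or tissue types produce an order-3 tensor
`X` of dimension `p1 x p2 x p` (type x sample x feature).  We treat the
`p` features as independent, identically distributed realisations of the
`p1 x p2` random matrix `X[, , i]`, so all decompositions act on the two
small modes and the feature axis supplies the statistics.

**Tensorial PCA.**  For each mode `m` in {1, 2}, the mode covariance matrix
is the `p_m x p_m` sum of outer products of the mode-`m` fibers over all
other indices.  Eigendecomposing both mode covariances gives orthogonal
bases `Omega_1`, `Omega_2`, and the tPCA source tensor is the input
contracted with their transposes.  At full dimensions the decomposition is
exactly invertible; retaining only the leading `d_m` eigenvectors yields a
reduced `d1 x d2 x p` source tensor.  We normalise each mode covariance by
the number of summed terms so that its eigenvalues are on a variance
scale; this rescales eigenvalues only and leaves every eigenvector — hence
every rotation and source estimate — unchanged.

**Dimension estimation.**  The number of significant sample-space
components is estimated per data type by counting eigenvalues of the
sample correlation matrix above the Marchenko–Pastur upper edge
`(1 + sqrt(n_var/n_obs))^2`, the largest eigenvalue expected from pure
noise.  The `"rmt"` dims policy keeps the (small) type mode full and sets
the sample-mode dimension to the maximum of the per-type estimates; modes
of dimension at most 3 are never reduced, since reduction buys nothing
there.  The raw MP edge is slightly liberal at finite size: on pure iid
1000 x 100 noise it reports 0 components in roughly 9 out of 10 seeds and
1 in the rest.  We accept this small upward bias rather than introduce a
tuning constant; planted signals of realistic amplitude are recovered
exactly (see the unit tests).

**Whitening.**  Whitening composes the reduced projection with
`Lambda_m^(-1/2)`, so retained components have unit variance.  The two
modes are whitened sequentially (mode 1, then mode 2).  After
transforming a single mode, that mode's covariance of the output is the
identity *exactly*; with both modes transformed, each is the identity up
to the coupling between modes, which is small whenever the population
covariance is approximately Kronecker-separable.  Eigenvalues below
`1e-12` times the leading eigenvalue are treated as zero and whitening
refuses to proceed (degenerate-whitening error naming the mode), rather
than amplifying numerical noise by huge factors.

**Tensorial ICA.**  The tICA model assumes the source slices
`S[k1, k2, ]` are mutually statistically independent with mean 0 and
variance 1; non-Gaussianity makes the rotation identifiable.  After
whitening, one orthogonal rotation per mode is estimated:

* **tWFOBI** eigendecomposes the fourth-moment matrix
  `B_m = mean_i [M_i M_i^T M_i M_i^T]` over the mode-`m` matricisations
  `M_i` of each realisation.  When the other mode has dimension 1 this is
  classical FOBI.
* **tWJADE** builds all `d(d+1)/2` symmetrised fourth-order cumulant
  matrices over the pooled mode-`m` fibers (`p * d_other` fibers) and
  jointly diagonalises them with Jacobi sweeps (closed-form Givens angle
  per pair, convergence when every angle in a sweep is below `1e-8`,
  at most 100 sweeps; the off-diagonal criterion is non-increasing).
  No eigen-matrix truncation is applied: the retained dimensions are
  always small (tens at most) in the intended applications, so using all
  cumulant matrices is cheap and avoids an extra approximation.

The per-mode unmixing matrix is `W_m = U_m^T Lambda_m^(-1/2) Omega_m^T`
and its pseudo-inverse `A_m = Omega_m Lambda_m^(1/2) U_m` is the mixing
matrix.  The pipeline contains no randomness: for a fixed input the
output is bit-reproducible.

# Identifiability: where FOBI stops working

FOBI separates sources only when their kurtosis "row sums" are distinct:
in the tensor case, mode-`m` source rows with equal summed excess
kurtosis span an eigenspace of `B_m` with a tied eigenvalue, inside which
the rotation is undetermined.  Independent unit-variance sources drawn
from a *single* distribution (e.g. all Laplace) tie every row sum, so
tFOBI cannot converge to the true sources no matter how many features are
observed — a property of the statistic, not of the implementation.  JADE
does not suffer this degeneracy.  Our unit tests therefore validate FOBI
recovery on sources with distinct kurtoses (uniform / triangular /
logistic / Laplace mixtures) and JADE additionally on iid Laplace
sources; a warning is emitted when tied fourth-moment eigenvalues are
detected.  On the benchmark simulation this distinction is immaterial:
the planted signal blocks differ sharply in kurtosis from the noise
components, and tWFOBI and tWJADE perform near-identically there.

# Sign and ordering conventions

Eigenvector and rotation columns are sign-fixed by making each column's
largest-magnitude entry positive.  Source slices are only sign-flippable
per mode (a slice's sign is the product of its mode-1 and mode-2
component signs), so an arbitrary per-slice convention is impossible for
`p1 > 1`; we flip each mode-2 component so that the slice with the
largest absolute skewness across mode-1 levels has non-negative skewness,
falling back (all |skewness| < 1e-8) to making the largest-|weight| entry
of the first slice positive.  Mode-2 components are ranked by decreasing
maximum excess kurtosis over mode-1 levels (ties by index); mode-1 stays
in data-type order after back-projection, since its levels correspond to
named data types rather than anonymous components.

# The simulator

`simulateMultiOmic()` emulates a two-omic experiment as two 1000 x 100
feature x sample matrices.  One source of joint variation is driven by a
common set of 20 samples and 50 genes per data type (distinct between
types, 100 joint genes in total); each type additionally carries one
individual source driven by 50 genes and 10 samples unique to that
matrix.  Joint blocks are drawn from distribution(+e, sigma) in type 1
and distribution(-e, sigma) in type 2, individual blocks from
distribution(+e, sigma), background from distribution(0, sigma), with
e = 3 and sigma the noise level, so SNR = e/sigma (1 at sigma = 3).
Signal blocks *replace* the background draw rather than adding to it, so
block means are exactly +-e.  The Laplace variant matches the Gaussian
mean and standard deviation (scale `sigma/sqrt(2)`).  Index sets are
drawn uniformly without replacement and kept disjoint (joint gene sets
between types; individual gene/sample sets from the joint sets and from
each other), which keeps the truth labels unambiguous; a flag allows
overlap for robustness experiments.  One Mersenne–Twister stream seeded
from `seed` is used with a documented draw order, so a fixed seed yields
bit-identical datasets.

What the simulator does *not* emulate: beta-value boundedness and
heteroscedasticity of methylation arrays, feature–feature correlation
(probes within a locus), batch structure, and missing values.  Passing
benchmarks here demonstrates correct inference under the generative
model, not performance on raw EWAS data.

# Evaluation protocol and benchmark

For tensorial methods we fit 2 x 6 = 12 components (type mode x sample
mode), back-project onto the original data types with the 2 x 2 mixing
matrix, select the top-50 genes per (type, component) by absolute
weight, and compute per-type sensitivity (SE) and specificity (SP)
against that type's 50 true joint-variation genes, averaging SE and SP
over the two types.  The reported values are those of the component with
the largest SE ("largest SE and SP value" is ambiguous when the argmax
components differ; we select by SE, break ties by SP then index, and the
per-component table is returned so both views are available).  Results
are insensitive to the number of fitted components as long as it exceeds
the number of planted sources.

`runBenchmark()` repeats this over a sigma grid; run `r` simulates with
seed `seed + r`, so every method sees identical data, and the same
underlying deviates are reused across sigma levels (common random
numbers), which sharpens monotonicity comparisons without biasing any
method.  Method comparison uses one-tailed *paired* Wilcoxon signed-rank
tests on the per-run values (exact for up to 25 pairs without ties,
normal approximation with tie correction otherwise).  The default suite
runs 50 Monte Carlo runs per noise level over sigma in {1, ..., 5} —
enough for stable means at desk scale; the generative model itself is
unchanged by this choice.

# Downstream inference

* **Feature selection** takes the `k` largest absolute weights
  (deterministic tie-break by index).  `k` is matched to the truth-set
  size for sensitivity screening, and 500 for enrichment scans of real
  components.
* **Enrichment**: Fisher's exact test (one-tailed hypergeometric, odds
  ratio ad/bc with +Inf when bc = 0) for category enrichment; the exact
  binomial upper tail for truth-set screening and chromosome enrichment.
  The binomial background fraction defaults to the category's share of
  the analysis universe (the array background is also supported, flagged
  in output).
* **SE(max)/SE(all)**: every (data-type, component) weight vector counts
  as one tested IC, so the Bonferroni divisor is `p1 * d2`; components
  are enriched when the binomial p-value is below `0.05 / (p1 * d2)`.
  SE(all) uses the union of selections over enriched components and is 0
  by convention when nothing is enriched (SE(max) is always reported).
* **Specificity calls**: a feature is *cell-type independent* when its
  absolute weight reaches the 90th percentile (inclusive, linear
  interpolation) in every mode-1 level, *cell-type specific* when it is
  strictly below the median in exactly one or two levels while reaching
  the top decile in at least one, and *unclassified* otherwise — gaps in
  the rule are reported as a bucket, never dropped.  Calls are invariant
  to positive rescaling of any level's weights.
* **Iterative kurtosis selection** strips a component's heavy tail:
  remove the largest-|weight| feature while the remaining excess kurtosis
  is at least 1, up to 500 removals (boundary semantics: the check runs
  before each removal, so an initially sub-threshold component selects
  nothing and the cap is exact).
* **Phenotype association**: OLS slope t-test for continuous/ordinal
  phenotypes, two-sided Wilcoxon rank sum for two groups (exact when the
  smaller group has at most 20 samples), with a caller-supplied
  Bonferroni divisor applied to the significance flag.

# Numerical choices and degenerate inputs

Missing or non-finite values are hard errors at tensor construction and
file parsing — the moment statistics underlying FOBI/JADE have no
principled treatment of missingness, so imputation is deliberately left
to upstream tools.  Zero-variance columns are excluded (with a warning)
from the MP estimate; an all-constant matrix is an error.  Tied FOBI
eigenvalues and cumulant-starved JADE fits (`N < d^2` fibers) warn.
Exact p-value routines are used throughout (`phyper`, `pbinom`, exact
signed-rank); the test suite checks them against independent log-space
enumeration oracles over exhaustive sweeps of small tables.

# Problem sizes used in the shipped checks

The packaged tests and the acceptance script run entirely on synthetic
data at desk scale, chosen as the smallest sizes at which the asymptotic
claims are visibly established: source-recovery checks at `p = 10000`
features with 2 x 4 sources (20 seeds), benchmark grids of 50 runs x 5
noise levels at the simulator's native 2 x 100 x 1000, and Monte Carlo
invariants at `p` in {1000, 5000, 20000}.

# Known limitations

Order-3 tensors only; decomposition always acts on modes 1 and 2.  The
two-mode whitening is sequential, so joint whiteness is approximate when
the population covariance is far from Kronecker-separable.  tFOBI is not
identifiable for sources with tied kurtosis row sums (see above).  The
MP-edge estimator ignores Tracy–Widom finite-size fluctuations.  The
benchmark harness ships adapters for the in-package methods only;
external decompositions (JIVE, PARAFAC, iCluster, CCA) plug in as named
functions mapping an `OmicsTensor` to a fitted model.
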