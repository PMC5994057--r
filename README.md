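# tensorICA

Tensorial blind source separation for multi-omic data tensors.

Multi-omic experiments that profile the **same features in the same
samples across several data or tissue types** — methylation plus
expression, or one assay across multiple purified cell types — naturally
form an order-3 tensor `X` of dimension `p1 × p2 × p` (data type ×
sample × feature).  This package infers statistically independent
sources of variation from such tensors, for analysts who want sparse,
interpretable components (mQTL signatures, exposure signatures, cancer
gene modules) rather than the dense mixtures that plain PCA returns.

## The method

Treating the `p` features as i.i.d. realisations of the `p1 × p2` random
matrix, the model is

    X = S ⊙₁ Ω₁ ⊙₂ Ω₂ ,

where `⊙ₘ` is contraction along mode `m`, the `Ωₘ` are `pₘ × pₘ`
orthogonal mixing matrices, and the source slices `S[k₁, k₂, ·]` are
independent with mean 0 and variance 1.

* **Tensorial PCA** (`tpcaFit`): eigendecompose the two mode covariance
  matrices `X ⊙₋ₘ X = Ωₘ Λₘ Ωₘᵀ`; the number of significant sample-space
  components is estimated from the Marchenko–Pastur upper edge
  `(1 + √(n_var/n_obs))²` of the per-type correlation spectra
  (`rmtEstimateDim`).
* **Whitening** (`whitenTensor`): project on the retained eigenbasis and
  rescale by `Λₘ^(−1/2)` so retained components have unit variance.
* **Tensorial ICA** (`tWFOBI`, `tWJADE`): one orthogonal rotation per
  mode after whitening — FOBI eigendecomposes the fourth-moment matrix
  `E[M MᵀM Mᵀ]`, JADE jointly diagonalises all fourth-order cumulant
  matrices of the whitened fibers by Jacobi sweeps.  Components are
  ranked by excess kurtosis: biological sources are sparse and
  heavy-tailed, so large positive kurtosis marks the interesting ones.
* **Downstream inference** (`sensitivityMeasures`, `fisherEnrichment`,
  `binomialEnrichment`, `classifySpecificity`,
  `iterativeKurtosisSelection`, `associatePhenotype`): select driver
  features per component, test category/chromosome enrichment, call
  cell-type-independent vs cell-type-specific features by the
  10%/50% weight-quantile rule, and associate sample-mode mixing columns
  with phenotypes.
* **Simulation benchmark** (`simulateMultiOmic`, `runBenchmark`,
  `compareMethods`): a generative model of two 1000 × 100 omic matrices
  with one joint (20 shared samples; 50 genes per type, disjoint) and
  one individual (50 genes, 10 samples per type) source of variation at
  signal-to-noise `e/σ`, plus a Monte Carlo harness with paired Wilcoxon
  method comparison.

## Worked example

```r
library(tensorICA)

sim <- simulateMultiOmic(simConfig(sigma = 2, seed = 42))
sim
#> SimulatedDataset: 2 x 100 x 1000 tensor (SNR e/sigma = 1.5)
#>   joint variation: 50 + 50 genes (disjoint), 20 shared samples
#>   individual variation: 50 genes, 10 samples per type

fit <- tWJADE(simTensor(sim), dims = c(2, 6))
fit
#> TICAModel (tWJADE): source 2 x 6 x 1000
#>   max excess kurtosis per mode-2 component (ranked):
#>   IC1=6.70  IC2=3.24  IC3=3.10  IC4=0.06  IC5=0.06  IC6=-0.12

ev <- evaluateSESP(fit, sim, k = 50)
str(ev[c("SE", "SP", "component")])
#> List of 3
#>  $ SE       : num 0.98
#>  $ SP       : num 0.999
#>  $ component: int 1
```

Three components carry real structure (positive kurtosis: the joint
source and the two individual sources) while the rest are Gaussian
noise with kurtosis near 0.  The top-ranked component recovers 98% of
the 100 planted joint-variation genes (SE = 0.98) at SP = 0.999, at a
signal-to-noise ratio of 1.5.

A command-line wrapper covers the same pipeline for shell use:

```sh
inst/scripts/tica simulate  --out sim --seed 1
inst/scripts/tica decompose --out dec --method twjade \
    --matrices sim/type1.tsv,sim/type2.tsv
inst/scripts/tica enrich    --out enr --weights dec/weights_type1.tsv \
    --category my_category.txt --k 500
```

## Notes

tFOBI is not identifiable when sources share a common kurtosis (e.g. all
unit-variance Laplace): its fourth-moment eigenvalues tie and the
rotation is undetermined in the tied subspace.  tWJADE does not have
this limitation and is the recommended default; see the methods
vignette (`vignettes/tensorICA-methods.Rmd`) for details, conventions
and design decisions.
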