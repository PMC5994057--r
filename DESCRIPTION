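Package: tensorICA
Title: Tensorial Blind Source Separation for Multi-Omic Data Tensors
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tensorial independent component analysis for order-3 multi-omic
    data tensors (data type x sample x feature). Implements tensorial PCA via
    simultaneous eigendecomposition of the two mode covariance matrices, with
    Marchenko-Pastur based estimation of the number of significant components,
    and two tensorial ICA flavours, tWFOBI and tWJADE, which apply a
    fourth-order blind identification or joint approximate diagonalisation
    rotation after tensorial PCA whitening. Includes a generative simulator of
    two-omic tensors with joint and individual variation blocks, a
    sensitivity/specificity benchmark harness with paired Wilcoxon method
    comparison, and downstream inference on fitted components: kurtosis-based
    component ranking, top-weight and iterative kurtosis-thresholded feature
    selection, Fisher and binomial enrichment tests, cell-type-specificity
    calls and phenotype association.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: DimensionReduction, Epigenetics, PrincipalComponent,
    StatisticalMethod, DNAMethylation, GeneExpression
RoxygenNote: 7.3.3
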