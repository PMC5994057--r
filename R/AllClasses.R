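#' @import methods
NULL

#' OmicsTensor: an order-3 multi-omic data tensor
#'
#' Container for an order-3 numeric array indexed (data type, sample,
#' feature).  Mode 1 is the data/tissue-type axis, mode 2 the sample axis and
#' mode 3 the feature axis; features are treated as independent realisations
#' of the (type x sample) random matrix, so all decompositions act on modes 1
#' and 2 only.
#'
#' @slot values numeric array of dimension p1 x p2 x p (all finite).
#' @slot mode1Labels character vector of length p1 (data-type labels).
#' @slot mode2Labels character vector of length p2 (sample labels).
#' @slot featureIDs character vector of length p (feature identifiers).
#'
#' @examples
#' x <- OmicsTensor(array(rnorm(2 * 4 * 10), c(2, 4, 10)))
#' dim(x)
#' @export
setClass("OmicsTensor",
    representation(
        values = "array",
        mode1Labels = "character",
        mode2Labels = "character",
        featureIDs = "character"
    )
)

setValidity("OmicsTensor", function(object) {
    v <- object@values
    if (length(dim(v)) != 3L)
        return("'values' must be a 3-dimensional array")
    if (!is.numeric(v))
        return("'values' must be numeric")
    if (any(!is.finite(v)))
        return("'values' must be finite (no NA/NaN/Inf)")
    d <- dim(v)
    if (d[3L] < 2L)
        return("the feature (realisation) axis must have length >= 2")
    if (length(object@mode1Labels) != d[1L])
        return("length(mode1Labels) must equal dim(values)[1]")
    if (length(object@mode2Labels) != d[2L])
        return("length(mode2Labels) must equal dim(values)[2]")
    if (length(object@featureIDs) != d[3L])
        return("length(featureIDs) must equal dim(values)[3]")
    TRUE
})

#' Construct an OmicsTensor
#'
#' @param values numeric 3-d array (type x sample x feature).
#' @param mode1Labels,mode2Labels,featureIDs optional axis labels; defaults
#'   are generated (\code{type1..}, \code{sample1..}, \code{f1..}).
#' @return An \linkS4class{OmicsTensor}.
#' @export
OmicsTensor <- function(values, mode1Labels = NULL, mode2Labels = NULL,
                        featureIDs = NULL) {
    if (length(dim(values)) != 3L)
        stop("'values' must be a 3-dimensional array")
    d <- dim(values)
    if (is.null(mode1Labels)) mode1Labels <- paste0("type", seq_len(d[1L]))
    if (is.null(mode2Labels)) mode2Labels <- paste0("sample", seq_len(d[2L]))
    if (is.null(featureIDs)) featureIDs <- paste0("f", seq_len(d[3L]))
    new("OmicsTensor", values = values,
        mode1Labels = as.character(mode1Labels),
        mode2Labels = as.character(mode2Labels),
        featureIDs = as.character(featureIDs))
}

#' Tensorial PCA model
#'
#' Result of \code{\link{tpcaFit}}: per-mode orthogonal eigenbases of the two
#' mode covariance matrices, their eigenvalues, retained dimensions, the
#' per-(type, sample) centering offsets and the source tensor.
#'
#' @slot omega list of two orthogonal matrices (full p_m x p_m, columns
#'   eigenvalue-descending, sign-fixed).
#' @slot lambda list of two non-increasing nonnegative eigenvalue vectors.
#' @slot dims integer(2), retained dimensions d1, d2.
#' @slot offsets p1 x p2 matrix of subtracted per-(type, sample) means.
#' @slot source \linkS4class{OmicsTensor} of dimension d1 x d2 x p.
#' @slot normalized logical; whether mode covariances were divided by the
#'   number of summed terms.
#' @export
setClass("TPCAModel",
    representation(
        omega = "list",
        lambda = "list",
        dims = "integer",
        offsets = "matrix",
        source = "OmicsTensor",
        normalized = "logical"
    )
)

setValidity("TPCAModel", function(object) {
    if (length(object@omega) != 2L || length(object@lambda) != 2L)
        return("omega and lambda must have one entry per decomposed mode (2)")
    for (m in 1:2) {
        om <- object@omega[[m]]
        if (max(abs(crossprod(om) - diag(ncol(om)))) > 1e-8)
            return(sprintf("omega[[%d]] is not orthogonal", m))
        lam <- object@lambda[[m]]
        if (is.unsorted(rev(lam)))
            return(sprintf("lambda[[%d]] is not non-increasing", m))
        if (object@dims[m] > ncol(om) || object@dims[m] < 1L)
            return("retained dims out of range")
    }
    TRUE
})

#' Tensorial ICA model
#'
#' Result of \code{\link{tWFOBI}} / \code{\link{tWJADE}}: per-mode unmixing
#' and mixing matrices, the independent source tensor, the per-slice excess
#' kurtosis table and the kurtosis-based component ordering.
#'
#' @slot unmixing list of two d_m x p_m unmixing matrices W_m
#'   (rotation composed with whitening).
#' @slot mixing list of two p_m x d_m mixing matrices A_m (pseudo-inverse of
#'   W_m).
#' @slot source \linkS4class{OmicsTensor} of dimension d1 x d2 x p; slice
#'   (k1, k2) holds one inferred independent component over features.
#' @slot kurtosis d1 x d2 matrix of excess kurtoses of the source slices.
#' @slot order integer permutation of the mode-2 components by decreasing
#'   max-over-mode-1 excess kurtosis.
#' @slot offsets p1 x p2 centering matrix from the whitening step.
#' @slot method character, "tWFOBI" or "tWJADE".
#' @export
setClass("TICAModel",
    representation(
        unmixing = "list",
        mixing = "list",
        source = "OmicsTensor",
        kurtosis = "matrix",
        order = "integer",
        offsets = "matrix",
        method = "character"
    )
)

setValidity("TICAModel", function(object) {
    if (length(object@unmixing) != 2L || length(object@mixing) != 2L)
        return("unmixing and mixing must each have two entries")
    for (m in 1:2) {
        W <- object@unmixing[[m]]
        A <- object@mixing[[m]]
        if (nrow(W) != ncol(A) || ncol(W) != nrow(A))
            return("unmixing/mixing shapes are inconsistent")
        if (max(abs(W %*% A - diag(nrow(W)))) > 1e-6)
            return(sprintf("W_%d A_%d is not the identity", m, m))
    }
    d <- dim(object@source@values)
    if (!all(dim(object@kurtosis) == d[1:2]))
        return("kurtosis table must be d1 x d2")
    if (length(object@order) != d[2L])
        return("order must be a mode-2 component permutation")
    TRUE
})

#' Simulated two-omic dataset with known drivers
#'
#' Output of \code{\link{simulateMultiOmic}}: the data tensor plus the
#' ground-truth index sets of the genes/samples driving joint and individual
#' variation, the generating configuration and the signal-to-noise ratio.
#'
#' @slot tensor \linkS4class{OmicsTensor} (2 x n_samples x n_genes).
#' @slot jvGenes list of two disjoint integer vectors: per-type genes driving
#'   joint variation.
#' @slot jvSamples integer vector of samples driving joint variation (shared
#'   between the two types).
#' @slot ivGenes,ivSamples lists of two integer vectors: per-type drivers of
#'   individual variation.
#' @slot config the \code{SimulationConfig}-style parameter list used.
#' @slot snr numeric, e / sigma.
#' @export
setClass("SimulatedDataset",
    representation(
        tensor = "OmicsTensor",
        jvGenes = "list",
        jvSamples = "integer",
        ivGenes = "list",
        ivSamples = "list",
        config = "list",
        snr = "numeric"
    )
)

setValidity("SimulatedDataset", function(object) {
    if (length(object@jvGenes) != 2L)
        return("jvGenes must hold one gene set per data type")
    if (length(intersect(object@jvGenes[[1L]], object@jvGenes[[2L]])) > 0L)
        return("joint-variation gene sets must be disjoint between types")
    TRUE
})

#' Enrichment test result
#'
#' A 2x2 contingency summary of a selected-feature set against a category,
#' with odds ratio and one-tailed enrichment p-value.
#'
#' @slot counts 2x2 integer matrix: rows selected yes/no, columns in-category
#'   yes/no.
#' @slot oddsRatio numeric; ad/bc, +Inf when bc = 0, NA when undefined.
#' @slot pValue one-tailed (greater) p-value.
#' @slot test character, "fisher" or "binomial".
#' @slot componentID character id of the tested component ("" if none).
#' @slot selectedIDs character vector of selected feature ids.
#' @slot note character; degenerate-case annotations (e.g. category equals
#'   universe).
#' @export
setClass("EnrichmentResult",
    representation(
        counts = "matrix",
        oddsRatio = "numeric",
        pValue = "numeric",
        test = "character",
        componentID = "character",
        selectedIDs = "character",
        note = "character"
    )
)

setValidity("EnrichmentResult", function(object) {
    if (!all(dim(object@counts) == c(2L, 2L)))
        return("counts must be a 2x2 matrix")
    if (any(object@counts < 0))
        return("counts must be nonnegative")
    if (object@pValue <= 0 || object@pValue > 1)
        return("pValue must lie in (0, 1]")
    TRUE
})

#' Monte Carlo benchmark result
#'
#' Per-run and summary sensitivity/specificity of decomposition methods over
#' a noise-level grid; produced by \code{\link{runBenchmark}}.
#'
#' @slot runs data.frame with columns method, sigma, run, SE, SP, component
#'   (one row per method x noise level x Monte Carlo run; NA for failed
#'   adapter runs).
#' @slot summary data.frame with columns method, sigma, meanSE, meanSP, nRuns.
#' @slot seed integer base seed.
#' @export
setClass("BenchmarkResult",
    representation(
        runs = "data.frame",
        summary = "data.frame",
        seed = "integer"
    )
)
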