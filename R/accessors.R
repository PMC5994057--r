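#' @describeIn OmicsTensor-class dimensions (p1, p2, p).
#' @param x an OmicsTensor.
#' @export
setMethod("dim", "OmicsTensor", function(x) dim(x@values))

#' Extract the numeric array of an OmicsTensor
#' @param x an \linkS4class{OmicsTensor}.
#' @return the underlying p1 x p2 x p array.
#' @export
tensorValues <- function(x) {
    stopifnot(is(x, "OmicsTensor"))
    x@values
}

#' Axis labels of an OmicsTensor
#' @param x an \linkS4class{OmicsTensor}.
#' @return character vector of labels for the requested axis.
#' @export
mode1Labels <- function(x) x@mode1Labels

#' @rdname mode1Labels
#' @export
mode2Labels <- function(x) x@mode2Labels

#' @rdname mode1Labels
#' @export
featureIDs <- function(x) x@featureIDs

#' Accessors for fitted tensor decompositions
#'
#' \code{modeOmega} / \code{modeLambda} return the orthogonal eigenbasis and
#' eigenvalues of mode \code{m}; \code{retainedDims} the retained dimensions
#' (d1, d2); \code{sourceTensor} the source \linkS4class{OmicsTensor};
#' \code{unmixingMatrices} / \code{mixingMatrices} the per-mode W_m / A_m of
#' a \linkS4class{TICAModel}; \code{kurtosisTable} its per-slice excess
#' kurtosis matrix; \code{centeringOffsets} the per-(type, sample) means
#' subtracted before decomposition.
#'
#' @param object a \linkS4class{TPCAModel} or \linkS4class{TICAModel}.
#' @param m mode index, 1 or 2.
#' @name decomposition-accessors
NULL

#' @rdname decomposition-accessors
#' @export
modeOmega <- function(object, m) {
    stopifnot(is(object, "TPCAModel"), m %in% 1:2)
    object@omega[[m]]
}

#' @rdname decomposition-accessors
#' @export
modeLambda <- function(object, m) {
    stopifnot(is(object, "TPCAModel"), m %in% 1:2)
    object@lambda[[m]]
}

#' @rdname decomposition-accessors
#' @export
retainedDims <- function(object) {
    if (is(object, "TPCAModel")) return(object@dims)
    if (is(object, "TICAModel"))
        return(vapply(object@unmixing, nrow, integer(1)))
    stop("no retained dimensions for this object")
}

#' @rdname decomposition-accessors
#' @export
sourceTensor <- function(object) {
    stopifnot(is(object, "TPCAModel") || is(object, "TICAModel"))
    object@source
}

#' @rdname decomposition-accessors
#' @export
unmixingMatrices <- function(object) {
    stopifnot(is(object, "TICAModel"))
    object@unmixing
}

#' @rdname decomposition-accessors
#' @export
mixingMatrices <- function(object) {
    stopifnot(is(object, "TICAModel"))
    object@mixing
}

#' @rdname decomposition-accessors
#' @export
kurtosisTable <- function(object) {
    stopifnot(is(object, "TICAModel"))
    object@kurtosis
}

#' @rdname decomposition-accessors
#' @export
centeringOffsets <- function(object) {
    stopifnot(is(object, "TPCAModel") || is(object, "TICAModel"))
    object@offsets
}

#' Ground-truth accessors for simulated data
#' @param object a \linkS4class{SimulatedDataset}.
#' @return the tensor or the requested truth index sets.
#' @name simulation-accessors
NULL

#' @rdname simulation-accessors
#' @export
simTensor <- function(object) object@tensor

#' @rdname simulation-accessors
#' @export
jointGenes <- function(object) object@jvGenes

#' @rdname simulation-accessors
#' @export
jointSamples <- function(object) object@jvSamples

#' @rdname simulation-accessors
#' @export
individualGenes <- function(object) object@ivGenes

#' @rdname simulation-accessors
#' @export
individualSamples <- function(object) object@ivSamples

setMethod("show", "OmicsTensor", function(object) {
    d <- dim(object@values)
    cat(sprintf("OmicsTensor: %d data type(s) x %d sample(s) x %d feature(s)\n",
                d[1L], d[2L], d[3L]))
    cat("  types:   ", paste(utils::head(object@mode1Labels, 5), collapse = ", "),
        if (d[1L] > 5) ", ..." else "", "\n", sep = "")
    cat("  samples: ", paste(utils::head(object@mode2Labels, 3), collapse = ", "),
        if (d[2L] > 3) ", ..." else "", "\n", sep = "")
    cat("  features:", paste(utils::head(object@featureIDs, 3), collapse = ", "),
        if (d[3L] > 3) ", ..." else "", "\n")
})

setMethod("show", "TPCAModel", function(object) {
    d <- dim(object@source@values)
    cat(sprintf("TPCAModel: source %d x %d x %d (retained dims %s)\n",
                d[1L], d[2L], d[3L], paste(object@dims, collapse = " x ")))
    cat(sprintf("  mode-1 eigenvalues: %s\n",
                paste(signif(utils::head(object@lambda[[1L]], 4), 4),
                      collapse = ", ")))
    cat(sprintf("  mode-2 eigenvalues: %s%s\n",
                paste(signif(utils::head(object@lambda[[2L]], 4), 4),
                      collapse = ", "),
                if (length(object@lambda[[2L]]) > 4) ", ..." else ""))
})

setMethod("show", "TICAModel", function(object) {
    d <- dim(object@source@values)
    cat(sprintf("TICAModel (%s): source %d x %d x %d\n", object@method,
                d[1L], d[2L], d[3L]))
    mx <- apply(object@kurtosis, 2L, max)
    cat("  max excess kurtosis per mode-2 component (ranked):\n  ")
    cat(paste(sprintf("IC%d=%.2f", object@order,
                      mx[object@order])[seq_len(min(6L, d[2L]))],
              collapse = "  "), "\n")
})

setMethod("show", "SimulatedDataset", function(object) {
    d <- dim(object@tensor@values)
    cat(sprintf("SimulatedDataset: %d x %d x %d tensor (SNR e/sigma = %.3g)\n",
                d[1L], d[2L], d[3L], object@snr))
    cat(sprintf("  joint variation: %d + %d genes (disjoint), %d shared samples\n",
                length(object@jvGenes[[1L]]), length(object@jvGenes[[2L]]),
                length(object@jvSamples)))
    cat(sprintf("  individual variation: %d genes, %d samples per type\n",
                length(object@ivGenes[[1L]]), length(object@ivSamples[[1L]])))
})

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf("EnrichmentResult (%s test%s)\n", object@test,
                if (nzchar(object@componentID))
                    paste0(", component ", object@componentID) else ""))
    print(object@counts)
    cat(sprintf("  odds ratio = %s, one-tailed p = %.4g\n",
                format(object@oddsRatio, digits = 4), object@pValue))
    if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "BenchmarkResult", function(object) {
    cat("BenchmarkResult\n")
    print(object@summary, row.names = FALSE)
})

#' Per-run and summary tables of a benchmark
#' @param object a \linkS4class{BenchmarkResult}.
#' @return a data.frame.
#' @export
benchmarkRuns <- function(object) object@runs

#' @rdname benchmarkRuns
#' @export
benchmarkSummary <- function(object) object@summary
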