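## Tensorial PCA: simultaneous eigendecomposition of the two mode covariance
## matrices, Marchenko-Pastur dimension estimation, and whitening.

## Deterministic sign convention: make each column's largest-magnitude entry
## positive (first such entry on ties).
.signFix <- function(V) {
    for (j in seq_len(ncol(V))) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    V
}

#' Estimate the number of significant components by random matrix theory
#'
#' Standardises the columns of \code{M}, computes their sample correlation
#' matrix, and counts eigenvalues exceeding the Marchenko-Pastur upper edge
#' \code{(1 + sqrt(n_var / n_obs))^2} — the largest eigenvalue expected from
#' pure noise when \code{n_obs} observations of \code{n_var} uncorrelated
#' variables are observed.  Deterministic for fixed input.
#'
#' @param M numeric matrix, rows = observations (e.g. features), columns =
#'   variables (e.g. samples).  Zero-variance columns are excluded with a
#'   warning.
#' @return nonnegative integer: estimated number of components above the
#'   noise edge.
#' @export
rmtEstimateDim <- function(M) {
    M <- as.matrix(M)
    if (nrow(M) < 2L || ncol(M) < 2L)
        stop("'M' must have at least 2 rows and 2 columns")
    sds <- apply(M, 2L, stats::sd)
    zero <- sds < .Machine$double.eps
    if (all(zero))
        stop("all columns have zero variance")
    if (any(zero)) {
        warning(sprintf("excluding %d zero-variance column(s)", sum(zero)))
        M <- M[, !zero, drop = FALSE]
    }
    if (ncol(M) < 2L)
        stop("fewer than 2 non-constant columns")
    edge <- (1 + sqrt(ncol(M) / nrow(M)))^2
    ev <- eigen(stats::cor(M), symmetric = TRUE, only.values = TRUE)$values
    sum(ev > edge)
}

## Resolve a dims specification against tensor dimensions.  Policy for
## "rmt" on a (type x sample x feature) tensor: the small type mode is kept
## full; the sample mode is reduced to the maximum of the per-type RMT
## estimates on the type-specific feature x sample matrices (kept full when
## p2 <= 3, where reduction is unnecessary).
.resolveDims <- function(X, dims) {
    d <- dim(X@values)
    if (is.character(dims) && length(dims) == 1L) {
        if (dims == "full") return(c(d[1L], d[2L]))
        if (dims == "rmt") {
            d1 <- d[1L]
            if (d[2L] <= 3L) {
                d2 <- d[2L]
            } else {
                est <- vapply(seq_len(d[1L]), function(t)
                    rmtEstimateDim(t(matrix(X@values[t, , ], d[2L], d[3L]))),
                    integer(1))
                d2 <- max(1L, min(d[2L], max(est)))
            }
            return(c(d1, d2))
        }
        stop("'dims' must be \"full\", \"rmt\" or an integer pair")
    }
    dims <- as.integer(dims)
    if (length(dims) != 2L || any(is.na(dims)) || any(dims < 1L))
        stop("'dims' must be \"full\", \"rmt\" or an integer pair")
    if (any(dims > d[1:2]))
        stop(sprintf("requested dims (%d, %d) exceed tensor mode dimensions (%d, %d)",
                     dims[1L], dims[2L], d[1L], d[2L]))
    dims
}

#' Fit a tensorial PCA decomposition
#'
#' Eigendecomposes the mode-1 and mode-2 covariance matrices of the centered
#' tensor, giving orthogonal per-mode bases Omega_m whose leading columns
#' span the directions of largest variance, and projects the tensor onto
#' them to obtain the source tensor \code{S = X (x)_1 Omega_1^T (x)_2
#' Omega_2^T} (reduced to the retained dimensions).  At full dimensions the
#' decomposition is exactly invertible: \code{S (x)_m Omega_m} plus the
#' centering offsets reconstructs the input.
#'
#' @param X an \linkS4class{OmicsTensor}.
#' @param dims \code{"rmt"} (default; type mode kept full, sample mode set
#'   to the maximum per-type Marchenko-Pastur estimate), \code{"full"}, or
#'   an integer pair (d1, d2).
#' @param center subtract per-(type, sample) means first (default TRUE).
#' @param normalize variance-scale the mode covariances (default TRUE; the
#'   eigenvectors, hence the decomposition, are invariant to this).
#' @return a \linkS4class{TPCAModel}.
#' @seealso \code{\link{whitenTensor}}, \code{\link{tWFOBI}}
#' @export
tpcaFit <- function(X, dims = "rmt", center = TRUE, normalize = TRUE) {
    stopifnot(is(X, "OmicsTensor"))
    d <- dim(X@values)
    if (d[3L] <= max(d[1:2]))
        warning("fewer realisations (features) than the largest decomposed ",
                "mode; eigenvectors will be poorly determined")
    if (center) {
        cc <- centerRealisations(X)
        Xc <- cc$tensor
        off <- cc$offsets
    } else {
        Xc <- X
        off <- matrix(0, d[1L], d[2L])
    }
    rd <- .resolveDims(Xc, dims)
    omega <- vector("list", 2L)
    lambda <- vector("list", 2L)
    for (m in 1:2) {
        eg <- eigen(modeCovariance(Xc, m, normalize = normalize),
                    symmetric = TRUE)
        omega[[m]] <- .signFix(eg$vectors)
        lambda[[m]] <- pmax(eg$values, 0)
    }
    src <- modeMultiply(Xc, t(omega[[1L]][, seq_len(rd[1L]), drop = FALSE]), 1L,
                        labels = paste0("tc", seq_len(rd[1L])))
    src <- modeMultiply(src, t(omega[[2L]][, seq_len(rd[2L]), drop = FALSE]), 2L,
                        labels = paste0("sc", seq_len(rd[2L])))
    new("TPCAModel", omega = omega, lambda = lambda, dims = rd,
        offsets = off, source = src, normalized = isTRUE(normalize))
}

#' Reconstruct the data tensor from a TPCAModel
#'
#' \code{S (x)_1 Omega_1^(R) (x)_2 Omega_2^(R)} plus the centering offsets;
#' exact (up to numerical error) when the model was fitted at full
#' dimensions.
#'
#' @param model a \linkS4class{TPCAModel}.
#' @return an \linkS4class{OmicsTensor} of the original dimensions.
#' @export
tpcaReconstruct <- function(model) {
    stopifnot(is(model, "TPCAModel"))
    rd <- model@dims
    out <- modeMultiply(model@source,
                        model@omega[[1L]][, seq_len(rd[1L]), drop = FALSE], 1L)
    out <- modeMultiply(out,
                        model@omega[[2L]][, seq_len(rd[2L]), drop = FALSE], 2L)
    OmicsTensor(out@values + as.vector(model@offsets),
                out@mode1Labels, out@mode2Labels, out@featureIDs)
}

#' Whiten an OmicsTensor by tensorial PCA
#'
#' Projects the centered tensor onto the retained eigenbasis of each mode
#' and (by default) rescales by the inverse square-root eigenvalues, so the
#' retained components have unit variance:
#' \code{Xw = X (x)_m Lambda_m^(-1/2) Omega_m^(R)T}, m = 1, 2.  The modes
#' are whitened sequentially (mode 1 first); the mode-2 eigenbasis is
#' computed on the mode-1-whitened tensor, so the scale coupling between
#' modes cancels.  After transforming a single mode, that mode's
#' (variance-scaled) covariance of the output is exactly the identity;
#' with both modes transformed, the last mode is exactly white and the
#' first is white up to the finite-sample coupling between modes.
#'
#' @inheritParams tpcaFit
#' @param scale rescale variances (default TRUE); with \code{scale = FALSE}
#'   the output is the plain tPCA projection.
#' @param modes which modes to transform (default \code{1:2}).
#' @return list with elements \code{tensor} (whitened
#'   \linkS4class{OmicsTensor}) and \code{model} (a
#'   \linkS4class{TPCAModel} carrying the per-mode bases and eigenvalues
#'   actually used).
#' @export
whitenTensor <- function(X, dims = "rmt", scale = TRUE, center = TRUE,
                         modes = 1:2) {
    stopifnot(is(X, "OmicsTensor"), all(modes %in% 1:2))
    d <- dim(X@values)
    if (center) {
        cc <- centerRealisations(X)
        Xc <- cc$tensor
        off <- cc$offsets
    } else {
        Xc <- X
        off <- matrix(0, d[1L], d[2L])
    }
    rd <- .resolveDims(Xc, dims)
    omega <- list(diag(d[1L]), diag(d[2L]))
    lambda <- lapply(1:2, function(m) rep(1, d[m]))
    out <- Xc
    for (m in sort(modes)) {
        eg <- eigen(modeCovariance(out, m, normalize = TRUE),
                    symmetric = TRUE)
        omega[[m]] <- .signFix(eg$vectors)
        lambda[[m]] <- pmax(eg$values, 0)
        dm <- rd[m]
        lam <- lambda[[m]][seq_len(dm)]
        if (any(lam <= 1e-12 * max(lambda[[m]][1L], .Machine$double.eps)))
            stop(sprintf("degenerate whitening: zero eigenvalue among the %d retained dimensions of mode %d",
                         dm, m))
        W <- t(omega[[m]][, seq_len(dm), drop = FALSE])
        if (scale) W <- W / sqrt(lam)
        out <- modeMultiply(out, W, m,
                            labels = paste0(if (m == 1L) "tc" else "sc",
                                            seq_len(dm)))
    }
    src <- modeMultiply(Xc, t(omega[[1L]][, seq_len(rd[1L]), drop = FALSE]),
                        1L, labels = paste0("tc", seq_len(rd[1L])))
    src <- modeMultiply(src, t(omega[[2L]][, seq_len(rd[2L]), drop = FALSE]),
                        2L, labels = paste0("sc", seq_len(rd[2L])))
    model <- new("TPCAModel", omega = omega, lambda = lambda, dims = rd,
                 offsets = off, source = src, normalized = TRUE)
    list(tensor = out, model = model)
}
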