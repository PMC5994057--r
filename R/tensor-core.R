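## Order-3 tensor algebra over modes 1 and 2; mode 3 (features) is the
## i.i.d.-realisation axis and is never contracted.

#' Center an OmicsTensor across realisations
#'
#' Subtracts, for every (data type, sample) cell, its mean over the feature
#' axis, so each scalar variable X[k1, k2, .] has empirical mean zero.  This
#' is the sample analogue of the zero-mean assumption on the latent sources.
#' No variance scaling is applied.
#'
#' @param X an \linkS4class{OmicsTensor}.
#' @return list with elements \code{tensor} (centered
#'   \linkS4class{OmicsTensor}) and \code{offsets} (p1 x p2 matrix of
#'   subtracted means; adding them back reconstructs \code{X} exactly).
#' @examples
#' x <- OmicsTensor(array(1:12, c(2, 2, 3)))
#' cc <- centerRealisations(x)
#' max(abs(apply(tensorValues(cc$tensor), c(1, 2), mean)))
#' @export
centerRealisations <- function(X) {
    stopifnot(is(X, "OmicsTensor"))
    v <- X@values
    off <- rowMeans(v, dims = 2L)  # p1 x p2 means over the feature axis
    out <- v - as.vector(off)      # recycles over dim 3 (column-major)
    list(tensor = OmicsTensor(out, X@mode1Labels, X@mode2Labels,
                              X@featureIDs),
         offsets = off)
}

#' Mode contraction of an order-3 tensor by a matrix
#'
#' Multiplies tensor \code{Z} along mode \code{m} by matrix \code{A}
#' (q x p_m), replacing that mode's dimension by q:
#' \code{(Z (x)_m A)[.., a, ..] = sum_j Z[.., j, ..] A[a, j]}.
#'
#' @param Z an \linkS4class{OmicsTensor}.
#' @param A numeric matrix with \code{ncol(A)} equal to Z's mode-m dimension.
#' @param m mode index, 1 or 2 (the feature mode is never contracted).
#' @param labels optional labels for the new axis; defaults to rownames(A)
#'   or generated names.
#' @return the contracted \linkS4class{OmicsTensor}.
#' @export
modeMultiply <- function(Z, A, m, labels = NULL) {
    stopifnot(is(Z, "OmicsTensor"))
    if (!(length(m) == 1L && m %in% 1:2))
        stop("'m' must be 1 or 2")
    A <- as.matrix(A)
    d <- dim(Z@values)
    if (ncol(A) != d[m])
        stop(sprintf("dimension mismatch: ncol(A) = %d but mode-%d dimension is %d",
                     ncol(A), m, d[m]))
    q <- nrow(A)
    if (is.null(labels)) {
        labels <- rownames(A)
        if (is.null(labels)) labels <- paste0("c", seq_len(q))
    }
    if (m == 1L) {
        out <- array(A %*% matrix(Z@values, d[1L], d[2L] * d[3L]),
                     c(q, d[2L], d[3L]))
        OmicsTensor(out, labels, Z@mode2Labels, Z@featureIDs)
    } else {
        perm <- aperm(Z@values, c(2L, 1L, 3L))
        out <- array(A %*% matrix(perm, d[2L], d[1L] * d[3L]),
                     c(q, d[1L], d[3L]))
        OmicsTensor(aperm(out, c(2L, 1L, 3L)),
                    Z@mode1Labels, labels, Z@featureIDs)
    }
}

#' Mode covariance matrix of an order-3 tensor
#'
#' Returns the p_m x p_m matrix of summed outer products over all other
#' indices (the other decomposed mode and the feature axis):
#' \code{C[u, v] = sum over (other, i) of X[.., u, ..] X[.., v, ..]},
#' optionally divided by the number of summed terms (p * p_other) so the
#' eigenvalues are variance-scaled.  Normalisation rescales eigenvalues
#' only; eigenvectors, hence all rotations, are unchanged.
#'
#' @param X an \linkS4class{OmicsTensor}, expected centered (a warning is
#'   emitted if any per-(type, sample) mean exceeds 1e-8).
#' @param m mode index, 1 or 2.
#' @param normalize divide by the number of summed terms (default TRUE).
#' @return symmetric positive semi-definite p_m x p_m matrix.
#' @export
modeCovariance <- function(X, m, normalize = TRUE) {
    stopifnot(is(X, "OmicsTensor"))
    if (!(length(m) == 1L && m %in% 1:2))
        stop("invalid mode: 'm' must be 1 or 2")
    v <- X@values
    d <- dim(v)
    mu <- rowMeans(v, dims = 2L)
    if (max(abs(mu)) > 1e-8)
        warning("tensor does not appear centered across realisations ",
                sprintf("(max |mean| = %.3g); consider centerRealisations()",
                        max(abs(mu))))
    M <- if (m == 1L) matrix(v, d[1L], d[2L] * d[3L])
         else matrix(aperm(v, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
    C <- tcrossprod(M)
    C <- (C + t(C)) / 2
    if (normalize) C <- C / (d[3L] * d[setdiff(1:2, m)])
    C
}

#' Realisation-wise matricisation of an OmicsTensor
#'
#' Returns one p_m x p_other matrix per feature/realisation: element i is
#' the (p1 x p2) slice of realisation i, transposed when \code{m = 2} so
#' mode m always indexes rows.  \code{restackTensor} is the exact inverse.
#'
#' @param X an \linkS4class{OmicsTensor}.
#' @param m mode index, 1 or 2.
#' @return list of p matrices.
#' @export
modeFlatten <- function(X, m) {
    stopifnot(is(X, "OmicsTensor"))
    if (!(length(m) == 1L && m %in% 1:2))
        stop("'m' must be 1 or 2")
    v <- X@values
    d <- dim(v)
    lapply(seq_len(d[3L]), function(i) {
        sl <- matrix(v[, , i], d[1L], d[2L])
        if (m == 2L) t(sl) else sl
    })
}

#' @rdname modeFlatten
#' @param slices list of matrices as produced by \code{modeFlatten}.
#' @param template \linkS4class{OmicsTensor} supplying labels.
#' @export
restackTensor <- function(slices, m, template) {
    stopifnot(is(template, "OmicsTensor"))
    d <- dim(template@values)
    v <- array(0, d)
    for (i in seq_along(slices)) {
        sl <- slices[[i]]
        v[, , i] <- if (m == 2L) t(sl) else sl
    }
    OmicsTensor(v, template@mode1Labels, template@mode2Labels,
                template@featureIDs)
}
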