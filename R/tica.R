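## Tensorial ICA: FOBI and JADE rotations applied per mode after tPCA
## whitening (tWFOBI / tWJADE), kurtosis ranking and back-projection.

#' Excess kurtosis of a sample
#'
#' \code{m4 / m2^2 - 3} using central moments, without small-sample bias
#' correction.  Zero for Gaussian data, positive for heavy-tailed/sparse
#' sources — the basis for ranking independent components.
#'
#' @param v numeric vector, length >= 4, nonzero variance.
#' @return excess kurtosis (a single number).
#' @export
excessKurtosis <- function(v) {
    v <- as.numeric(v)
    if (length(v) < 4L)
        stop("need at least 4 observations for kurtosis")
    m <- mean(v)
    m2 <- mean((v - m)^2)
    if (m2 <= 0)
        stop("kurtosis undefined: zero variance")
    mean((v - m)^4) / m2^2 - 3
}

## Fourth-moment matrix B_m = mean_i [ M_i M_i^T M_i M_i^T ] over the
## mode-m matricisations M_i (d_m x d_other) of each realisation.
## Vectorised: with A[u, v, i] = (M_i M_i^T)[u, v],
## B = unfold(A) unfold(A)^T / p.
.fobiMatrix <- function(Xw, m) {
    v <- Xw@values
    if (m == 2L) v <- aperm(v, c(2L, 1L, 3L))
    d <- dim(v)  # (d_m, d_other, p)
    A <- array(0, c(d[1L], d[1L], d[3L]))
    for (u in seq_len(d[1L])) {
        Vu <- matrix(v[u, , ], d[2L], d[3L])
        for (w in u:d[1L]) {
            s <- colSums(Vu * matrix(v[w, , ], d[2L], d[3L]))
            A[u, w, ] <- s
            A[w, u, ] <- s
        }
    }
    tcrossprod(matrix(A, d[1L], d[1L] * d[3L])) / d[3L]
}

#' FOBI rotation for one mode of a whitened tensor
#'
#' Computes the fourth-moment matrix \code{B_m = mean_i [M_i M_i^T M_i
#' M_i^T]} over the mode-m matricisations of each realisation of the
#' whitened tensor and returns its eigenvector matrix (eigenvalue-
#' descending, sign-fixed).  When the other mode has dimension 1 this is
#' classical FOBI on vector data.
#'
#' @param Xw a whitened (variance-scaled) \linkS4class{OmicsTensor}.
#' @param m mode index, 1 or 2.
#' @return orthogonal d_m x d_m rotation matrix.
#' @export
fobiRotation <- function(Xw, m) {
    stopifnot(is(Xw, "OmicsTensor"), m %in% 1:2)
    d <- dim(Xw@values)[m]
    if (d == 1L) return(matrix(1, 1L, 1L))
    B <- .fobiMatrix(Xw, m)
    eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
    gaps <- abs(diff(eg$values))
    if (any(gaps < 1e-10))
        warning("tied eigenvalues of the fourth-moment matrix; the FOBI ",
                "rotation is not identifiable in the tied subspace")
    .signFix(eg$vectors)
}

## Pooled mode-m fibers of the whitened tensor as an N x d matrix
## (N = p * d_other rows).
.pooledFibers <- function(Xw, m) {
    v <- Xw@values
    if (m == 2L) v <- aperm(v, c(2L, 1L, 3L))
    d <- dim(v)
    t(matrix(v, d[1L], d[2L] * d[3L]))
}

## Symmetrised fourth-order cumulant matrices of whitened fibers:
## C^(ij) = mean_n[r_i r_j r r^T] - delta_ij I - e_i e_j^T - e_j e_i^T.
.cumulantMatrices <- function(R) {
    N <- nrow(R)
    d <- ncol(R)
    out <- vector("list", d * (d + 1L) / 2L)
    k <- 0L
    I <- diag(d)
    for (i in seq_len(d)) for (j in i:d) {
        w <- R[, i] * R[, j]
        C <- crossprod(R, R * w) / N
        C <- (C + t(C)) / 2
        C <- C - I[, i, drop = FALSE] %*% t(I[, j, drop = FALSE]) -
                 I[, j, drop = FALSE] %*% t(I[, i, drop = FALSE])
        if (i == j) C <- C - I
        k <- k + 1L
        out[[k]] <- C
    }
    out
}

#' Jacobi joint approximate diagonalisation
#'
#' Jointly diagonalises a set of symmetric matrices by Givens sweeps with
#' the closed-form optimal angle per 2x2 subproblem; stops when every
#' rotation angle in a sweep is below \code{tol} or after
#' \code{maxSweeps}.  The summed squared off-diagonal criterion is
#' non-increasing across sweeps.
#'
#' @param mats list of symmetric d x d matrices (asymmetry above 1e-8 is an
#'   error).
#' @param tol rotation-angle convergence threshold (default 1e-8 radians).
#' @param maxSweeps maximum number of full sweeps (default 100).
#' @return orthogonal d x d matrix V such that V^T M V is as diagonal as
#'   possible simultaneously for all inputs.
#' @export
jointDiagonalize <- function(mats, tol = 1e-8, maxSweeps = 100L) {
    stopifnot(is.list(mats), length(mats) >= 1L)
    d <- nrow(mats[[1L]])
    for (M in mats) {
        if (!is.matrix(M) || nrow(M) != d || ncol(M) != d)
            stop("all matrices must be square with equal dimension")
        if (max(abs(M - t(M))) > 1e-8)
            stop("non-symmetric input matrix (asymmetry > 1e-8)")
    }
    if (d == 1L) return(matrix(1, 1L, 1L))
    K <- length(mats)
    A <- array(unlist(mats), c(d, d, K))
    V <- diag(d)
    for (sweep in seq_len(maxSweeps)) {
        maxAngle <- 0
        for (p in seq_len(d - 1L)) for (q in (p + 1L):d) {
            h1 <- A[p, p, ] - A[q, q, ]
            h2 <- A[p, q, ] + A[q, p, ]
            ton <- sum(h1 * h1) - sum(h2 * h2)
            toff <- 2 * sum(h1 * h2)
            theta <- 0.5 * atan2(toff, ton + sqrt(ton * ton + toff * toff))
            maxAngle <- max(maxAngle, abs(theta))
            if (abs(theta) > tol) {
                cs <- cos(theta); sn <- sin(theta)
                Ap <- A[, p, ]; Aq <- A[, q, ]
                A[, p, ] <- cs * Ap + sn * Aq
                A[, q, ] <- -sn * Ap + cs * Aq
                Ap <- A[p, , ]; Aq <- A[q, , ]
                A[p, , ] <- cs * Ap + sn * Aq
                A[q, , ] <- -sn * Ap + cs * Aq
                vp <- V[, p]
                V[, p] <- cs * vp + sn * V[, q]
                V[, q] <- -sn * vp + cs * V[, q]
            }
        }
        if (maxAngle <= tol) break
    }
    V
}

#' JADE rotation for one mode of a whitened tensor
#'
#' Builds the d_m(d_m+1)/2 symmetrised fourth-cumulant matrices over the
#' pooled mode-m fibers of the whitened tensor (N = p * d_other fibers) and
#' jointly diagonalises them by Jacobi sweeps.  Columns of the returned
#' rotation are ordered by decreasing excess kurtosis of the rotated fibers
#' and sign-fixed.
#'
#' @inheritParams fobiRotation
#' @return orthogonal d_m x d_m rotation matrix.
#' @export
jadeRotation <- function(Xw, m) {
    stopifnot(is(Xw, "OmicsTensor"), m %in% 1:2)
    d <- dim(Xw@values)[m]
    if (d == 1L) return(matrix(1, 1L, 1L))
    R <- .pooledFibers(Xw, m)
    if (nrow(R) < d * d)
        warning(sprintf("only %d pooled fibers for a %d-dimensional mode: cumulant estimates may be unstable",
                        nrow(R), d))
    V <- jointDiagonalize(.cumulantMatrices(R))
    S <- R %*% V
    kt <- apply(S, 2L, excessKurtosis)
    V <- V[, order(-kt, seq_along(kt)), drop = FALSE]
    .signFix(V)
}

## Skewness-based deterministic sign fix of mode-2 components: flip W_2 row
## j (and A_2 column j) so the source slice with the largest |skewness|
## across mode-1 levels has non-negative skewness; when all |skewness| are
## below 1e-8, make the largest-|weight| entry of slice (1, j) positive.
.fixComponentSigns <- function(S, W2) {
    d <- dim(S)
    flip <- rep(1, d[2L])
    for (j in seq_len(d[2L])) {
        sk <- vapply(seq_len(d[1L]), function(k) {
            x <- S[k, j, ]
            m2 <- mean((x - mean(x))^2)
            if (m2 <= 0) return(0)
            mean((x - mean(x))^3) / m2^1.5
        }, numeric(1))
        k <- which.max(abs(sk))
        if (abs(sk[k]) >= 1e-8) {
            if (sk[k] < 0) flip[j] <- -1
        } else {
            x <- S[1L, j, ]
            if (x[which.max(abs(x))] < 0) flip[j] <- -1
        }
    }
    flip
}

.ticaFit <- function(X, dims, rotation, method) {
    wh <- whitenTensor(X, dims = dims, scale = TRUE, center = TRUE)
    fit <- wh$model
    U <- lapply(1:2, function(m) rotation(wh$tensor, m))
    W <- vector("list", 2L)
    A <- vector("list", 2L)
    for (m in 1:2) {
        dm <- fit@dims[m]
        lam <- fit@lambda[[m]][seq_len(dm)]
        Om <- fit@omega[[m]][, seq_len(dm), drop = FALSE]
        W[[m]] <- t(U[[m]]) %*% (t(Om) / sqrt(lam))
        A[[m]] <- Om %*% (sqrt(lam) * U[[m]])
    }
    cc <- centerRealisations(X)
    src <- modeMultiply(cc$tensor, W[[1L]], 1L,
                        labels = paste0("tc", seq_len(fit@dims[1L])))
    src <- modeMultiply(src, W[[2L]], 2L,
                        labels = paste0("IC", seq_len(fit@dims[2L])))
    flip <- .fixComponentSigns(src@values, W[[2L]])
    if (any(flip < 0)) {
        W[[2L]] <- flip * W[[2L]]
        A[[2L]] <- sweep(A[[2L]], 2L, flip, "*")
        src@values <- src@values * rep(flip, each = dim(src@values)[1L])
    }
    kt <- apply(src@values, c(1L, 2L), excessKurtosis)
    kt <- matrix(kt, dim(src@values)[1L], dim(src@values)[2L])
    mx <- apply(kt, 2L, max)
    new("TICAModel", unmixing = W, mixing = A, source = src,
        kurtosis = kt, order = order(-mx, seq_along(mx)),
        offsets = cc$offsets, method = method)
}

#' Tensorial ICA with tPCA whitening (tWFOBI, tWJADE)
#'
#' Whitens the tensor by tensorial PCA (centering, projection onto the
#' retained per-mode eigenbases, variance rescaling), then applies an ICA
#' rotation to each mode — FOBI (\code{tWFOBI}) or JADE (\code{tWJADE}) —
#' giving per-mode unmixing matrices \code{W_m = U_m^T Lambda_m^(-1/2)
#' Omega_m^T} and the source tensor \code{S = X (x)_1 W_1 (x)_2 W_2} whose
#' slices are maximally statistically independent across features.  The
#' whole pipeline is deterministic.
#'
#' @inheritParams tpcaFit
#' @return a \linkS4class{TICAModel}.
#' @examples
#' sim <- simulateMultiOmic(simConfig(seed = 7))
#' fit <- tWFOBI(simTensor(sim), dims = c(2, 6))
#' fit
#' @export
tWFOBI <- function(X, dims = "rmt") {
    .ticaFit(X, dims, fobiRotation, "tWFOBI")
}

#' @rdname tWFOBI
#' @export
tWJADE <- function(X, dims = "rmt") {
    .ticaFit(X, dims, jadeRotation, "tWJADE")
}

#' Rank inferred components by excess kurtosis
#'
#' Orders the mode-2 (sample-space) components by decreasing maximum excess
#' kurtosis over the mode-1 levels; ties are broken by component index.
#' Sparse, non-Gaussian sources of variation have large positive kurtosis,
#' so highly ranked components are the biologically interesting ones.
#'
#' @param model a \linkS4class{TICAModel}.
#' @return data.frame with one row per (mode-1 level, component), ordered by
#'   component rank: columns rank, component, mode1, kurtosis, maxKurtosis.
#' @export
rankComponents <- function(model) {
    stopifnot(is(model, "TICAModel"))
    kt <- model@kurtosis
    d1 <- nrow(kt); d2 <- ncol(kt)
    ord <- model@order
    lv1 <- mode1Labels(model@source)
    out <- do.call(rbind, lapply(seq_len(d2), function(r) {
        j <- ord[r]
        data.frame(rank = r, component = j, mode1 = lv1,
                   kurtosis = kt[, j], maxKurtosis = max(kt[, j]),
                   row.names = NULL)
    }))
    out
}

#' Back-project sources onto the original mode-1 (data-type) axes
#'
#' Applies the mode-1 mixing matrix to the source tensor, \code{S (x)_1
#' A_1}, turning each mode-2 component into one weight vector per original
#' data type — the representation used for feature selection and
#' enrichment.  Requires the mode-1 axis to be unreduced (d1 = p1).
#'
#' @param model a \linkS4class{TICAModel}.
#' @return an \linkS4class{OmicsTensor} of dimension p1 x d2 x p.
#' @export
projectMode1 <- function(model) {
    stopifnot(is(model, "TICAModel"))
    A1 <- model@mixing[[1L]]
    if (ncol(A1) < nrow(A1))
        stop("mode-1 was reduced (d1 < p1); back-projection requires an unreduced data-type mode")
    modeMultiply(model@source, A1, 1L,
                 labels = rownames(A1) %||% paste0("type", seq_len(nrow(A1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
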