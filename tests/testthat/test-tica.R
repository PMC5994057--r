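test_that("excess kurtosis matches analytic values", {
    expect_equal(excessKurtosis(rep(c(-1, 1), 50)), -2)
    set.seed(20)
    expect_lt(abs(excessKurtosis(rnorm(2e5))), 0.1)
    expect_lt(abs(excessKurtosis(unit_source(2e5, "laplace")) - 3), 0.2)
    expect_lt(abs(excessKurtosis(unit_source(2e5, "uniform")) + 1.2), 0.1)
    expect_error(excessKurtosis(rep(1, 10)), "zero variance")
    expect_error(excessKurtosis(1:3), "at least 4")
})

test_that("joint diagonalisation recovers a common eigenbasis", {
    set.seed(21)
    # already-diagonal input: identity
    V <- jointDiagonalize(list(diag(c(3, 2, 1)), diag(c(1, 5, 2))))
    expect_lt(max(abs(abs(V) - diag(3))), 1e-8)

    # common basis with distinct diagonals is recovered up to sign/perm
    Q <- rand_orthogonal(4)
    mats <- list(Q %*% diag(c(4, 3, 2, 1)) %*% t(Q),
                 Q %*% diag(c(1, 4, 2, 3)) %*% t(Q))
    V <- jointDiagonalize(mats)
    expect_lt(md_index(t(V) %*% Q), 0.01)

    # a single symmetric matrix reaches the eigendecomposition optimum
    M <- crossprod(matrix(rnorm(36), 6))
    V1 <- jointDiagonalize(list(M))
    off <- function(A) sum(A^2) - sum(diag(A)^2)
    eg <- eigen(M, symmetric = TRUE)
    expect_lt(abs(off(t(V1) %*% M %*% V1) -
                  off(diag(eg$values))), 1e-10)

    # criterion is never worse than the un-rotated input
    expect_lte(off(t(V) %*% mats[[1]] %*% V), off(mats[[1]]) + 1e-12)

    expect_error(jointDiagonalize(list(matrix(rnorm(9), 3))),
                 "non-symmetric")
})

test_that("FOBI rotation reduces to classical FOBI and finds sources", {
    set.seed(22)
    # d_other = 1: identical to classical FOBI on vector data
    p <- 5000
    Xw <- OmicsTensor(array(rnorm(3 * 1 * p), c(3, 1, p)))
    U <- suppressWarnings(fobiRotation(Xw, 1))
    xs <- matrix(tensorValues(Xw), 3, p)
    B <- matrix(0, 3, 3)
    for (i in seq_len(p)) {
        x <- xs[, i]
        B <- B + sum(x^2) * tcrossprod(x)
    }
    B <- B / p
    Uc <- eigen(B, symmetric = TRUE)$vectors
    expect_lt(max(abs(abs(U) - abs(Uc))), 1e-8)

    # independent fibers with distinct kurtoses: rotation ~ identity.
    # (unit-variance independent slices are already white, so the tensor
    # is used directly; re-whitening would insert an arbitrary rotation
    # from the tied sample eigenvalues)
    fam <- fobi_friendly_families()
    S0 <- make_source_tensor(2, 3, 100000, fam)
    for (m in 1:2) {
        U <- fobiRotation(OmicsTensor(S0), m)
        expect_lt(md_index(U), 0.15)
    }

    # Gaussian-only input: the contract (orthogonality) still holds
    Xg <- OmicsTensor(array(rnorm(2 * 2 * 2000), c(2, 2, 2000)))
    Ug <- fobiRotation(whitenTensor(Xg, dims = "full")$tensor, 1)
    expect_lt(max(abs(crossprod(Ug) - diag(2))), 1e-10)
})

test_that("JADE rotation inverts a known orthogonal mixing", {
    set.seed(23)
    p <- 50000
    fam <- matrix(c("laplace", "uniform", "logistic", "laplace"), 2, 2)
    S0 <- make_source_tensor(2, 2, p, fam)
    Q <- rand_orthogonal(4)  # mix the pooled mode-1 fibers? no: per mode
    Q1 <- rand_orthogonal(2)
    X <- modeMultiply(OmicsTensor(S0), Q1, 1)
    U <- jadeRotation(X, 1)  # already unit-variance, whitening-free mixing
    expect_lt(md_index(t(U) %*% Q1), 0.05)

    # d_m = 1 returns the trivial rotation
    X1 <- OmicsTensor(array(rnorm(1 * 2 * 100), c(1, 2, 100)))
    expect_equal(jadeRotation(X1, 1), matrix(1, 1, 1))

    # cumulant matrices of exactly Gaussian whitened data vanish in mean
    N <- 100000
    R <- matrix(rnorm(N * 3), N, 3)
    R <- scale(R, scale = apply(R, 2, sd))
    mats <- tensorICA:::.cumulantMatrices(R)
    fro <- vapply(mats, function(C) norm(C, "F"), numeric(1))
    # entries are means of N 4th-order terms: SE ~ sqrt(Var/N) with
    # Var <= E[r^8]-ish ~ 100; 3-sigma bound on the Frobenius norm
    expect_lt(max(fro), 3 * sqrt(9 * 100 / N))
})

test_that("tWFOBI and tWJADE recover planted independent sources", {
    set.seed(24)
    p <- 10000
    # JADE: iid Laplace sources (equal kurtosis is fine for JADE)
    S0 <- make_source_tensor(2, 3, p, matrix("laplace", 2, 3))
    Q1 <- rand_orthogonal(2); Q2 <- rand_orthogonal(3)
    X <- modeMultiply(modeMultiply(OmicsTensor(S0), Q1, 1), Q2, 2)
    fit <- tWJADE(X, dims = "full")
    expect_gt(min(match_correlations(tensorValues(sourceTensor(fit)), S0)),
              0.95)

    # FOBI: its identifiability regime needs distinct kurtosis sums
    S0f <- make_source_tensor(2, 3, p, fobi_friendly_families())
    Xf <- modeMultiply(modeMultiply(OmicsTensor(S0f), Q1, 1), Q2, 2)
    fitf <- tWFOBI(Xf, dims = "full")
    expect_gt(min(match_correlations(tensorValues(sourceTensor(fitf)), S0f)),
              0.95)

    for (f in list(fit, fitf)) {
        # unmixing/mixing are mutual pseudo-inverses
        for (m in 1:2)
            expect_lt(max(abs(unmixingMatrices(f)[[m]] %*%
                              mixingMatrices(f)[[m]] -
                              diag(nrow(unmixingMatrices(f)[[m]])))), 1e-8)
        # source slices have mean 0 and variance 1 (per-slice variance is
        # exact only on average across the other mode; individual slices
        # fluctuate at the O(p^-1/2) cross-mode coupling scale)
        S <- tensorValues(sourceTensor(f))
        expect_lt(max(abs(apply(S, c(1, 2), mean))), 1e-8)
        expect_lt(max(abs(apply(S, c(1, 2), function(v)
            mean(v^2)) - 1)), 0.05)
        # mode-2 (last-whitened) covariance is exactly diagonal; mode-1 is
        # diagonal up to the finite-sample coupling between modes
        C2 <- modeCovariance(sourceTensor(f), 2)
        expect_lt(max(abs(C2 - diag(diag(C2)))), 1e-8 * sum(diag(C2)))
        C1 <- modeCovariance(sourceTensor(f), 1)
        expect_lt(max(abs(C1 - diag(diag(C1)))), 5e-3 * sum(diag(C1)))
    }
})

test_that("Gaussian-only tensors give valid models with near-zero kurtosis", {
    set.seed(25)
    X <- OmicsTensor(array(rnorm(2 * 3 * 10000), c(2, 3, 10000)))
    for (fitter in list(tWFOBI, tWJADE)) {
        f <- suppressWarnings(fitter(X, dims = "full"))
        expect_lt(max(abs(kurtosisTable(f))), 0.1)
    }
})

test_that("fitting is equivariant to orthogonal sample-mode rotation", {
    set.seed(26)
    p <- 10000
    S0 <- make_source_tensor(2, 3, p, matrix("laplace", 2, 3))
    Q2 <- rand_orthogonal(3)
    X <- OmicsTensor(S0)
    XQ <- modeMultiply(X, Q2, 2)
    f1 <- tWJADE(X, dims = "full")
    f2 <- tWJADE(XQ, dims = "full")
    S1 <- tensorValues(sourceTensor(f1))
    S2 <- tensorValues(sourceTensor(f2))
    # same sources up to sign/permutation of components
    cors <- match_correlations(S2, S1)
    expect_gt(min(cors), 0.95)
})

test_that("source recovery improves with the number of realisations", {
    # minimum-distance index decreases as p grows (median over seeds)
    md_at <- function(p, nseeds = 7) {
        vapply(seq_len(nseeds), function(s) {
            set.seed(1000 + s)
            S0 <- make_source_tensor(2, 3, p, matrix("laplace", 2, 3))
            Q2 <- rand_orthogonal(3)
            X <- modeMultiply(OmicsTensor(S0), Q2, 2)
            f <- tWJADE(X, dims = "full")
            md_index(unmixingMatrices(f)[[2]] %*% Q2)
        }, numeric(1))
    }
    meds <- vapply(c(1000, 5000, 20000), function(p) median(md_at(p)),
                   numeric(1))
    expect_true(all(diff(meds) < 0))
    expect_lt(meds[3], 0.05)
})

test_that("components are ranked by decreasing max kurtosis", {
    set.seed(27)
    p <- 5000
    # component 3 given a heavy-tailed source, others Gaussian
    fam <- matrix("gaussian", 2, 3)
    fam[1, 3] <- "laplace"
    proj <- make_source_tensor(2, 3, p, fam)
    model <- make_fake_model(proj)
    tab <- rankComponents(model)
    expect_equal(tab$component[1], 3)
    expect_equal(nrow(tab), 6)  # one row per (mode-1 level, component)
    expect_false(is.unsorted(tab$rank))

    # all-equal kurtoses: stable natural order
    v <- array(rep(unit_source(p, "laplace"), each = 6), c(2, 3, p))
    m2 <- make_fake_model(v)
    expect_identical(m2@order, 1:3)

    # ordering is invariant to feature permutation
    perm <- sample(p)
    m3 <- make_fake_model(proj[, , perm])
    expect_identical(m3@order, model@order)
})

test_that("mode-1 back-projection applies the mixing matrix exactly", {
    set.seed(28)
    p <- 2000
    S0 <- make_source_tensor(2, 3, p, fobi_friendly_families())
    Q1 <- rand_orthogonal(2); Q2 <- rand_orthogonal(3)
    X <- modeMultiply(modeMultiply(OmicsTensor(S0), Q1, 1), Q2, 2)
    fit <- tWFOBI(X, dims = "full")
    proj <- projectMode1(fit)
    A1 <- mixingMatrices(fit)[[1]]
    want <- loop_mode_multiply(tensorValues(sourceTensor(fit)), A1, 1)
    expect_lt(max(abs(tensorValues(proj) - want)), 1e-10)

    # round trip: W1 (x)_1 proj recovers the source
    back <- modeMultiply(proj, unmixingMatrices(fit)[[1]], 1)
    expect_lt(max(abs(tensorValues(back) -
                      tensorValues(sourceTensor(fit)))), 1e-8)

    # identity mixing: projection equals the source
    fake <- make_fake_model(S0)
    expect_equal(tensorValues(projectMode1(fake)), unname(S0),
                 tolerance = 1e-12)
})
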