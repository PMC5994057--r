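# Independent oracles used across the suite: naive nested-loop tensor
# algebra, log-space enumeration of exact test tails, simple source
# generators and rotation-recovery metrics.

# Naive Einstein-summation contraction: out[.., a, ..] = sum_j Z[.., j, ..] A[a, j]
loop_mode_multiply <- function(Z, A, m) {
    d <- dim(Z)
    q <- nrow(A)
    nd <- d; nd[m] <- q
    out <- array(0, nd)
    for (i1 in seq_len(nd[1])) for (i2 in seq_len(nd[2]))
        for (i3 in seq_len(nd[3])) {
            s <- 0
            for (j in seq_len(d[m])) {
                idx <- c(i1, i2, i3)
                idx[m] <- j
                s <- s + Z[idx[1], idx[2], idx[3]] *
                    A[c(i1, i2, i3)[m], j]
            }
            out[i1, i2, i3] <- s
        }
    out
}

# Naive mode covariance: C[u,v] = sum over (other, i) X[..u..] X[..v..]
loop_mode_covariance <- function(X, m, normalize = FALSE) {
    d <- dim(X)
    pm <- d[m]
    po <- d[setdiff(1:2, m)]
    C <- matrix(0, pm, pm)
    for (u in seq_len(pm)) for (v in seq_len(pm))
        for (o in seq_len(po)) for (i in seq_len(d[3])) {
            iu <- if (m == 1) c(u, o, i) else c(o, u, i)
            iv <- if (m == 1) c(v, o, i) else c(o, v, i)
            C[u, v] <- C[u, v] + X[iu[1], iu[2], iu[3]] *
                X[iv[1], iv[2], iv[3]]
        }
    if (normalize) C <- C / (po * d[3])
    C
}

rand_orthogonal <- function(d, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    qr.Q(qr(matrix(rnorm(d * d), d)))
}

# Unit-variance zero-mean samples from named symmetric families with known
# excess kurtosis: uniform -1.2, triangular -0.6, logistic 1.2, laplace 3.
unit_source <- function(n, family) {
    switch(family,
        gaussian = rnorm(n),
        uniform = runif(n, -sqrt(3), sqrt(3)),
        triangular = (runif(n) - runif(n)) * sqrt(6),
        logistic = rlogis(n) * sqrt(3) / pi,
        laplace = {
            u <- runif(n) - 0.5
            -sign(u) * log1p(-2 * abs(u)) / sqrt(2)
        },
        stop("unknown family"))
}

# Source tensor whose slice (i,j) is drawn from families[i,j]; chosen so
# kurtosis row/column sums are distinct (the FOBI identifiability regime)
# when asked for.
make_source_tensor <- function(d1, d2, p, families) {
    S <- array(0, c(d1, d2, p))
    for (i in seq_len(d1)) for (j in seq_len(d2))
        S[i, j, ] <- unit_source(p, families[i, j])
    S
}

# Families grid with distinct kurtosis row and column sums (2 x 3).
fobi_friendly_families <- function() {
    matrix(c("laplace", "uniform", "logistic",
             "uniform", "triangular", "laplace"),
           2, 3, byrow = TRUE)
}

# Best |correlation| match of each recovered slice against any true slice.
match_correlations <- function(Shat, S0) {
    d <- dim(S0)
    p <- d[3]
    Sflat <- matrix(aperm(S0, c(3, 1, 2)), p)
    vapply(seq_len(d[1] * d[2]), function(k) {
        i <- (k - 1) %% d[1] + 1
        j <- (k - 1) %/% d[1] + 1
        max(abs(cor(Shat[i, j, ], Sflat)))
    }, numeric(1))
}

# Minimum-distance index of a gain matrix G = What %*% A: 0 iff G is a
# signed permutation (up to row scaling).  Exact minimisation over signed
# permutations (d small).
md_index <- function(G) {
    d <- nrow(G)
    G <- G / sqrt(rowSums(G^2))
    perms <- function(v) {
        if (length(v) == 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
        out
    }
    best <- Inf
    for (pm in perms(seq_len(d))) {
        # signed permutation P with P[i, pm[i]] = +/-1; optimal sign matches
        # the sign of G[i, pm[i]]
        err <- 0
        for (i in seq_len(d)) {
            row <- G[i, ]
            row[pm[i]] <- abs(row[pm[i]]) - 1
            err <- err + sum(row^2)
        }
        best <- min(best, err)
    }
    sqrt(best) / sqrt(d - 1)
}

# Log-space enumeration of the hypergeometric upper tail P(X >= a) for X ~
# Hypergeometric(N, K, n), summing exact lchoose terms.
hyper_tail_oracle <- function(a, K, N, n) {
    hi <- min(K, n)
    if (a > hi) return(0)
    lo <- max(0L, a)
    j <- lo:hi
    terms <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
    sum(exp(terms))
}

# Log-space enumeration of the binomial upper tail P(X >= x), X~Bin(k, q).
binom_tail_oracle <- function(x, k, q) {
    if (x <= 0) return(1)
    j <- x:k
    sum(exp(lchoose(k, j) + j * log(q) + (k - j) * log1p(-q)))
}

# Minimal TICAModel whose back-projection equals the supplied (p1 x d2 x p)
# weight array: identity mixing, used to test evaluation protocols in
# isolation from the fitting path.
make_fake_model <- function(proj) {
    d <- dim(proj)
    kt <- apply(proj, c(1, 2), tensorICA::excessKurtosis)
    kt <- matrix(kt, d[1], d[2])
    mx <- apply(kt, 2, max)
    new("TICAModel",
        unmixing = list(diag(d[1]), diag(d[2])),
        mixing = list(diag(d[1]), diag(d[2])),
        source = OmicsTensor(proj),
        kurtosis = kt, order = order(-mx, seq_along(mx)),
        offsets = matrix(0, d[1], d[2]), method = "fake")
}

make_fake_truth <- function(nGenes, jv1, jv2, nSamples = 10L) {
    v <- array(rnorm(2 * nSamples * nGenes), c(2, nSamples, nGenes))
    new("SimulatedDataset", tensor = OmicsTensor(v),
        jvGenes = list(as.integer(jv1), as.integer(jv2)),
        jvSamples = 1:2, ivGenes = list(integer(0), integer(0)),
        ivSamples = list(integer(0), integer(0)),
        config = list(), snr = 1)
}
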