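test_that("top-feature selection is deterministic and agrees with sorting", {
    expect_identical(selectTopFeatures(c(0, 3, -5, 1), 2), c(3L, 2L))
    w <- c(2, -2, 1)
    expect_identical(selectTopFeatures(w, 3), c(1L, 2L, 3L))  # tie by index
    set.seed(40)
    for (rep in 1:5) {
        w <- rnorm(50)
        k <- sample(50, 1)
        got <- selectTopFeatures(w, k)
        expect_identical(sort(abs(w)[got], decreasing = TRUE)[1],
                         max(abs(w)))
        expect_identical(abs(w)[got], sort(abs(w), decreasing = TRUE)[1:k])
    }
    expect_error(selectTopFeatures(w, 0), "must lie")
    expect_error(selectTopFeatures(w, 51), "must lie")
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
    uni <- paste0("f", 1:20)
    cat6 <- uni[1:6]
    sel <- uni[c(1, 2, 7, 8, 9, 10)]  # a=2, b=4, c=4, d=10
    er <- fisherEnrichment(sel, cat6, uni)
    expect_equal(er@counts[1, 1], 2L)
    expect_equal(er@pValue, hyper_tail_oracle(2, 6, 20, 6),
                 tolerance = 1e-12)
    expect_equal(er@oddsRatio, (2 * 10) / (4 * 4))

    # bc = 0: odds ratio +Inf
    er2 <- fisherEnrichment(uni[1:6], cat6, uni)
    expect_identical(er2@oddsRatio, Inf)
    # category = universe: p = 1, OR undefined and flagged
    er3 <- fisherEnrichment(sel, uni, uni)
    expect_equal(er3@pValue, 1)
    expect_true(is.na(er3@oddsRatio))
    expect_match(er3@note, "universe")

    expect_error(fisherEnrichment(c(sel, "zz"), cat6, uni), "subsets")
    expect_error(fisherEnrichment(sel, cat6, character(0)), "empty")
})

test_that("binomial enrichment is the exact upper tail", {
    expect_equal(binomialEnrichment(2, 2, 0.5), 0.25)
    expect_equal(binomialEnrichment(10, 0, 0.3), 1)
    expect_equal(binomialEnrichment(500, 60, 0.05),
                 binom_tail_oracle(60, 500, 0.05), tolerance = 1e-12)
    expect_error(binomialEnrichment(10, 2, 1.5), "strictly")
    expect_error(binomialEnrichment(10, 11, 0.5), "\\[0, k\\]")
})

test_that("SE(max)/SE(all) follow the enrichment-union protocol", {
    set.seed(41)
    p <- 1000
    ids <- paste0("f", 1:p)
    truth <- ids[1:62]
    # two components each capturing a disjoint half of the truth; the
    # deterministic background ramp keeps every other top-62 slot outside
    # the truth set, so the halves are exact
    ramp <- seq_len(p) / 1e6
    proj <- array(rep(ramp, each = 8), c(2, 4, p))
    proj[1, 1, 1:31] <- 10
    proj[1, 2, 32:62] <- 10
    model <- make_fake_model(proj)
    model@source@featureIDs <- ids
    sm <- sensitivityMeasures(model, truth, k = 62)
    expect_equal(sm$SEmax, 0.5)
    expect_equal(sm$SEall, 1.0)

    # single enriched component: SE(all) = SE(max)
    proj1 <- array(rep(ramp, each = 8), c(2, 4, p))
    proj1[2, 3, 1:62] <- 10
    m1 <- make_fake_model(proj1)
    m1@source@featureIDs <- ids
    sm1 <- sensitivityMeasures(m1, truth, k = 62)
    expect_equal(sm1$SEall, sm1$SEmax)
    expect_equal(sm1$SEmax, 1.0)

    # nothing enriched: SE(all) = 0 by convention, SE(max) still reported
    projn <- array(rnorm(2 * 4 * p, sd = 1), c(2, 4, p))
    mn <- make_fake_model(projn)
    mn@source@featureIDs <- ids
    smn <- sensitivityMeasures(mn, truth, k = 62)
    expect_identical(smn$SEall, 0)
    expect_gte(smn$SEmax, 0)
    expect_length(smn$enriched, 0)

    # SE(all) is monotone non-decreasing in the Bonferroni threshold
    alphas <- c(1e-6, 1e-3, 0.05, 0.5)
    seall <- vapply(alphas, function(a)
        sensitivityMeasures(model, truth, k = 62, alpha = a)$SEall,
        numeric(1))
    expect_false(is.unsorted(seall))

    expect_error(sensitivityMeasures(model, character(0)), "empty truth")
})

test_that("the 10%/50% quantile rule classifies specificity", {
    set.seed(42)
    p <- 500
    proj <- array(rnorm(3 * 2 * p), c(3, 2, p))
    # feature 1: at the max |weight| in all three levels -> independent
    proj[, 1, 1] <- 50
    # feature 2: max in level 1, below median in levels 2 and 3 -> specific
    proj[1, 1, 2] <- 40
    proj[2, 1, 2] <- 0
    proj[3, 1, 2] <- 0
    # feature 3: ~70th percentile everywhere -> unclassified
    for (t in 1:3) proj[t, 1, 3] <- quantile(abs(proj[t, 1, ]), 0.7)
    model <- make_fake_model(proj)
    calls <- classifySpecificity(model, paste0("f", 1:3), component = 1)
    expect_identical(as.character(calls),
                     c("independent", "specific", "unclassified"))

    # invariant to positive rescaling of any level's weights
    proj2 <- proj
    proj2[2, , ] <- proj2[2, , ] * 13.7
    m2 <- make_fake_model(proj2)
    expect_identical(as.character(classifySpecificity(m2, paste0("f", 1:3), 1)),
                     as.character(calls))

    # fewer than 2 mode-1 levels is an error
    m1 <- make_fake_model(array(rnorm(1 * 2 * p), c(1, 2, p)))
    expect_error(classifySpecificity(m1, "f1", 1), "fewer than 2")
})

test_that("iterative kurtosis selection strips the heavy tail and stops", {
    set.seed(43)
    # Gaussian weights: initial excess kurtosis < 1, empty selection
    w <- rnorm(10000)
    if (excessKurtosis(w) < 1)
        expect_length(iterativeKurtosisSelection(w), 0)

    # 10 planted outliers at |w| = 20: the outliers are removed first and
    # the recursion stops soon after the tail is gone
    lens <- vapply(1:20, function(s) {
        set.seed(100 + s)
        w <- rnorm(10000)
        idx <- sample(10000, 10)
        w[idx] <- 20 * sample(c(-1, 1), 10, replace = TRUE)
        sel <- iterativeKurtosisSelection(w)
        expect_true(all(idx %in% sel))
        length(sel)
    }, numeric(1))
    expect_true(all(lens >= 10 & lens <= 40))

    # selection returns features in removal (|weight|-descending) order
    w <- rnorm(1000)
    w[c(5, 500)] <- c(30, -40)
    sel <- iterativeKurtosisSelection(w, maxRemoved = 500)
    expect_identical(sel[1:2], c(500L, 5L))

    # a Cauchy-tailed vector never drops below the floor: cap honoured
    set.seed(44)
    wc <- rcauchy(5000)
    sel <- iterativeKurtosisSelection(wc, maxRemoved = 500)
    expect_length(sel, 500)

    expect_error(iterativeKurtosisSelection(rnorm(100), maxRemoved = 500),
                 "longer")
})

test_that("a planted 62-driver joint signature is recovered end to end", {
    # exposure-style signature: the same 62 genes driven in both data
    # types over a shared 20-sample block, at SNR 1.5
    semax <- vapply(1:5, function(s) {
        set.seed(500 + s)
        v <- array(rnorm(2 * 100 * 1000, 0, 2), c(2, 100, 1000))
        genes <- sample(1000, 62)
        samp <- sample(100, 20)
        for (t in 1:2) v[t, samp, genes] <- rnorm(20 * 62, 3, 2)
        X <- OmicsTensor(v)
        fit <- tWFOBI(X, dims = c(2, 6))
        sensitivityMeasures(fit, featureIDs(X)[genes], k = 62)$SEmax
    }, numeric(1))
    expect_gte(median(semax), 0.8)
})

test_that("phenotype association uses OLS and exact Wilcoxon", {
    set.seed(45)
    # mixing column equal to the phenotype: essentially zero p
    ph <- rnorm(30)
    r <- associatePhenotype(ph, ph)
    expect_lt(r$p.value, 1e-12)
    expect_identical(r$test, "ols-t")

    # complete separation of two groups of 3: exact two-sided p = 0.1
    g <- factor(rep(c("a", "b"), each = 3))
    r2 <- associatePhenotype(c(1, 2, 3, 4, 5, 6), g)
    expect_identical(r2$test, "wilcoxon")
    expect_equal(r2$p.value, 0.1, tolerance = 1e-12)

    # permutation null: p-values uniform on (0,1)
    x <- rnorm(40)
    y <- rnorm(40)
    ps <- replicate(500, associatePhenotype(x, sample(y))$p.value)
    expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)

    # Bonferroni divisor controls the significance flag
    r3 <- associatePhenotype(ph + rnorm(30, sd = 2), ph, bonferroni = 1000)
    expect_false(r3$significant && r3$p.value > 0.05 / 1000)

    expect_error(associatePhenotype(ph, rep(1, 30)), "constant")
})
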