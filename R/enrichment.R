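## Downstream inference on fitted components: feature selection, enrichment
## statistics, sensitivity measures, cell-type-specificity calls and
## phenotype association.

#' Select the top features of a weight vector
#'
#' Indices of the \code{k} largest absolute weights, ordered by decreasing
#' |weight|; ties are broken by the smaller index, so the result is
#' deterministic.
#'
#' @param weights numeric vector (component weights over features).
#' @param k number of features to select, 1 <= k <= length(weights).
#' @return integer vector of length \code{k}.
#' @export
selectTopFeatures <- function(weights, k) {
    p <- length(weights)
    if (!(length(k) == 1L && k >= 1L && k <= p))
        stop(sprintf("'k' must lie in [1, %d]", p))
    order(-abs(weights), seq_len(p))[seq_len(k)]
}

#' Fisher (hypergeometric) enrichment of a selection in a category
#'
#' One-tailed test of over-representation of \code{category} among
#' \code{selected} within \code{universe}: p = P(overlap >= observed) under
#' the hypergeometric null, odds ratio = ad/bc from the 2x2 table (+Inf
#' when bc = 0).
#'
#' @param selected,category,universe vectors of feature ids (selected and
#'   category must be subsets of universe).
#' @param componentID optional component label carried into the result.
#' @return an \linkS4class{EnrichmentResult}.
#' @export
fisherEnrichment <- function(selected, category, universe,
                             componentID = "") {
    selected <- unique(selected); category <- unique(category)
    universe <- unique(universe)
    if (length(universe) == 0L) stop("empty universe")
    if (length(setdiff(selected, universe)) ||
        length(setdiff(category, universe)))
        stop("'selected' and 'category' must be subsets of 'universe'")
    N <- length(universe)
    K <- length(category)
    n <- length(selected)
    a <- length(intersect(selected, category))
    b <- K - a            # in category, not selected
    cc <- n - a           # selected, not in category
    d <- N - K - cc       # neither
    p <- stats::phyper(a - 1L, K, N - K, n, lower.tail = FALSE)
    note <- ""
    if (K == N) {
        or <- NA_real_
        note <- "category equals universe; odds ratio undefined"
    } else if (b * cc == 0) {
        or <- if (a * d == 0) NA_real_ else Inf
        if (is.na(or)) note <- "degenerate 2x2 table; odds ratio undefined"
    } else {
        or <- (a * d) / (b * cc)
    }
    counts <- matrix(as.integer(c(a, b, cc, d)), 2L, 2L,
                     dimnames = list(selected = c("yes", "no"),
                                     category = c("yes", "no")))
    new("EnrichmentResult", counts = counts, oddsRatio = or,
        pValue = min(1, max(p, .Machine$double.xmin)), test = "fisher",
        componentID = as.character(componentID),
        selectedIDs = as.character(selected), note = note)
}

#' Binomial enrichment tail probability
#'
#' P(X >= x) for X ~ Binomial(k, q): the chance of observing at least
#' \code{x} category members among \code{k} selected features when the
#' category occupies fraction \code{q} of the universe.
#'
#' @param k number of selected features.
#' @param x observed hits, 0 <= x <= k.
#' @param q category fraction, in (0, 1).
#' @return one-tailed p-value.
#' @export
binomialEnrichment <- function(k, x, q) {
    if (!(length(q) == 1L && q > 0 && q < 1))
        stop("'q' must lie strictly in (0, 1)")
    if (!(length(x) == 1L && x >= 0 && x <= k))
        stop("'x' must lie in [0, k]")
    stats::pbinom(x - 1, k, q, lower.tail = FALSE)
}

#' SE(max) and SE(all) sensitivity of a model for a truth set
#'
#' Back-projects the model onto the original data-type axes and, for every
#' (data type, mode-2 component) weight vector, selects the top-\code{k}
#' features by absolute weight (k matched to the truth-set size by
#' default) and computes the sensitivity for the truth set.  SE(max) is
#' the best single-component sensitivity.  A component is called enriched
#' when its binomial enrichment p-value is below the Bonferroni-corrected
#' threshold alpha / (number of weight vectors tested), and SE(all) is the
#' sensitivity of the union of selections over all enriched components
#' (0 when none is enriched).
#'
#' @param model a fitted \linkS4class{TICAModel} (mode 1 unreduced).
#' @param truth character vector of true-positive feature ids (subset of
#'   the tensor's features).
#' @param k features selected per weight vector (default \code{length(truth)}).
#' @param alpha nominal significance level before Bonferroni (default 0.05).
#' @return list with \code{SEmax}, \code{SEall}, \code{enriched} (indices
#'   into the table) and \code{table} (per (type, component) row: hits, SE,
#'   binomial p, enriched flag).
#' @export
sensitivityMeasures <- function(model, truth, k = length(truth),
                                alpha = 0.05) {
    if (length(truth) == 0L) stop("empty truth set")
    proj <- projectMode1(model)
    ids <- featureIDs(proj)
    truth <- unique(as.character(truth))
    if (length(setdiff(truth, ids)))
        stop("truth set contains ids absent from the tensor features")
    d <- dim(proj@values)
    p <- d[3L]
    q <- length(truth) / p
    nTest <- d[1L] * d[2L]
    tab <- expand.grid(mode1 = seq_len(d[1L]), component = seq_len(d[2L]))
    tab$hits <- NA_integer_; tab$SE <- NA_real_; tab$p <- NA_real_
    sel <- vector("list", nrow(tab))
    for (r in seq_len(nrow(tab))) {
        t <- tab$mode1[r]; j <- tab$component[r]
        idx <- selectTopFeatures(proj@values[t, j, ], k)
        sel[[r]] <- ids[idx]
        tab$hits[r] <- length(intersect(sel[[r]], truth))
        tab$SE[r] <- tab$hits[r] / length(truth)
        tab$p[r] <- binomialEnrichment(k, tab$hits[r], q)
    }
    tab$enriched <- tab$p < alpha / nTest
    SEmax <- max(tab$SE)
    enriched <- which(tab$enriched)
    SEall <- if (length(enriched) == 0L) 0 else
        length(intersect(unique(unlist(sel[enriched])), truth)) /
            length(truth)
    list(SEmax = SEmax, SEall = SEall, enriched = enriched, table = tab)
}

#' Cell-type specificity calls for features of one component
#'
#' Back-projects the model onto the original mode-1 (cell/tissue type)
#' axes and, for each requested feature, compares its absolute weight in
#' the chosen component against the per-type weight distribution:
#' \emph{independent} if within the top 10% quantile (>= 90th percentile)
#' for all types; \emph{specific} if below the median for exactly one or
#' two types while in the top decile of at least one; otherwise
#' \emph{unclassified}.  Quantiles use linear interpolation
#' (\code{stats::quantile} type 7).
#'
#' @param model a fitted \linkS4class{TICAModel} with at least two mode-1
#'   levels.
#' @param features character vector of feature ids to classify.
#' @param component mode-2 component index.
#' @return named factor with levels independent/specific/unclassified.
#' @export
classifySpecificity <- function(model, features, component) {
    proj <- projectMode1(model)
    d <- dim(proj@values)
    if (d[1L] < 2L)
        stop("specificity is undefined with fewer than 2 mode-1 levels")
    if (!(component %in% seq_len(d[2L])))
        stop("invalid component index")
    ids <- featureIDs(proj)
    features <- as.character(features)
    if (length(setdiff(features, ids)))
        stop("unknown feature ids")
    W <- abs(matrix(proj@values[, component, ], d[1L], d[3L]))
    q90 <- apply(W, 1L, stats::quantile, probs = 0.9, type = 7)
    med <- apply(W, 1L, stats::quantile, probs = 0.5, type = 7)
    idx <- match(features, ids)
    calls <- vapply(idx, function(i) {
        top <- W[, i] >= q90
        low <- W[, i] < med
        if (all(top)) return("independent")
        if (sum(low) %in% 1:2 && any(top)) return("specific")
        "unclassified"
    }, character(1))
    factor(stats::setNames(calls, features),
           levels = c("independent", "specific", "unclassified"))
}

#' Iterative kurtosis-thresholded feature selection
#'
#' Recursively removes the current largest-|weight| feature, recomputing
#' the excess kurtosis of the remaining weights, until the kurtosis drops
#' below \code{kurtFloor} or \code{maxRemoved} features have been removed.
#' The removed features — the ones driving the heavy tail of the component
#' — are returned in removal order.  An initial kurtosis below the floor
#' yields an empty selection.
#'
#' @param weights numeric weight vector, length > \code{maxRemoved}.
#' @param kurtFloor stop once excess kurtosis falls below this (default 1).
#' @param maxRemoved cap on the number of removed features (default 500).
#' @return integer vector of selected (removed) feature indices, possibly
#'   empty.
#' @export
iterativeKurtosisSelection <- function(weights, kurtFloor = 1,
                                       maxRemoved = 500L) {
    p <- length(weights)
    if (p <= maxRemoved)
        stop("'weights' must be longer than 'maxRemoved'")
    ord <- order(-abs(weights), seq_len(p))
    ## raw power sums of the full vector; removing a feature updates them
    s1 <- sum(weights); s2 <- sum(weights^2)
    s3 <- sum(weights^3); s4 <- sum(weights^4)
    n <- p
    kurt <- function() {
        m <- s1 / n
        m2 <- s2 / n - m^2
        if (m2 <= 0) return(-Inf)
        m4 <- (s4 - 4 * m * s3 + 6 * m^2 * s2 - 3 * n * m^4) / n
        m4 / m2^2 - 3
    }
    removed <- integer(0)
    for (r in seq_len(maxRemoved)) {
        if (kurt() < kurtFloor) break
        i <- ord[r]
        w <- weights[i]
        s1 <- s1 - w; s2 <- s2 - w^2; s3 <- s3 - w^3; s4 <- s4 - w^4
        n <- n - 1L
        removed <- c(removed, i)
    }
    removed
}

#' Associate a sample-mode component with a phenotype
#'
#' Tests one column of the sample-mode mixing matrix against a phenotype:
#' continuous/ordinal phenotypes by the two-sided t-test on the ordinary
#' least squares slope, two-group phenotypes by the two-sided Wilcoxon
#' rank sum test (exact when the smaller group has <= 20 samples, normal
#' approximation with tie correction otherwise).
#'
#' @param mixingColumn numeric vector (one column of the mode-2 mixing
#'   matrix; one value per sample).
#' @param phenotype numeric (continuous/ordinal) or factor/character/
#'   logical (two-group), same length.
#' @param type \code{"auto"} (default), \code{"continuous"} or
#'   \code{"two-group"}.
#' @param bonferroni divisor for the significance flag (number of
#'   components tested; default 1).
#' @param alpha nominal level (default 0.05).
#' @return list with \code{statistic}, \code{p.value}, \code{test} and
#'   \code{significant} (p < alpha/bonferroni).
#' @export
associatePhenotype <- function(mixingColumn, phenotype,
                               type = c("auto", "continuous", "two-group"),
                               bonferroni = 1, alpha = 0.05) {
    type <- match.arg(type)
    x <- as.numeric(mixingColumn)
    if (length(x) != length(phenotype))
        stop("phenotype length must match the mixing column")
    if (length(unique(phenotype)) < 2L)
        stop("constant phenotype")
    if (type == "auto")
        type <- if (is.numeric(phenotype) &&
                    length(unique(phenotype)) > 2L) "continuous"
                else if (is.numeric(phenotype)) "two-group"
                else "two-group"
    if (type == "continuous") {
        ph <- as.numeric(phenotype)
        fit <- stats::lm(x ~ ph)
        ## summary() warns on a perfect fit; that case is handled below
        cf <- suppressWarnings(summary(fit))$coefficients
        tval <- cf["ph", "t value"]
        pval <- cf["ph", "Pr(>|t|)"]
        if (!is.finite(pval)) {
            ## perfect linear fit: zero residual variance
            pval <- 0
            tval <- Inf
        }
        res <- list(statistic = tval, p.value = pval, test = "ols-t")
    } else {
        g <- factor(phenotype)
        if (nlevels(g) != 2L)
            stop("two-group test requires exactly 2 phenotype levels")
        n1 <- min(table(g))
        wt <- suppressWarnings(
            stats::wilcox.test(x ~ g, exact = n1 <= 20L, correct = TRUE))
        res <- list(statistic = unname(wt$statistic), p.value = wt$p.value,
                    test = "wilcoxon")
    }
    res$significant <- res$p.value < alpha / bonferroni
    res
}
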