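## Generative model for two-omic tensors with joint and individual
## variation, the sensitivity/specificity evaluation protocol and the Monte
## Carlo benchmark harness.

#' Simulation configuration
#'
#' Parameters of the two-omic generative model: two feature x sample data
#' matrices share one source of joint variation (JV) driven by a common
#' sample set but distinct gene sets, and each carries one source of
#' individual variation (IV) with genes and samples unique to that matrix.
#' Signal blocks are drawn from distribution(mean = +/-e, sd = sigma) and
#' the background from distribution(mean = 0, sd = sigma), so the
#' signal-to-noise ratio is e/sigma.
#'
#' @param nGenes,nSamples matrix dimensions (defaults 1000 x 100).
#' @param e effect size (default 3).
#' @param sigma noise standard deviation (default 1; benchmarks sweep a
#'   grid).
#' @param ivGenes,ivSamples drivers of individual variation per type
#'   (defaults 50 genes, 10 samples).
#' @param jvSamples samples driving joint variation, shared between types
#'   (default 20).
#' @param jvGenesPerType genes driving joint variation in each type
#'   (default 50; the per-type sets are disjoint, 100 genes in total).
#' @param distribution \code{"gaussian"} or \code{"laplace"} (same mean and
#'   standard deviation; Laplace scale b = sigma/sqrt(2)).
#' @param seed integer RNG seed.
#' @param allowOverlap allow IV gene/sample sets to overlap the JV sets
#'   (default FALSE: drawn disjoint, giving clean truth labels).
#' @return a named list (validated by \code{\link{simulateMultiOmic}}).
#' @export
simConfig <- function(nGenes = 1000L, nSamples = 100L, e = 3, sigma = 1,
                      ivGenes = 50L, ivSamples = 10L, jvSamples = 20L,
                      jvGenesPerType = 50L,
                      distribution = c("gaussian", "laplace"),
                      seed = 1L, allowOverlap = FALSE) {
    list(nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
         e = e, sigma = sigma, ivGenes = as.integer(ivGenes),
         ivSamples = as.integer(ivSamples), jvSamples = as.integer(jvSamples),
         jvGenesPerType = as.integer(jvGenesPerType),
         distribution = match.arg(distribution), seed = as.integer(seed),
         allowOverlap = isTRUE(allowOverlap))
}

## Laplace with given mean and standard deviation (scale b = sd/sqrt(2)),
## by inverse-CDF on a single runif stream (keeps the draw order stable).
.rdist <- function(n, mean, sd, distribution) {
    if (distribution == "gaussian") return(stats::rnorm(n, mean, sd))
    u <- stats::runif(n) - 0.5
    mean - (sd / sqrt(2)) * sign(u) * log1p(-2 * abs(u))
}

.checkConfig <- function(cfg) {
    with(cfg, {
        if (sigma <= 0) stop("sigma must be > 0")
        if (jvGenesPerType < 1L || ivGenes < 0L)
            stop("gene counts must be positive")
        needG <- 2L * jvGenesPerType + (if (allowOverlap) 0L else 2L * ivGenes)
        needS <- if (allowOverlap) max(jvSamples, ivSamples)
                 else jvSamples + 2L * ivSamples
        if (needG > nGenes)
            stop("unsatisfiable disjointness: joint + individual gene sets exceed nGenes")
        if (needS > nSamples)
            stop("unsatisfiable disjointness: joint + individual sample sets exceed nSamples")
    })
    invisible(cfg)
}

#' Simulate a two-omic tensor with joint and individual variation
#'
#' Generates two feature x sample data matrices and stacks them into a
#' (2 x nSamples x nGenes) \linkS4class{OmicsTensor}.  The JV block of
#' type 1 is drawn from distribution(+e, sigma), the JV block of type 2
#' from distribution(-e, sigma), the per-type IV blocks from
#' distribution(+e, sigma), and the background from distribution(0, sigma);
#' signal blocks replace the background.  Index sets are drawn uniformly
#' without replacement subject to the disjointness constraints; a fixed
#' seed yields bit-identical output.
#'
#' Draw order (one base-R Mersenne-Twister stream seeded with
#' \code{cfg$seed}): JV genes type 1, JV genes type 2, IV genes type 1, IV
#' genes type 2, JV samples, IV samples type 1, IV samples type 2, then the
#' two background matrices (type 1 then type 2, column-major), then the JV
#' and IV signal blocks in that order.
#'
#' @param cfg a configuration from \code{\link{simConfig}}.
#' @return a \linkS4class{SimulatedDataset}.
#' @examples
#' sim <- simulateMultiOmic(simConfig(seed = 1))
#' dim(simTensor(sim))
#' @export
simulateMultiOmic <- function(cfg = simConfig()) {
    .checkConfig(cfg)
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(cfg$seed)

    gPool <- seq_len(cfg$nGenes)
    jvG1 <- sort(sample(gPool, cfg$jvGenesPerType))
    jvG2 <- sort(sample(setdiff(gPool, jvG1), cfg$jvGenesPerType))
    ivPool <- if (cfg$allowOverlap) gPool else setdiff(gPool, c(jvG1, jvG2))
    ivG1 <- sort(sample(ivPool, cfg$ivGenes))
    ivG2 <- sort(sample(if (cfg$allowOverlap) gPool else setdiff(ivPool, ivG1),
                        cfg$ivGenes))
    sPool <- seq_len(cfg$nSamples)
    jvS <- sort(sample(sPool, cfg$jvSamples))
    ivSPool <- if (cfg$allowOverlap) sPool else setdiff(sPool, jvS)
    ivS1 <- sort(sample(ivSPool, cfg$ivSamples))
    ivS2 <- sort(sample(if (cfg$allowOverlap) sPool
                        else setdiff(ivSPool, ivS1), cfg$ivSamples))

    mats <- lapply(1:2, function(t)
        matrix(.rdist(cfg$nGenes * cfg$nSamples, 0, cfg$sigma,
                      cfg$distribution),
               cfg$nGenes, cfg$nSamples))
    jvMean <- c(cfg$e, -cfg$e)
    jvGenes <- list(jvG1, jvG2)
    for (t in 1:2)
        mats[[t]][jvGenes[[t]], jvS] <-
            .rdist(length(jvGenes[[t]]) * length(jvS), jvMean[t], cfg$sigma,
                   cfg$distribution)
    ivGenes <- list(ivG1, ivG2)
    ivSamples <- list(ivS1, ivS2)
    for (t in 1:2)
        mats[[t]][ivGenes[[t]], ivSamples[[t]]] <-
            .rdist(length(ivGenes[[t]]) * length(ivSamples[[t]]), cfg$e,
                   cfg$sigma, cfg$distribution)

    v <- array(0, c(2L, cfg$nSamples, cfg$nGenes))
    for (t in 1:2) v[t, , ] <- t(mats[[t]])
    tensor <- OmicsTensor(v, c("type1", "type2"),
                          paste0("s", seq_len(cfg$nSamples)),
                          paste0("g", seq_len(cfg$nGenes)))
    new("SimulatedDataset", tensor = tensor, jvGenes = jvGenes,
        jvSamples = jvS, ivGenes = ivGenes, ivSamples = ivSamples,
        config = cfg, snr = cfg$e / cfg$sigma)
}

#' Sensitivity and specificity of a fitted model on simulated data
#'
#' Back-projects the fitted sources onto the original data-type axes, then,
#' for every (data type, mode-2 component), selects the top-\code{k}
#' features by absolute weight and scores them against that type's true
#' joint-variation genes: SE = fraction of true drivers recovered, SP =
#' true-negative rate over the remaining genes.  SE and SP are averaged
#' over the two data types per component, and the component with the
#' largest SE is reported (ties broken by SP, then component index).
#'
#' @param model a fitted \linkS4class{TICAModel} (mode 1 unreduced).
#' @param truth the \linkS4class{SimulatedDataset} the model was fitted on.
#' @param k features selected per (type, component); default 50, matching
#'   the number of true drivers per type.
#' @return list with elements \code{SE}, \code{SP}, \code{component} (the
#'   selected mode-2 component) and \code{table} (per-component averaged SE
#'   and SP).
#' @export
evaluateSESP <- function(model, truth, k = 50L) {
    stopifnot(is(truth, "SimulatedDataset"))
    proj <- projectMode1(model)
    d <- dim(proj@values)
    p <- d[3L]
    if (k > p) stop("'k' exceeds the number of genes")
    se <- matrix(0, d[1L], d[2L])
    sp <- matrix(0, d[1L], d[2L])
    for (t in seq_len(d[1L])) {
        tp <- truth@jvGenes[[t]]
        nNeg <- p - length(tp)
        for (j in seq_len(d[2L])) {
            sel <- selectTopFeatures(proj@values[t, j, ], k)
            hits <- length(intersect(sel, tp))
            se[t, j] <- hits / length(tp)
            fp <- k - hits
            sp[t, j] <- (nNeg - fp) / nNeg
        }
    }
    SE <- colMeans(se)
    SP <- colMeans(sp)
    best <- order(-SE, -SP, seq_along(SE))[1L]
    list(SE = SE[best], SP = SP[best], component = best,
         table = data.frame(component = seq_along(SE), SE = SE, SP = SP))
}

#' Built-in decomposition adapters for the benchmark
#'
#' Maps method names to adapter functions OmicsTensor -> TICAModel.
#' External methods can be plugged in by passing named functions with the
#' same signature to \code{\link{runBenchmark}}.
#'
#' @param methods character vector among \code{"tWFOBI"}, \code{"tWJADE"}.
#' @param dims dims policy passed to the fitting functions (default
#'   \code{c(2, 6)}: the two data types and six sample-space components,
#'   i.e. 12 components over the combined modes).
#' @return named list of adapter functions.
#' @export
benchmarkAdapters <- function(methods = c("tWFOBI", "tWJADE"),
                              dims = c(2L, 6L)) {
    fns <- list(tWFOBI = function(X) tWFOBI(X, dims = dims),
                tWJADE = function(X) tWJADE(X, dims = dims))
    unknown <- setdiff(methods, names(fns))
    if (length(unknown))
        stop("no built-in adapter for: ", paste(unknown, collapse = ", "),
             "; pass a named function instead")
    fns[methods]
}

#' Monte Carlo benchmark over a noise-level grid
#'
#' For each noise level sigma and each of \code{nRuns} Monte Carlo runs,
#' simulates a dataset (run r uses seed \code{seed + r}, so every method
#' sees identical data; the same underlying normal deviates are reused
#' across sigma levels as common random numbers), fits each method and
#' records the SE/SP of \code{\link{evaluateSESP}}.  Adapter failures are
#' recorded as NA with a warning and excluded pairwise downstream.
#'
#' @param methods named list of adapter functions (OmicsTensor ->
#'   TICAModel), or a character vector resolved by
#'   \code{\link{benchmarkAdapters}}.
#' @param sigmas numeric vector of noise levels.
#' @param nRuns Monte Carlo runs per level.
#' @param seed integer base seed.
#' @param config base configuration from \code{\link{simConfig}}; its
#'   \code{sigma} and \code{seed} are overridden per run.
#' @param k features selected per (type, component).
#' @return a \linkS4class{BenchmarkResult}.
#' @export
runBenchmark <- function(methods = c("tWFOBI", "tWJADE"),
                         sigmas = seq(1, 5, by = 0.5), nRuns = 50L,
                         seed = 1L, config = simConfig(), k = 50L) {
    if (is.character(methods)) methods <- benchmarkAdapters(methods)
    stopifnot(is.list(methods), !is.null(names(methods)))
    rows <- vector("list", 0L)
    for (sg in sigmas) {
        for (r in seq_len(nRuns)) {
            cfg <- config
            cfg$sigma <- sg
            cfg$seed <- as.integer(seed + r)
            sim <- simulateMultiOmic(cfg)
            for (nm in names(methods)) {
                res <- tryCatch({
                    fit <- methods[[nm]](sim@tensor)
                    ev <- evaluateSESP(fit, sim, k = k)
                    list(SE = ev$SE, SP = ev$SP, comp = ev$component)
                }, error = function(e) {
                    warning(sprintf("method '%s' failed at sigma=%g run %d: %s",
                                    nm, sg, r, conditionMessage(e)))
                    list(SE = NA_real_, SP = NA_real_, comp = NA_integer_)
                })
                rows[[length(rows) + 1L]] <-
                    data.frame(method = nm, sigma = sg, run = r,
                               SE = res$SE, SP = res$SP,
                               component = res$comp)
            }
        }
    }
    runs <- if (length(rows)) do.call(rbind, rows)
            else data.frame(method = character(), sigma = numeric(),
                            run = integer(), SE = numeric(), SP = numeric(),
                            component = integer())
    summ <- if (nrow(runs)) {
        agg <- aggregate(cbind(SE, SP) ~ method + sigma, data = runs,
                         FUN = function(x) mean(x, na.rm = TRUE),
                         na.action = stats::na.pass)
        names(agg)[3:4] <- c("meanSE", "meanSP")
        agg$nRuns <- aggregate(run ~ method + sigma, data = runs,
                               FUN = length)$run
        agg[order(agg$method, agg$sigma), , drop = FALSE]
    } else data.frame(method = character(), sigma = numeric(),
                      meanSE = numeric(), meanSP = numeric(),
                      nRuns = integer())
    new("BenchmarkResult", runs = runs, summary = summ,
        seed = as.integer(seed))
}

#' Pairwise paired Wilcoxon comparison of benchmarked methods
#'
#' One-tailed paired Wilcoxon signed-rank test for every ordered method
#' pair at one noise level: entry (A, B) tests the alternative that
#' method A's per-run metric exceeds method B's.  Exact distribution for
#' up to 25 pairs (without ties/zeros), normal approximation with tie
#' correction otherwise.
#'
#' @param result a \linkS4class{BenchmarkResult}.
#' @param metric \code{"SE"} or \code{"SP"}.
#' @param sigma which noise level to compare at.
#' @param selfNA report NA (instead of 1) on the diagonal.
#' @return square matrix of one-tailed p-values.
#' @export
compareMethods <- function(result, metric = c("SE", "SP"), sigma,
                           selfNA = FALSE) {
    stopifnot(is(result, "BenchmarkResult"))
    metric <- match.arg(metric)
    runs <- result@runs[result@runs$sigma == sigma, , drop = FALSE]
    meths <- unique(runs$method)
    if (length(meths) < 2L) stop("need at least 2 methods to compare")
    wide <- stats::reshape(runs[, c("method", "run", metric)],
                           idvar = "run", timevar = "method",
                           direction = "wide")
    vals <- as.matrix(wide[, paste0(metric, ".", meths), drop = FALSE])
    P <- matrix(NA_real_, length(meths), length(meths),
                dimnames = list(meths, meths))
    for (a in seq_along(meths)) for (b in seq_along(meths)) {
        if (a == b) {
            P[a, b] <- if (selfNA) NA_real_ else 1
            next
        }
        ok <- stats::complete.cases(vals[, c(a, b)])
        x <- vals[ok, a]; y <- vals[ok, b]
        if (sum(ok) < 6L)
            stop("fewer than 6 complete paired runs for ",
                 meths[a], " vs ", meths[b])
        if (all(x == y)) {
            warning("all paired differences are zero for ", meths[a],
                    " vs ", meths[b], "; p = 1 reported")
            P[a, b] <- 1
            next
        }
        P[a, b] <- suppressWarnings(
            stats::wilcox.test(x, y, paired = TRUE,
                               alternative = "greater",
                               exact = sum(ok) <= 25L,
                               correct = TRUE)$p.value)
    }
    P
}
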