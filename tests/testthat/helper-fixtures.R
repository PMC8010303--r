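## Shared fixtures and independent oracles for the test suite.

## small two-block generator config (no missingness, no outliers)
twoBlockConfig <- function(seed, blockSize = 20L, nNoise = 0L, wcor = 0.8,
                           nSubjects = 50L) {
    syntheticConfig(nProteins = 2L * blockSize + nNoise,
                    moduleSizes = c(blockSize, blockSize),
                    withinModuleCor = wcor,
                    groupSizes = c(A = nSubjects), seed = seed)
}

logValues <- function(sim) log(abundanceValues(sim$abundance))

## definitional BH step-up: q_(i) = min_{j>=i} p_(j) * m / j, input order
bhBrute <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- vapply(seq_len(m), function(i) min(1, min(ps[i:m] * m / (i:m))), 0)
    out <- numeric(m)
    out[o] <- q
    out
}

## hypergeometric upper tail by direct enumeration of binomial coefficients
hyperTailBrute <- function(N, K, n, a) {
    ks <- a:min(K, n)
    ks <- ks[ks >= max(0L, n - (N - K))]
    if (!length(ks)) return(0)
    sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

## adjusted Rand index between two labelings (mclust is the oracle where
## installed; this mirrors its definition for standalone use)
ari <- function(a, b) {
    tab <- table(a, b)
    sumij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2))
    bj <- sum(choose(colSums(tab), 2))
    n2 <- choose(sum(tab), 2)
    expected <- ai * bj / n2
    (sumij - expected) / ((ai + bj) / 2 - expected)
}

## run the study fixture through the default preprocessing + network chain;
## memoised across test files (several acceptance checks share these runs)
.fixtureCache <- new.env(parent = emptyenv())
fixtureRun <- function(seed) {
    key <- as.character(seed)
    if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
    sim <- defaultStudyFixture(seed = seed)
    pa <- logTransform(sim$abundance)
    flt <- filterMissingByGroup(pa)
    nrm <- normalizeAbundance(flt$abundance, selectBackground(flt$abundance))
    info <- sim$sampleInfo
    baseline <- nrm$abundance[, colnames(nrm$abundance) %in%
                                   info$sample_id[info$visit == 1L]]
    net <- buildNetwork(baseline, networkConfig())
    res <- list(sim = sim, normalized = nrm$abundance, baseline = baseline,
                net = net,
                baselineGroups = info$group[match(sampleIds(baseline),
                                                  info$sample_id)],
                normReport = nrm$report,
                background = selectBackground(flt$abundance))
    .fixtureCache[[key]] <- res
    res
}
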