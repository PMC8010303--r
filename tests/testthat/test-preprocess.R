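makePA <- function(m, scale = "log") {
    if (is.null(rownames(m))) rownames(m) <- sprintf("P%02d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
    ProteinAbundance(m, scale = scale)
}

test_that("log transform is exact, guards positivity and preserves missingness", {
    m <- matrix(c(exp(1), 2, NA, 8), 2, 2)
    pa <- makePA(m, "linear")
    lg <- logTransform(pa)
    expect_equal(abundanceValues(lg)[1, 1], 1.0)
    expect_identical(abundanceScale(lg), "log")
    expect_identical(is.na(abundanceValues(lg)), is.na(abundanceValues(pa)))
    expect_equal(exp(abundanceValues(lg)), abundanceValues(pa))
    ## zero slipped past construction must still be caught
    assay(pa, "abundance")[2, 1] <- 0
    expect_error(logTransform(pa), "non-positive")
    expect_error(logTransform(lg), "linear-scale")
})

test_that("missingness filter removes proteins strictly over the per-group threshold", {
    set.seed(1)
    m <- matrix(rnorm(3 * 30), 3, 30,
                dimnames = list(c("Pa", "Pb", "Pc"), sprintf("S%02d", 1:30)))
    groups <- rep(c("G1", "G2"), c(20, 10))
    m["Pa", 1:13] <- NA            # 13/20 = 0.65 in G1 -> removed
    m["Pb", 1:10] <- NA            # exactly 10/20 = 0.50 -> retained
    res <- filterMissingByGroup(makePA(m), groups)
    expect_identical(proteinIds(res$abundance), c("Pb", "Pc"))
    expect_equal(res$report$protein_id, "Pa")
    expect_equal(res$report$missing_frac, 0.65)
    expect_identical(res$report$worst_group, "G1")
})

test_that("background selection takes floor(frac*P) lowest-variance proteins with id tie-break", {
    set.seed(2)
    m <- matrix(rnorm(10 * 8), 10, 8)
    m <- m * (1:10)                               # increasing variance
    rownames(m) <- sprintf("P%02d", 1:10); colnames(m) <- paste0("S", 1:8)
    bg <- selectBackground(makePA(m), frac = 0.9)
    expect_length(bg, 9L)
    ## constant protein has minimal variance
    m[10, ] <- 3
    rownames(m)[10] <- "Pzz"
    expect_true("Pzz" %in% selectBackground(makePA(m), frac = 0.5))
    ## exact tie at the cutoff: lexicographically smaller id wins
    m2 <- rbind(P01 = c(1, 2, 3, 4),              # smallest variance
                P02 = c(1, 3, 5, 7),              # middle variance
                Pb_tie = c(2, 5, 8, 11),          # tied pair spans the cutoff
                Pa_tie = c(2, 5, 8, 11))
    colnames(m2) <- paste0("S", 1:4)
    bg2 <- selectBackground(makePA(m2), frac = 0.75)   # 3 of 4
    expect_setequal(bg2, c("P01", "P02", "Pa_tie"))
})

test_that("normalization centers to background median and scales by unscaled MAD", {
    m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("P", 1:3), "S1"))
    res <- normalizeAbundance(makePA(m), background = paste0("P", 1:3))
    expect_equal(unname(abundanceValues(res$abundance)[, 1]), c(-1, 0, 1))
    expect_equal(res$report$offset, 2)
    expect_equal(res$report$scale_factor, 1)
})

test_that("normalization post-conditions hold exactly and the map is idempotent", {
    set.seed(3)
    m <- matrix(rnorm(40 * 6, 5), 40, 6,
                dimnames = list(sprintf("P%02d", 1:40), sprintf("S%02d", 1:6)))
    m[sample(length(m), 15)] <- NA
    pa <- makePA(m)
    bg <- selectBackground(pa)
    res <- normalizeAbundance(pa, bg)
    v <- abundanceValues(res$abundance)[bg, ]
    meds <- apply(v, 2, median, na.rm = TRUE)
    mads <- vapply(seq_len(ncol(v)), function(j)
        median(abs(v[, j] - meds[j]), na.rm = TRUE), 0)
    expect_equal(unname(meds), rep(0, 6), tolerance = 1e-12)
    expect_equal(mads, rep(1, 6), tolerance = 1e-12)
    ## missingness untouched
    expect_identical(is.na(abundanceValues(res$abundance)), is.na(m))
    ## idempotent
    res2 <- normalizeAbundance(res$abundance, bg)
    expect_equal(abundanceValues(res2$abundance),
                 abundanceValues(res$abundance), tolerance = 1e-12)
    expect_equal(res2$report$offset, rep(0, 6))
    expect_equal(res2$report$scale_factor, rep(1, 6))
})

test_that("constant background values are rejected (zero MAD)", {
    m <- matrix(1, 4, 3, dimnames = list(paste0("P", 1:4), paste0("S", 1:3)))
    expect_error(normalizeAbundance(makePA(m), paste0("P", 1:4)), "zero")
})

test_that("the planted affine outlier is flagged before normalization", {
    hits <- logical(20); extra <- integer(20)
    for (s in 1:20) {
        sim <- defaultStudyFixture(seed = 300 + s, nOutlierSamples = 1L)
        out <- detectOutlierSamples(logTransform(sim$abundance))
        hits[s] <- sim$truth$outlierSamples %in% out$outliers
        extra[s] <- length(setdiff(out$outliers, sim$truth$outlierSamples))
    }
    expect_gte(mean(hits), 0.95)
    ## a handful of legitimate extreme samples may also exceed z = 3
    expect_lte(median(extra), 3)
})

test_that("iid data triggers outlier flags at the rate the z-rule implies; duplicates never do", {
    flagged <- logical(40)
    for (s in 1:40) {
        set.seed(1000 + s)
        m <- matrix(rnorm(40 * 20), 40, 20,
                    dimnames = list(sprintf("P%02d", 1:40),
                                    sprintf("S%02d", 1:20)))
        flagged[s] <- length(detectOutlierSamples(makePA(m))$outliers) > 0
    }
    ## any-of-20 samples at z > 3 plus MAD estimation noise: low, not zero
    expect_lte(mean(flagged), 0.15)
    ## duplicated samples are unusually central, not outlying
    set.seed(9)
    m <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(sprintf("P%02d", 1:30), sprintf("S%02d", 1:10)))
    m[, 2] <- m[, 1]
    out <- detectOutlierSamples(makePA(m))
    expect_false(any(c("S01", "S02") %in% out$outliers))
    expect_error(detectOutlierSamples(makePA(m[, 1:3])), "at least 4")
})

test_that("correlations are invariant under a global affine map but not under per-sample centering", {
    set.seed(4)
    m <- matrix(rnorm(20 * 15), 20, 15,
                dimnames = list(sprintf("P%02d", 1:20), sprintf("S%02d", 1:15)))
    r0 <- cor(t(m))
    expect_equal(cor(t((m - 3) / 2)), r0, tolerance = 1e-12)
    ## per-sample offsets of non-trivial spread change correlations
    offsets <- rnorm(15, 0, 5)
    r1 <- cor(t(sweep(m, 2, offsets)))
    expect_gt(max(abs(r1 - r0)), 0.1)
})

test_that("preprocessing chain keeps truth indices consistent on the fixture", {
    fx <- fixtureRun(1)
    ## every retained protein still has its planted label; group sizes intact
    keep <- proteinIds(fx$baseline)
    expect_true(all(keep %in% names(fx$sim$truth$modules)))
    expect_equal(as.integer(table(fx$baselineGroups)[c("ALS", "HC", "PD")]),
                 c(41L, 20L, 19L))
    ## samples were only ever dropped, never reordered
    expect_identical(sampleIds(fx$baseline),
                     intersect(fx$sim$sampleInfo$sample_id[
                         fx$sim$sampleInfo$visit == 1], sampleIds(fx$baseline)))
})
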