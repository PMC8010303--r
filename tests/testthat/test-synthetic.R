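test_that("generation is bit-identical for identical seeds", {
    cfg <- twoBlockConfig(seed = 11, nNoise = 10L)
    a <- generateSynthetic(cfg)
    b <- generateSynthetic(cfg)
    expect_identical(abundanceValues(a$abundance), abundanceValues(b$abundance))
    expect_identical(a$truth$modules, b$truth$modules)
    expect_identical(a$truth$factors, b$truth$factors)
})

test_that("planted same-module correlation hits its target; cross-module is near zero", {
    sameR <- crossR <- numeric(20)
    for (s in 1:20) {
        cfg <- syntheticConfig(nProteins = 40L, moduleSizes = c(10L, 10L),
                               withinModuleCor = 0.7,
                               groupSizes = c(A = 30L), seed = s)
        sim <- generateSynthetic(cfg)
        r <- cor(t(logValues(sim)))
        mod <- sim$truth$modules
        same <- (outer(mod, mod, "==") & outer(mod, mod, "*") > 0)
        cross <- outer(mod > 0, mod > 0) & outer(mod, mod, "!=")
        ut <- upper.tri(r)
        sameR[s] <- mean(r[same & ut])
        crossR[s] <- mean(abs(r[cross & ut]))
    }
    expect_gt(mean(sameR), 0.6)
    expect_lt(mean(sameR), 0.8)
    ## cross-module |r| reflects factor-sampling noise lambda^2*rhat(f,f')
    ## at n = 30 (~0.17 in expectation); far below the planted correlation
    expect_lt(mean(crossR), 0.2)
    expect_lt(mean(crossR), mean(sameR) / 3)
    ## same-module beats cross-module in every seed tested
    expect_true(all(sameR > crossR))
})

test_that("the noise-free limit gives perfectly correlated modules", {
    cfg <- syntheticConfig(nProteins = 10L, moduleSizes = c(5L, 5L),
                           withinModuleCor = 1, groupSizes = c(A = 20L),
                           seed = 3)
    sim <- generateSynthetic(cfg)
    r <- cor(t(logValues(sim)))
    mod <- sim$truth$modules
    same <- outer(mod, mod, "==") & outer(mod, mod, "*") > 0 & upper.tri(r)
    expect_equal(unname(r[same]), rep(1, sum(same)), tolerance = 1e-12)
})

test_that("decorrelation reduces |r| by >= 0.3 in the named group and leaves other values untouched", {
    drop <- kept <- numeric(10)
    for (s in 1:10) {
        base <- syntheticConfig(nProteins = 20L, moduleSizes = c(10L, 10L),
                                withinModuleCor = 0.75,
                                groupSizes = c(HC = 25L, ALS = 25L), seed = s)
        pert <- base
        pert$decorrelatedPairs <- data.frame(protein_i = "P0001",
                                             protein_j = "P0005",
                                             group = "ALS")
        class(pert) <- "SyntheticConfig"
        a <- generateSynthetic(base)
        b <- generateSynthetic(pert)
        grp <- a$sampleInfo$group
        rA <- cor(logValues(a)["P0001", grp == "ALS"],
                  logValues(a)["P0005", grp == "ALS"])
        rB <- cor(logValues(b)["P0001", grp == "ALS"],
                  logValues(b)["P0005", grp == "ALS"])
        drop[s] <- abs(rA) - abs(rB)
        kept[s] <- max(abs(logValues(a)[-1, ] - logValues(b)[-1, ]))
    }
    expect_gt(mean(drop), 0.3)
    ## all proteins other than the perturbed one are bit-identical
    expect_equal(max(kept), 0)
})

test_that("per-subject OLS slopes recover the planted longitudinal slope", {
    est <- numeric(10)
    for (s in 1:10) {
        cfg <- syntheticConfig(
            nProteins = 5L, moduleSizes = c(3L,  2L),
            withinModuleCor = 0.75, groupSizes = c(ALS = 15L),
            longitudinal = list(group = "ALS", visitCounts = rep(4L, 15),
                                spacingMonths = 6,
                                slopes = c(P0001 = -0.04)),
            seed = s)
        sim <- generateSynthetic(cfg)
        y <- log(abundanceValues(sim$abundance)["P0001", ])
        info <- sim$sampleInfo
        slopes <- vapply(split(seq_len(nrow(info)), info$subject_id),
                         function(ix) {
                             if (length(ix) < 2) return(NA_real_)
                             coef(lm(y[ix] ~ info$months_from_baseline[ix]))[2]
                         }, 0)
        est[s] <- mean(slopes, na.rm = TRUE)
    }
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) + 0.04), 2 * se + 0.005)
})

test_that("the study fixture matches its design: sizes, groups, visits, plants", {
    sim <- defaultStudyFixture(seed = 5)
    truth <- sim$truth
    sizes <- as.integer(table(truth$modules[truth$modules > 0]))
    expect_equal(length(sizes), 10L)
    expect_equal(min(sizes), 7L)
    expect_equal(max(sizes), 183L)
    expect_equal(length(truth$modules), 870L)
    info <- sim$sampleInfo
    expect_equal(sum(info$visit == 1), 80L)
    expect_equal(as.integer(table(info$group[info$visit == 1])[
        c("ALS", "HC", "PD")]), c(41L, 20L, 19L))
    ## longitudinal subjects: 20 with >= 2 visits, attrition 20/12/10/2
    visits <- table(info$subject_id)
    expect_equal(sum(visits >= 2), 20L)
    expect_equal(sum(visits >= 3), 12L)
    expect_equal(sum(visits >= 4), 10L)
    expect_equal(sum(visits >= 5), 2L)
    expect_equal(sum(truth$slopes < 0), 15L)
    expect_equal(sum(truth$slopes > 0), 10L)
    expect_equal(nrow(truth$decorrelatedPairs), 10L)
    expect_length(truth$outlierSamples, 3L)
})

test_that("config invariants are enforced", {
    expect_error(syntheticConfig(10, c(6L, 6L)), "sum")
    expect_error(syntheticConfig(10, c(5L, 5L), withinModuleCor = 1.2))
    expect_error(syntheticConfig(10, c(5L, 5L), missingRate = c(A = 1.5)))
    expect_error(syntheticConfig(
        20, c(10L, 10L), groupSizes = c(A = 5L),
        decorrelatedPairs = data.frame(protein_i = "P0001",
                                       protein_j = "P0011", group = "A")),
        "same planted module|one planted module")
})
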