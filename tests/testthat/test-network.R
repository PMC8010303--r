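test_that("pairwise correlation reports r, complete-pair counts and undefined flags", {
    m <- rbind(P1 = c(1, 2, 3), P2 = c(2, 4, 6), P3 = c(3, 2, 1))
    colnames(m) <- paste0("S", 1:3)
    pc <- pairwiseCorrelation(m, minPairwiseN = 2L)
    expect_equal(pc$r["P1", "P2"], 1)
    expect_equal(pc$r["P1", "P3"], -1)
    expect_equal(pc$n["P1", "P2"], 3L)

    set.seed(1)
    m2 <- matrix(rnorm(4 * 12), 4, 12,
                 dimnames = list(paste0("P", 1:4), paste0("S", 1:12)))
    m2[1, 1:8] <- NA; m2[2, 5:12] <- NA     # P1/P2 share 4 samples only
    pc2 <- pairwiseCorrelation(m2, minPairwiseN = 10L)
    expect_true(pc2$undefined["P1", "P2"])
    expect_true(is.na(pc2$r["P1", "P2"]))
    ## zero-variance protein undefined with all partners
    m2[3, ] <- 7
    pc3 <- pairwiseCorrelation(m2, minPairwiseN = 3L)
    expect_true(all(pc3$undefined["P3", -3]))
})

test_that("signed adjacency matches its closed form and is monotone in r", {
    pair <- function(r) matrix(c(1, r, r, 1), 2)
    expect_equal(signedAdjacency(pair(1), beta = 7)[1, 2], 1)
    expect_equal(signedAdjacency(pair(-1), beta = 7)[1, 2], 0)
    expect_identical(signedAdjacency(pair(0), beta = 7)[1, 2], 0.5^7)
    rs <- seq(-1, 1, by = 0.01)
    a <- vapply(rs, function(r) signedAdjacency(pair(r), beta = 7)[1, 2], 0)
    expect_true(all(diff(a) > 0))       # strictly increasing in r
    expect_true(all(a >= 0 & a <= 1))
    ## undefined correlations take the neutral weight, with a warning
    r <- matrix(c(1, NA, NA, 1), 2)
    expect_warning(au <- signedAdjacency(r, 7), "undefined")
    expect_equal(au[1, 2], 0.5^7)
})

test_that("dissimilarity: complement and topological overlap agree with hand computation", {
    a1 <- matrix(1, 2, 2)
    expect_equal(networkDissimilarity(a1, "adjacency")[1, 2], 0)
    ## 3-node toy, all off-diagonal a = 0.5: t = (0.25 + 0.5)/(1 + 1 - 0.5)
    a <- matrix(0.5, 3, 3); diag(a) <- 1
    d <- networkDissimilarity(a, "tom")
    expect_equal(d[1, 2], 1 - 0.5, tolerance = 1e-12)
    ## a shared neighbour raises topological overlap above direct adjacency
    a4 <- diag(4)
    a4[1, 2] <- a4[2, 1] <- 0.3
    a4[1, 3] <- a4[3, 1] <- 0.8
    a4[2, 3] <- a4[3, 2] <- 0.8
    dtom <- networkDissimilarity(a4, "tom")
    ## brute-force evaluation of the formula for the pair (1,2)
    k <- rowSums(a4) - 1
    tij <- (a4[1, 3] * a4[3, 2] + a4[1, 4] * a4[4, 2] + a4[1, 2]) /
        (min(k[1], k[2]) + 1 - a4[1, 2])
    expect_equal(1 - dtom[1, 2], tij, tolerance = 1e-12)
    expect_gt(1 - dtom[1, 2], a4[1, 2])
})

test_that("module detection recovers a clean two-block structure exactly", {
    sim <- generateSynthetic(twoBlockConfig(seed = 21, wcor = 0.8))
    v <- logValues(sim)
    pc <- pairwiseCorrelation(v, 10L)
    a <- signedAdjacency(pc$r, 7)
    det <- detectModules(networkDissimilarity(a, "adjacency"), v)
    expect_equal(ari(det$modules, sim$truth$modules), 1)
    ## relabeling invariance: permuted protein order, same partition
    set.seed(1)
    perm <- sample(nrow(v))
    pc2 <- pairwiseCorrelation(v[perm, ], 10L)
    a2 <- signedAdjacency(pc2$r, 7)
    det2 <- detectModules(networkDissimilarity(a2, "adjacency"), v[perm, ])
    expect_equal(ari(det2$modules[rownames(v)], det$modules), 1)
})

test_that("clusters below the minimum module size stay unassigned", {
    set.seed(5)
    common <- rnorm(30)
    m <- rbind(t(sapply(1:4, function(i) common + rnorm(30, 0, 0.05))),
               matrix(rnorm(12 * 30), 12, 30))
    rownames(m) <- sprintf("P%02d", 1:16); colnames(m) <- paste0("S", 1:30)
    pc <- pairwiseCorrelation(m, 10L)
    a <- signedAdjacency(pc$r, 7)
    det <- detectModules(networkDissimilarity(a, "adjacency"), m,
                         minModuleSize = 5L)
    expect_true(all(det$modules[1:4] == 0L))
})

test_that("pure-noise matrices leave at least 90% of proteins unassigned", {
    unass <- numeric(10)
    for (s in 1:10) {
        set.seed(s)
        m <- matrix(rnorm(100 * 50), 100, 50,
                    dimnames = list(sprintf("P%03d", 1:100),
                                    sprintf("S%02d", 1:50)))
        pc <- pairwiseCorrelation(m, 10L)
        a <- signedAdjacency(pc$r, 7)
        det <- detectModules(networkDissimilarity(a, "adjacency"), m)
        unass[s] <- mean(det$modules == 0L)
    }
    expect_gte(mean(unass), 0.9)
})

test_that("eigenproteins summarize their module and carry the contracted sign", {
    ## degenerate module: identical proteins
    set.seed(6)
    profile <- rnorm(20)
    m <- matrix(rep(profile, each = 5), 5, 20,
                dimnames = list(paste0("P", 1:5), paste0("S", 1:20)))
    mods <- structure(rep(1L, 5), names = rownames(m))
    eig <- moduleEigenproteins(m, mods)
    zstd <- (profile - mean(profile)) / sd(profile)
    expect_gte(abs(cor(eig$eigenproteins[1, ], zstd)), 0.999)
    expect_equal(unname(eig$varianceExplained), 1, tolerance = 1e-12)
    expect_equal(sd(eig$eigenproteins[1, ]), 1, tolerance = 1e-12)

    ## exactly-orthogonal 2-protein module: variance explained = 1/2
    m2 <- rbind(Pa = c(1, 0, -1, 0), Pb = c(0, 1, 0, -1))
    colnames(m2) <- paste0("S", 1:4)
    eig2 <- moduleEigenproteins(m2, structure(c(1L, 1L), names = c("Pa", "Pb")))
    expect_equal(unname(eig2$varianceExplained), 0.5, tolerance = 1e-12)

    ## sign contract on random data
    set.seed(7)
    m3 <- matrix(rnorm(30 * 25), 30, 25,
                 dimnames = list(sprintf("P%02d", 1:30), paste0("S", 1:25)))
    mods3 <- structure(rep(1:3, each = 10), names = rownames(m3))
    eig3 <- moduleEigenproteins(m3, mods3)
    for (k in 1:3) {
        xm <- t(scale(t(m3[mods3 == k, ])))
        expect_gte(cor(eig3$eigenproteins[k, ], colMeans(xm)), 0)
    }
    ## constant protein in a module is an error
    m3[1, ] <- 2
    expect_error(moduleEigenproteins(m3, mods3), "constant")
})

test_that("intramodular connectivity counts within-module adjacency; hub quota is ceil(frac*size)", {
    set.seed(8)
    n <- 15
    a <- matrix(runif(n * n, 0.2, 0.9), n, n)
    a <- (a + t(a)) / 2; diag(a) <- 1
    ids <- sprintf("P%02d", 1:n)
    dimnames(a) <- list(ids, ids)
    mods <- structure(c(rep(1L, 10), rep(2L, 5)), names = ids)
    conn <- intramodularConnectivity(a, mods, hubFrac = 0.10)
    expect_equal(sum(conn$hub[mods == 1]), 1L)   # ceil(0.1*10)
    expect_equal(sum(conn$hub[mods == 2]), 1L)   # ceil(0.1*5) = ceil(0.5)
    i <- which(ids == "P03")
    expect_equal(conn$kIn[["P03"]], sum(a[i, which(mods == 1L)]) - 1)
    ## unassigned proteins: kIn 0, never hubs
    mods0 <- mods; mods0[1:3] <- 0L
    conn0 <- intramodularConnectivity(a, mods0)
    expect_true(all(conn0$kIn[1:3] == 0))
    expect_true(!any(conn0$hub[1:3]))
})

test_that("adjacency- and TOM-based partitions agree on block-diagonal adjacency", {
    ## two noise-free blocks: zero cross-block adjacency by construction
    ids <- sprintf("P%02d", 1:12)
    a <- matrix(0, 12, 12, dimnames = list(ids, ids))
    a[1:6, 1:6] <- 0.8; a[7:12, 7:12] <- 0.8; diag(a) <- 1
    set.seed(9)
    f1 <- rnorm(30); f2 <- rnorm(30)
    v <- rbind(matrix(rep(f1, each = 6), 6) + rnorm(180, 0, 0.01),
               matrix(rep(f2, each = 6), 6) + rnorm(180, 0, 0.01))
    dimnames(v) <- list(ids, paste0("S", 1:30))
    dAdj <- detectModules(networkDissimilarity(a, "adjacency"), v)$modules
    dTom <- detectModules(networkDissimilarity(a, "tom"), v)$modules
    expect_equal(ari(dAdj, dTom), 1)
})

test_that("leave-one-out stability is deterministic, 1 on noise-free blocks, low on noise", {
    sim <- generateSynthetic(twoBlockConfig(seed = 31, wcor = 1,
                                            nSubjects = 30L))
    v <- logValues(sim)
    s1 <- moduleStability(v, networkConfig(), nIter = 10L, seed = 4)
    s2 <- moduleStability(v, networkConfig(), nIter = 10L, seed = 4)
    expect_identical(s1, s2)
    expect_equal(unname(s1[sim$truth$modules > 0]),
                 rep(1, sum(sim$truth$modules > 0)))
    ## pure noise: assigned proteins are unstable
    set.seed(10)
    m <- matrix(rnorm(60 * 30), 60, 30,
                dimnames = list(sprintf("P%02d", 1:60), paste0("S", 1:30)))
    pc <- pairwiseCorrelation(m, 10L)
    a <- signedAdjacency(pc$r, 7)
    ref <- detectModules(networkDissimilarity(a, "adjacency"), m)$modules
    if (any(ref > 0)) {
        st <- moduleStability(m, networkConfig(), nIter = 10L, seed = 5,
                              refModules = ref)
        expect_lt(mean(st[ref > 0]), 0.5)
    } else succeed("no spurious modules to score")
})
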