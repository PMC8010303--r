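## Synthetic CSF-proteome generator: a latent-factor model with planted
## correlation modules, group-level eigenprotein shifts, disease-specific
## decorrelation, longitudinal slopes, missingness and outlier samples,
## together with the ground truth needed for recovery tests.

moduleOf <- function(nProteins, moduleSizes) {
    assignment <- rep(0L, nProteins)
    assignment[seq_len(sum(moduleSizes))] <-
        rep(seq_along(moduleSizes), moduleSizes)
    names(assignment) <- sprintf("P%04d", seq_len(nProteins))
    assignment
}

#' Configuration for the synthetic abundance generator
#'
#' The model: protein i in module m, sample j of subject s (group g, visit v)
#' has log abundance
#' `x_ij = mu_i + lambda_i * (f_mj + delta_gm) + sigma_i * eps_ij (+ slope_i * months_j)`
#' with per-module latent factors `f` standard normal across subjects,
#' loadings `lambda_i = sqrt(withinModuleCor_m)` (so same-module pairs have
#' correlation ~ `withinModuleCor`), and unique noise of variance
#' `1 - lambda_i^2` (unit total variance). Repeat visits keep the subject's
#' factor up to an innovation of sd `factorInnovationSd`, and a fraction
#' `subjectShare` of the unique variance is subject-level — the
#' repeated-measures structure a random-intercept model assumes. Noise
#' proteins are pure unique noise. Decorrelation resamples the factor path of
#' the named protein within the named group's samples (marginal variance
#' preserved). Missingness is MCAR per group by default.
#'
#' @param nProteins total protein count.
#' @param moduleSizes integer vector; `sum(moduleSizes) <= nProteins`, the
#'   remainder are unassigned noise proteins.
#' @param withinModuleCor target same-module correlation in (0, 1], scalar or
#'   one value per module.
#' @param groupSizes named integer vector, subjects per group; the first
#'   group name is arbitrary (the reference group is named downstream).
#' @param eigenproteinShift data.frame (`group`, `module`, `delta`) of
#'   latent-factor offsets, or NULL.
#' @param decorrelatedPairs data.frame (`protein_i`, `protein_j`, `group`);
#'   both proteins must share a planted module; `protein_i`'s factor path is
#'   resampled within the named group.
#' @param longitudinal NULL, or list with `group`, `visitCounts` (total
#'   visits for that many leading subjects of the group), `spacingMonths`,
#'   and `slopes` (named per-protein log-abundance change per month).
#' @param missingRate named per-group missingness probability (MCAR).
#' @param missingMechanism `"mcar"` or `"intensity"` (missingness odds decay
#'   with abundance; group-level rate preserved on average).
#' @param highMissing NULL, or list(`n`, `rate`, `group`): that many noise
#'   proteins get elevated missingness in one group (exercises the
#'   missingness filter).
#' @param nOutlierSamples baseline samples receiving a global distortion.
#' @param outlierShift,outlierScale location shift (in within-sample SD
#'   units, i.e. log units here) and spread multiplier for outlier samples.
#' @param subjectShare fraction of unique variance that is subject-level.
#' @param factorInnovationSd per-visit innovation sd of the subject factor.
#' @param baselineMean,baselineSd distribution of per-protein mean log
#'   abundance `mu_i`.
#' @param outputScale `"linear"` (exponentiated, the default — mirrors raw
#'   abundance exports) or `"log"`.
#' @param seed integer seed; generation is deterministic given the config.
#' @return validated config (class `SyntheticConfig`).
#' @export
syntheticConfig <- function(nProteins,
                            moduleSizes,
                            withinModuleCor = 0.7,
                            groupSizes = c(A = 30),
                            eigenproteinShift = NULL,
                            decorrelatedPairs = NULL,
                            longitudinal = NULL,
                            missingRate = NULL,
                            missingMechanism = c("mcar", "intensity"),
                            highMissing = NULL,
                            nOutlierSamples = 0L,
                            outlierShift = 4,
                            outlierScale = 1,
                            subjectShare = 0.7,
                            factorInnovationSd = 0.3,
                            baselineMean = 5,
                            baselineSd = 1,
                            outputScale = c("linear", "log"),
                            seed = 1L) {
    missingMechanism <- match.arg(missingMechanism)
    outputScale <- match.arg(outputScale)
    stopifnot(nProteins >= 1, all(moduleSizes >= 1),
              sum(moduleSizes) <= nProteins,
              all(withinModuleCor > 0), all(withinModuleCor <= 1),
              length(withinModuleCor) %in% c(1L, length(moduleSizes)),
              !is.null(names(groupSizes)), all(groupSizes >= 1),
              subjectShare >= 0, subjectShare <= 1,
              factorInnovationSd >= 0, factorInnovationSd <= 1)
    if (is.null(missingRate))
        missingRate <- structure(rep(0, length(groupSizes)),
                                 names = names(groupSizes))
    stopifnot(all(missingRate >= 0 & missingRate <= 1),
              all(names(groupSizes) %in% names(missingRate) |
                  length(missingRate) == length(groupSizes)))
    assignment <- moduleOf(nProteins, moduleSizes)
    if (!is.null(decorrelatedPairs)) {
        mi <- assignment[decorrelatedPairs$protein_i]
        mj <- assignment[decorrelatedPairs$protein_j]
        if (anyNA(mi) || anyNA(mj) || any(mi == 0L) || any(mi != mj))
            stop("decorrelated pairs must reference proteins of one planted module")
        if (!all(decorrelatedPairs$group %in% names(groupSizes)))
            stop("decorrelated pair group not in groupSizes")
    }
    if (!is.null(longitudinal)) {
        stopifnot(longitudinal$group %in% names(groupSizes),
                  length(longitudinal$visitCounts) <=
                      groupSizes[[longitudinal$group]],
                  all(longitudinal$visitCounts >= 2))
        if (is.null(longitudinal$spacingMonths))
            longitudinal$spacingMonths <- 6
    }
    structure(list(nProteins = nProteins, moduleSizes = moduleSizes,
                   withinModuleCor = withinModuleCor,
                   groupSizes = groupSizes,
                   eigenproteinShift = eigenproteinShift,
                   decorrelatedPairs = decorrelatedPairs,
                   longitudinal = longitudinal,
                   missingRate = missingRate,
                   missingMechanism = missingMechanism,
                   highMissing = highMissing,
                   nOutlierSamples = as.integer(nOutlierSamples),
                   outlierShift = outlierShift,
                   outlierScale = outlierScale,
                   subjectShare = subjectShare,
                   factorInnovationSd = factorInnovationSd,
                   baselineMean = baselineMean, baselineSd = baselineSd,
                   outputScale = outputScale, seed = as.integer(seed)),
              class = "SyntheticConfig")
}

withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Generate a synthetic abundance matrix with known truth
#'
#' @param config a [syntheticConfig()] object.
#' @return list with elements `abundance` (a [ProteinAbundance-class], scale
#'   per `config$outputScale`), `sampleInfo` (validated metadata data.frame)
#'   and `truth` (planted module assignment, per-sample metadata, shifts,
#'   decorrelated pairs, slopes, baseline latent factors, outlier samples,
#'   high-missingness proteins, seed).
#' @export
generateSynthetic <- function(config) {
    stopifnot(inherits(config, "SyntheticConfig"))
    withSeed(config$seed, {
        nP <- config$nProteins
        sizes <- config$moduleSizes
        M <- length(sizes)
        assignment <- moduleOf(nP, sizes)
        pids <- names(assignment)
        wcor <- rep(config$withinModuleCor, length.out = M)
        lambda <- ifelse(assignment > 0L, sqrt(wcor)[pmax(assignment, 1L)], 0)
        sigmaU <- sqrt(1 - lambda^2)

        ## subjects and samples
        groups <- names(config$groupSizes)
        subjTab <- do.call(rbind, lapply(groups, function(g) {
            n <- config$groupSizes[[g]]
            data.frame(subject_id = sprintf("%s%02d", g, seq_len(n)),
                       group = g, stringsAsFactors = FALSE)
        }))
        nVisits <- rep(1L, nrow(subjTab))
        spacing <- 6
        lon <- config$longitudinal
        if (!is.null(lon)) {
            idx <- which(subjTab$group == lon$group)[
                seq_along(lon$visitCounts)]
            nVisits[idx] <- as.integer(lon$visitCounts)
            spacing <- lon$spacingMonths
        }
        info <- do.call(rbind, lapply(seq_len(nrow(subjTab)), function(k) {
            v <- seq_len(nVisits[k])
            data.frame(sample_id = sprintf("%s_V%d", subjTab$subject_id[k], v),
                       subject_id = subjTab$subject_id[k],
                       group = subjTab$group[k], visit = v,
                       months_from_baseline = (v - 1) * spacing,
                       stringsAsFactors = FALSE)
        }))
        S <- nrow(subjTab); J <- nrow(info)
        subjIdx <- match(info$subject_id, subjTab$subject_id)

        ## latent factor paths: subject baseline + per-visit innovation
        iv <- config$factorInnovationSd
        factorPath <- function() {
            F0 <- matrix(stats::rnorm(M * S), M, S)
            f <- F0[, subjIdx, drop = FALSE]
            rep1 <- info$visit > 1L
            if (any(rep1))
                f[, rep1] <- sqrt(1 - iv^2) * f[, rep1] +
                    iv * matrix(stats::rnorm(M * sum(rep1)), M)
            f
        }
        f <- factorPath()

        ## group/module factor shifts
        delta <- matrix(0, length(groups), M,
                        dimnames = list(groups, NULL))
        if (!is.null(config$eigenproteinShift)) {
            es <- config$eigenproteinShift
            delta[cbind(match(es$group, groups), es$module)] <- es$delta
        }
        fShift <- f + t(delta[info$group, , drop = FALSE])

        ## unique noise: subject-level share + observation-level remainder
        rho <- config$subjectShare
        U0 <- matrix(stats::rnorm(nP * S), nP, S)
        eps <- sqrt(rho) * U0[, subjIdx, drop = FALSE] +
            sqrt(1 - rho) * matrix(stats::rnorm(nP * J), nP, J)

        mu <- stats::rnorm(nP, config$baselineMean, config$baselineSd)
        x <- mu + lambda * fShift[pmax(assignment, 1L), , drop = FALSE] *
            (assignment > 0L) + sigmaU * eps
        dimnames(x) <- list(pids, info$sample_id)

        ## disease-specific decorrelation: independent factor path for the
        ## named protein within the named group's samples
        dp <- config$decorrelatedPairs
        if (!is.null(dp)) {
            done <- character()
            for (k in seq_len(nrow(dp))) {
                i <- dp$protein_i[k]; g <- dp$group[k]
                key <- paste(i, g)
                if (key %in% done) next
                done <- c(done, key)
                m <- assignment[[i]]
                fNew <- factorPath()[m, ] + delta[g, m]
                inG <- info$group == g
                x[i, inG] <- mu[match(i, pids)] +
                    lambda[match(i, pids)] * fNew[inG] +
                    sigmaU[match(i, pids)] * eps[match(i, pids), inG]
            }
        }

        ## longitudinal slopes (months are 0 at baseline)
        if (!is.null(lon) && length(lon$slopes)) {
            sl <- lon$slopes
            x[names(sl), ] <- x[names(sl), , drop = FALSE] +
                outer(unname(sl), info$months_from_baseline)
        }

        ## outlier samples: global location/scale distortion at baseline
        outlierSamples <- character()
        if (config$nOutlierSamples > 0L) {
            cand <- which(info$visit == 1L)
            pick <- sample(cand, config$nOutlierSamples)
            outlierSamples <- info$sample_id[pick]
            for (j in pick) {
                ctr <- stats::median(x[, j])
                x[, j] <- ctr + config$outlierScale * (x[, j] - ctr) +
                    config$outlierShift
            }
        }

        ## missingness
        rate <- config$missingRate[info$group]
        if (any(rate > 0)) {
            if (config$missingMechanism == "mcar") {
                drop <- matrix(stats::runif(nP * J), nP, J) <
                    matrix(rate, nP, J, byrow = TRUE)
            } else {
                ## intensity-dependent: lower abundance, higher odds;
                ## per-protein weights normalized to keep the group rate
                z <- (x - rowMeans(x)) / apply(x, 1L, stats::sd)
                w <- exp(-z); w <- w / rowMeans(w)
                drop <- matrix(stats::runif(nP * J), nP, J) <
                    pmin(1, w * matrix(rate, nP, J, byrow = TRUE))
            }
            x[drop] <- NA
        }
        highMissingProteins <- character()
        hm <- config$highMissing
        if (!is.null(hm) && hm$n > 0L) {
            noise <- pids[assignment == 0L]
            if (hm$n > length(noise))
                stop("highMissing$n exceeds the number of noise proteins")
            highMissingProteins <- utils::tail(noise, hm$n)
            inG <- info$group == hm$group
            block <- matrix(stats::runif(hm$n * sum(inG)), hm$n) < hm$rate
            xi <- x[highMissingProteins, inG, drop = FALSE]
            xi[block] <- NA
            x[highMissingProteins, inG] <- xi
        }

        if (config$outputScale == "linear") x <- exp(x)
        info <- validateSampleInfo(info)
        abundance <- ProteinAbundance(x, scale = config$outputScale,
                                      sampleInfo = info)
        truth <- list(modules = assignment,
                      sampleInfo = info,
                      shifts = config$eigenproteinShift,
                      decorrelatedPairs = config$decorrelatedPairs,
                      slopes = if (is.null(lon)) NULL else lon$slopes,
                      factors = structure(fShift,
                                          dimnames = list(
                                              sprintf("F%d", seq_len(M)),
                                              info$sample_id)),
                      outlierSamples = outlierSamples,
                      highMissingProteins = highMissingProteins,
                      seed = config$seed)
        list(abundance = abundance, sampleInfo = info, truth = truth)
    })
}

#' Ready-made synthetic analogue of the CSF study design
#'
#' Three groups of 41/20/19 subjects (ALS/HC/PD analogue), 10 planted modules
#' with sizes from 7 to 183 plus 114 noise proteins (870 in total, ~80
#' baseline samples), latent shifts in three modules (decreased module 2 and
#' increased modules 4/9 in ALS; increased module 9 in PD), 10 ALS-specific
#' decorrelated pairs hosted in modules 8 and 9, 15 longitudinally decreasing
#' (modules 6 and 2) and 10 increasing (noise) proteins at +/-0.04 log
#' units/month among 20 ALS subjects with 2-5 six-monthly visits, group-wise
#' MCAR missingness plus 18 high-missingness proteins, and 3 outlier samples.
#'
#' @param seed integer seed.
#' @param nOutlierSamples number of planted outlier samples (default 3).
#' @return as [generateSynthetic()].
#' @export
defaultStudyFixture <- function(seed = 1L, nOutlierSamples = 3L) {
    sizes <- c(183L, 115L, 100L, 90L, 75L, 67L, 58L, 45L, 16L, 7L)
    nP <- sum(sizes) + 114L
    pid <- function(i) sprintf("P%04d", i)
    ends <- cumsum(sizes)                       # module end indices
    m6 <- (ends[5] + 1):ends[6]; m2 <- (ends[1] + 1):ends[2]
    m8 <- (ends[7] + 1):ends[8]; m9 <- (ends[8] + 1):ends[9]
    noise <- (ends[10] + 1):nP
    decreasing <- pid(c(m6[1:10], m2[1:5]))
    increasing <- pid(noise[1:10])
    slopes <- c(structure(rep(-0.04, 15), names = decreasing),
                structure(rep(+0.04, 10), names = increasing))
    pairs <- data.frame(
        protein_i = pid(c(m8[1:5], m9[1:5])),
        protein_j = pid(c(m8[11:15], m9[6:10])),
        group = "ALS", stringsAsFactors = FALSE)
    cfg <- syntheticConfig(
        nProteins = nP, moduleSizes = sizes, withinModuleCor = 0.75,
        groupSizes = c(ALS = 41L, HC = 20L, PD = 19L),
        eigenproteinShift = data.frame(
            group = c("ALS", "ALS", "ALS", "PD"),
            module = c(2L, 4L, 9L, 9L),
            delta = c(-1.2, 1.2, 1.0, 1.5)),
        decorrelatedPairs = pairs,
        longitudinal = list(group = "ALS",
                            visitCounts = c(rep(2L, 8), rep(3L, 2),
                                            rep(4L, 8), rep(5L, 2)),
                            spacingMonths = 6, slopes = slopes),
        missingRate = c(ALS = 0.03, HC = 0.02, PD = 0.03),
        highMissing = list(n = 18L, rate = 0.65, group = "PD"),
        nOutlierSamples = nOutlierSamples,
        seed = seed)
    generateSynthetic(cfg)
}
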