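## End-to-end orchestration: load/generate -> log transform -> missingness
## filter -> background normalization -> outlier removal -> baseline-only
## network -> eigenprotein group tests -> differential correlation ->
## enrichment -> longitudinal screen -> optional cross-tabulation; all
## artifacts as TSV plus one JSON summary.

#' Pipeline configuration
#'
#' All study-level thresholds live here as defaults (soft power 7, minimum
#' module size 5, merge cut height 0.05, >50% per-group missingness filter,
#' 10% hubs, outlier robust z 3, BH alpha 0.1), never hard-coded in the
#' stages.
#'
#' @param abundancePath,metadataPath input files (see [readAbundance()],
#'   [readSampleInfo()]); alternatively give `synthetic`.
#' @param synthetic a [syntheticConfig()], or `"default_study_fixture"`.
#' @param geneMapPath,geneSetsPath optional protein->gene map and GMT file.
#' @param crossAssignmentPath optional TSV (`id`, `module`) of a second
#'   network's assignment for cross-tabulation.
#' @param orientation,inputScale passed to [readAbundance()].
#' @param referenceGroup reference (control) group label; defaults to the
#'   first group level.
#' @param network a [networkConfig()].
#' @param maxMissingFrac per-group missingness filter threshold.
#' @param backgroundFrac background fraction for normalization.
#' @param outlierZCut robust z threshold for outlier samples.
#' @param alpha BH significance threshold.
#' @param stabilityIter leave-one-out stability iterations (0 = skip).
#' @param withinModuleOnly restrict differential correlation to same-module
#'   pairs (default FALSE: all pairs).
#' @param seed global seed; per-stage child seeds are derived from it.
#' @param outDir output directory.
#' @return validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(abundancePath = NULL, metadataPath = NULL,
                           synthetic = NULL, geneMapPath = NULL,
                           geneSetsPath = NULL, crossAssignmentPath = NULL,
                           orientation = "proteins_in_rows",
                           inputScale = "linear",
                           referenceGroup = NULL,
                           network = networkConfig(),
                           maxMissingFrac = 0.5, backgroundFrac = 0.9,
                           outlierZCut = 3.0, alpha = 0.1,
                           stabilityIter = 0L, withinModuleOnly = FALSE,
                           seed = 1L, outDir = "proteonet_out") {
    if (is.null(synthetic) &&
        (is.null(abundancePath) || is.null(metadataPath)))
        stop("config error: provide abundancePath+metadataPath or a ",
             "synthetic spec")
    if (!is.null(abundancePath) && !file.exists(abundancePath))
        stop("config error: abundance file not found: ", abundancePath)
    if (!is.null(metadataPath) && !file.exists(metadataPath))
        stop("config error: metadata file not found: ", metadataPath)
    stopifnot(alpha > 0, alpha < 1, maxMissingFrac >= 0, maxMissingFrac <= 1,
              backgroundFrac > 0, backgroundFrac <= 1, outlierZCut > 0)
    structure(list(abundancePath = abundancePath,
                   metadataPath = metadataPath, synthetic = synthetic,
                   geneMapPath = geneMapPath, geneSetsPath = geneSetsPath,
                   crossAssignmentPath = crossAssignmentPath,
                   orientation = orientation, inputScale = inputScale,
                   referenceGroup = referenceGroup, network = network,
                   maxMissingFrac = maxMissingFrac,
                   backgroundFrac = backgroundFrac,
                   outlierZCut = outlierZCut, alpha = alpha,
                   stabilityIter = as.integer(stabilityIter),
                   withinModuleOnly = withinModuleOnly,
                   seed = as.integer(seed), outDir = outDir),
              class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the [pipelineConfig()] arguments; `network:` is a nested
#' block of [networkConfig()] arguments.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    netArgs <- y$network
    y$network <- NULL
    net <- if (is.null(netArgs)) networkConfig()
           else do.call(networkConfig, netArgs)
    do.call(pipelineConfig, c(y, list(network = net)))
}

childSeed <- function(seed, stage) {
    (as.integer(seed) + 1000003L * as.integer(stage)) %% 2147483647L
}

stageLog <- function(stage, ...) {
    message(sprintf("[%s] ", stage), ...)
}

writeTsv <- function(df, outDir, name) {
    path <- file.path(outDir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order and writes every artifact as TSV plus a
#' versioned JSON summary (`summary.json`) with per-stage counts, the seeds
#' used and a config echo. A stage failure aborts with a stage-labeled
#' error; artifacts already written are retained.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the in-memory stage results and the
#'   summary.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    artifacts <- character()
    summary <- list(schema_version = "1.0",
                    package_version = as.character(
                        utils::packageVersion("ProteoNet")),
                    seed = config$seed, stages = list(),
                    timestamp = format(Sys.time(), tz = "UTC"))

    ## ---- load or generate ----
    stageLog("load", "reading inputs")
    truth <- NULL
    if (!is.null(config$synthetic)) {
        spec <- config$synthetic
        sim <- if (identical(spec, "default_study_fixture"))
            defaultStudyFixture(seed = childSeed(config$seed, 1L))
        else generateSynthetic(spec)
        pa <- sim$abundance; info <- sim$sampleInfo; truth <- sim$truth
        artifacts <- c(artifacts,
                       writeTsv(data.frame(protein_id = names(truth$modules),
                                           module = truth$modules),
                                config$outDir, "truth_modules.tsv"))
    } else {
        pa <- readAbundance(config$abundancePath,
                            orientation = config$orientation,
                            scale = config$inputScale)
        info <- readSampleInfo(config$metadataPath)
        pa <- attachSampleInfo(pa, info)
        info <- as.data.frame(colData(pa))
    }
    if (is.null(config$referenceGroup))
        config$referenceGroup <- levels(as.factor(info$group))[1L]
    summary$stages$load <- list(proteins = nrow(pa), samples = ncol(pa),
                                groups = as.list(table(info$group)))

    ## ---- log transform ----
    if (abundanceScale(pa) == "linear") {
        stageLog("log_transform", "natural log")
        pa <- logTransform(pa)
    }

    ## ---- missingness filter ----
    stageLog("missing_filter", "per-group > ", config$maxMissingFrac)
    flt <- filterMissingByGroup(pa, maxFrac = config$maxMissingFrac)
    pa <- flt$abundance
    artifacts <- c(artifacts, writeTsv(flt$report, config$outDir,
                                       "excluded_proteins.tsv"))
    summary$stages$missing_filter <-
        list(excluded_proteins = nrow(flt$report), retained = nrow(pa))

    ## ---- normalization ----
    stageLog("normalize", "background median/MAD per sample")
    bg <- selectBackground(pa, config$backgroundFrac)
    nrm <- normalizeAbundance(pa, bg)
    pa <- nrm$abundance
    artifacts <- c(artifacts, writeTsv(nrm$report, config$outDir,
                                       "normalization_factors.tsv"))
    summary$stages$normalize <- list(background_size = length(bg))

    ## ---- outlier removal ----
    stageLog("outliers", "robust z > ", config$outlierZCut)
    outl <- detectOutlierSamples(pa, zCut = config$outlierZCut)
    pa <- outl$abundance
    info <- info[info$sample_id %in% sampleIds(pa), ]
    artifacts <- c(artifacts, writeTsv(outl$report, config$outDir,
                                       "sample_outlier_scores.tsv"))
    summary$stages$outliers <- list(excluded_samples = outl$outliers)

    ## ---- baseline network ----
    stageLog("network", "baseline samples only; beta = ",
             config$network$beta)
    baseline <- pa[, sampleIds(pa) %in%
                       info$sample_id[info$visit == 1L]]
    net <- buildNetwork(baseline, config$network,
                        stabilityIter = config$stabilityIter,
                        seed = childSeed(config$seed, 6L))
    modules <- moduleAssignment(net)
    artifacts <- c(artifacts,
        writeTsv(data.frame(protein_id = names(modules), module = modules,
                            kIn = intramodularK(net), hub = net@hub,
                            stability = if (length(stabilityScores(net)))
                                stabilityScores(net) else NA),
                 config$outDir, "module_assignment.tsv"),
        writeTsv(data.frame(module = rownames(eigenproteins(net)),
                            variance_explained = net@varianceExplained,
                            eigenproteins(net), check.names = FALSE),
                 config$outDir, "eigenproteins.tsv"))
    el <- exportEdgeList(net, file.path(config$outDir, "edge_list.tsv"),
                         minAbsR = 0.5)
    artifacts <- c(artifacts, file.path(config$outDir, "edge_list.tsv"))
    nMod <- length(setdiff(unique(modules), 0L))
    summary$stages$network <-
        list(modules = nMod,
             module_sizes = as.list(table(modules[modules > 0L])),
             unassigned = sum(modules == 0L), hubs = sum(net@hub),
             edges_exported = nrow(el))

    ## ---- eigenprotein group tests ----
    stageLog("eigenprotein_tests", "Mann-Whitney vs ", config$referenceGroup)
    blGroups <- info$group[match(sampleIds(baseline), info$sample_id)]
    met <- eigenproteinGroupTests(eigenproteins(net), blGroups,
                                  config$referenceGroup)
    artifacts <- c(artifacts, writeTsv(met, config$outDir,
                                       "eigenprotein_tests.tsv"))
    summary$stages$eigenprotein_tests <-
        list(tests = nrow(met), significant_raw = sum(met$p < 0.05))

    ## ---- differential correlation ----
    geneMap <- if (!is.null(config$geneMapPath))
        readGeneMap(config$geneMapPath) else NULL
    refProf <- groupCorrelationProfiles(baseline, blGroups,
                                        config$referenceGroup,
                                        config$network$minPairwiseN)
    pairsArg <- NULL
    if (config$withinModuleOnly) {
        sameMod <- which(outer(modules, modules, "==") &
                             outer(modules, modules, "*") > 0 &
                             upper.tri(net@correlation), arr.ind = TRUE)
        pairsArg <- data.frame(i = names(modules)[sameMod[, 1L]],
                               j = names(modules)[sameMod[, 2L]])
    }
    dcAll <- list()
    enrAll <- list()
    for (g in setdiff(levels(as.factor(blGroups)), config$referenceGroup)) {
        stageLog("diffcorr", g, " vs ", config$referenceGroup)
        disProf <- groupCorrelationProfiles(baseline, blGroups, g,
                                            config$network$minPairwiseN)
        dc <- differentialCorrelation(refProf$r, refProf$n, disProf$r,
                                      disProf$n, alpha = config$alpha,
                                      pairs = pairsArg)
        dc <- dc[order(dc$p_adj, dc$p), ]
        dcAll[[g]] <- dc
        artifacts <- c(artifacts, writeTsv(dc, config$outDir,
                                           sprintf("diffcorr_%s.tsv", g)))
        ## enrichment of the dyscorrelated foreground against modules
        fgProt <- unique(c(dc$protein_i[dc$significant],
                           dc$protein_j[dc$significant]))
        background <- proteinIds(baseline)
        fg <- fgProt
        modAssign <- modules
        if (!is.null(geneMap)) {
            fg <- abstractToGenes(fgProt, geneMap)
            modAssign <- geneModuleAssignment(modules, geneMap,
                                              intramodularK(net))
            background <- abstractToGenes(background, geneMap)
        }
        if (length(fg)) {
            moduleSets <- lapply(setdiff(sort(unique(modAssign)), 0L),
                                 function(m) names(modAssign)[modAssign == m])
            names(moduleSets) <- paste0("M", setdiff(sort(unique(modAssign)),
                                                     0L))
            enr <- hypergeometricEnrichment(intersect(fg, background),
                                            background, moduleSets,
                                            config$alpha)
            enrAll[[g]] <- enr
            artifacts <- c(artifacts,
                writeTsv(enr, config$outDir,
                         sprintf("diffcorr_enrichment_%s.tsv", g)))
        }
        summary$stages[[paste0("diffcorr_", g)]] <-
            list(pairs_tested = nrow(dc),
                 significant_pairs = sum(dc$significant),
                 proteins_in_significant_pairs = length(fgProt))
    }

    ## ---- longitudinal screen (all visits) ----
    lonRes <- NULL
    nLonSubj <- sum(table(info$subject_id) >= 2L)
    if (nLonSubj >= 2L) {
        stageLog("longitudinal", nLonSubj, " subjects with repeat visits")
        lonRes <- longitudinalScreen(pa, info, alpha = config$alpha)
        lonRes <- lonRes[order(lonRes$p_adj, lonRes$p), ]
        artifacts <- c(artifacts, writeTsv(lonRes, config$outDir,
                                           "longitudinal_screen.tsv"))
        summary$stages$longitudinal <-
            list(fitted = nrow(lonRes),
                 increasing = sum(lonRes$direction == "increasing"),
                 decreasing = sum(lonRes$direction == "decreasing"))
        for (dirn in c("increasing", "decreasing")) {
            fgProt <- lonRes$protein_id[lonRes$direction == dirn]
            if (!length(fgProt)) next
            moduleSets <- lapply(setdiff(sort(unique(modules)), 0L),
                                 function(m) names(modules)[modules == m])
            names(moduleSets) <- paste0("M", setdiff(sort(unique(modules)),
                                                     0L))
            enr <- hypergeometricEnrichment(
                intersect(fgProt, names(modules)), names(modules),
                moduleSets, config$alpha)
            artifacts <- c(artifacts,
                writeTsv(enr, config$outDir,
                         sprintf("longitudinal_enrichment_%s.tsv", dirn)))
        }
    } else stageLog("longitudinal", "skipped: no repeated visits")

    ## ---- optional cross-tabulation ----
    if (!is.null(config$crossAssignmentPath)) {
        stageLog("crosstab", "module preservation vs ",
                 config$crossAssignmentPath)
        other <- utils::read.table(config$crossAssignmentPath, sep = "\t",
                                   header = TRUE, colClasses = c("character",
                                                                 "integer"))
        otherAssign <- structure(other[[2L]], names = other[[1L]])
        ct <- crossTabulation(modules, otherAssign, alpha = config$alpha)
        artifacts <- c(artifacts,
                       writeTsv(ct$records, config$outDir,
                                "crosstab_records.tsv"),
                       writeTsv(data.frame(module_b = rownames(ct$logP),
                                           ct$logP, check.names = FALSE),
                                config$outDir, "crosstab_logp.tsv"))
        summary$stages$crosstab <- list(cells = nrow(ct$records))
    }

    ## ---- summary ----
    summary$config <- list(
        reference_group = config$referenceGroup,
        beta = config$network$beta,
        min_module_size = config$network$minModuleSize,
        merge_cut_height = config$network$mergeCutHeight,
        max_missing_frac = config$maxMissingFrac,
        hub_frac = config$network$hubFrac,
        alpha = config$alpha, outlier_z_cut = config$outlierZCut,
        stability_iter = config$stabilityIter)
    summary$artifacts <- basename(artifacts)
    jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(abundance = pa, network = net, eigenproteinTests = met,
                   differentialCorrelation = dcAll,
                   diffcorrEnrichment = enrAll, longitudinal = lonRes,
                   truth = truth, summary = summary))
}
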