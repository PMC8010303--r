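## Signed weighted correlation network construction: pairwise-complete
## Pearson correlation, soft-threshold adjacency, clustering dissimilarity
## (1 - adjacency, or topological overlap), adaptive tree-cut module
## detection with eigenprotein merging, intramodular connectivity / hubs,
## and leave-one-out module stability.

#' Network construction parameters
#'
#' @param beta soft-threshold power (>= 1, default 7).
#' @param networkSign `"signed"` (adjacency `((1+r)/2)^beta`, default) or
#'   `"unsigned"` (`|r|^beta`).
#' @param dissimilarityMode `"adjacency"` (`1 - a`, default) or `"tom"`
#'   (topological overlap complement).
#' @param linkage hierarchical clustering linkage (default `"average"`).
#' @param minModuleSize smallest retained module (default 5).
#' @param mergeCutHeight eigenprotein-dissimilarity threshold below which
#'   modules are merged (default 0.05).
#' @param minPairwiseN minimum complete pairs for a defined correlation
#'   (default 10).
#' @param hubFrac fraction of each module called hub proteins (default 0.10).
#' @param cutHeightFrac adaptive tree cut: the dendrogram is cut at this
#'   fraction of its maximum merge height (default 0.97).
#' @param staticCutHeight optional absolute cut height overriding
#'   `cutHeightFrac`.
#' @return validated list of class `NetworkConfig`.
#' @export
networkConfig <- function(beta = 7, networkSign = c("signed", "unsigned"),
                          dissimilarityMode = c("adjacency", "tom"),
                          linkage = "average", minModuleSize = 5L,
                          mergeCutHeight = 0.05, minPairwiseN = 10L,
                          hubFrac = 0.10, cutHeightFrac = 0.97,
                          staticCutHeight = NULL) {
    networkSign <- match.arg(networkSign)
    dissimilarityMode <- match.arg(dissimilarityMode)
    stopifnot(beta >= 1, minModuleSize >= 2,
              mergeCutHeight > 0, mergeCutHeight < 1,
              minPairwiseN >= 2, hubFrac > 0, hubFrac <= 1,
              cutHeightFrac > 0, cutHeightFrac <= 1)
    structure(list(beta = beta, networkSign = networkSign,
                   dissimilarityMode = dissimilarityMode, linkage = linkage,
                   minModuleSize = as.integer(minModuleSize),
                   mergeCutHeight = mergeCutHeight,
                   minPairwiseN = as.integer(minPairwiseN),
                   hubFrac = hubFrac, cutHeightFrac = cutHeightFrac,
                   staticCutHeight = staticCutHeight),
              class = "NetworkConfig")
}

asValues <- function(x) {
    if (is(x, "ProteinAbundance")) abundanceValues(x) else as.matrix(x)
}

#' Pairwise-complete Pearson correlation with complete-pair counts
#'
#' Correlations computed over samples where both proteins are observed.
#' Entries with fewer than `minPairwiseN` complete pairs, or involving a
#' protein with zero variance over its observed samples, are flagged
#' undefined (`NA` in `r`); they enter adjacency as r = 0 (with a warning).
#'
#' @param x [ProteinAbundance-class] or proteins x samples matrix.
#' @param minPairwiseN minimum complete pairs (default 10).
#' @return list with `r` (correlations, `NA` = undefined), `n`
#'   (complete-pair counts) and `undefined` (logical matrix).
#' @export
pairwiseCorrelation <- function(x, minPairwiseN = 10L) {
    v <- asValues(x)
    if (ncol(v) < minPairwiseN)
        stop("fewer samples than minPairwiseN")
    r <- suppressWarnings(stats::cor(t(v), use = "pairwise.complete.obs"))
    obs <- (!is.na(v)) * 1
    n <- tcrossprod(obs)
    storage.mode(n) <- "integer"
    undefined <- is.na(r) | n < minPairwiseN
    diag(undefined) <- FALSE
    r[undefined] <- NA_real_
    diag(r) <- 1
    list(r = r, n = n, undefined = undefined)
}

#' Soft-threshold adjacency from a correlation matrix
#'
#' Signed: `a = ((1 + r) / 2)^beta`; unsigned: `a = |r|^beta`. Undefined
#' correlations (`NA`) are given the neutral weight of r = 0, with a warning
#' stating how many.
#'
#' @param r correlation matrix in `[-1, 1]` (NA allowed off-diagonal).
#' @param beta soft-threshold power (default 7).
#' @param networkSign `"signed"` (default) or `"unsigned"`.
#' @return adjacency matrix with entries in `[0, 1]` and unit diagonal.
#' @export
signedAdjacency <- function(r, beta = 7,
                            networkSign = c("signed", "unsigned")) {
    networkSign <- match.arg(networkSign)
    stopifnot(all(abs(r) <= 1, na.rm = TRUE), beta >= 1)
    nUndef <- sum(is.na(r))
    if (nUndef > 0L) {
        warning(nUndef, " undefined correlation(s) entered adjacency as r = 0")
        r[is.na(r)] <- 0
    }
    a <- if (networkSign == "signed") ((1 + r) / 2)^beta else abs(r)^beta
    diag(a) <- 1
    a
}

#' Clustering dissimilarity from an adjacency matrix
#'
#' `mode = "adjacency"`: `d = 1 - a`. `mode = "tom"`: topological overlap
#' `t_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `k_i = sum_{u != i} a_iu`, and `d = 1 - t`.
#'
#' @param a adjacency matrix (entries in `[0, 1]`, unit diagonal).
#' @param mode `"adjacency"` (default) or `"tom"`.
#' @return dissimilarity matrix with zero diagonal.
#' @export
networkDissimilarity <- function(a, mode = c("adjacency", "tom")) {
    mode <- match.arg(mode)
    if (mode == "adjacency") {
        d <- 1 - a
    } else {
        k <- rowSums(a) - 1
        shared <- a %*% a - 2 * a          # sum over u != i,j of a_iu a_uj
        t <- (shared + a) / (outer(k, k, pmin) + 1 - a)
        diag(t) <- 1
        d <- 1 - t
    }
    diag(d) <- 0
    d
}

relabelBySize <- function(modules) {
    labs <- setdiff(sort(unique(modules)), 0L)
    if (!length(labs)) return(modules)
    sizes <- vapply(labs, function(l) sum(modules == l), 0L)
    ord <- labs[order(-sizes, labs)]
    out <- integer(length(modules))
    out[modules > 0L] <- match(modules[modules > 0L], ord)
    names(out) <- names(modules)
    out
}

#' Detect co-correlation modules by adaptive tree cut and eigenprotein merge
#'
#' Average-linkage (configurable) hierarchical clustering of the
#' dissimilarity; the tree is cut adaptively at `cutHeightFrac` of its
#' maximum merge height (or at `staticCutHeight` if given), clusters of at
#' least `minModuleSize` proteins become initial modules and smaller ones
#' are left unassigned (label 0). Modules whose eigenproteins have
#' dissimilarity (1 - Pearson r) below `mergeCutHeight` are then merged
#' iteratively, recomputing eigenproteins after each merge. Final labels are
#' 1..M by decreasing module size.
#'
#' @param d dissimilarity matrix.
#' @param values proteins x samples matrix (or [ProteinAbundance-class])
#'   used to compute eigenproteins during merging.
#' @param minModuleSize,mergeCutHeight,linkage,cutHeightFrac,staticCutHeight
#'   see [networkConfig()].
#' @return list with `dendrogram` (`hclust`), `modules` (named integer
#'   vector, 0 = unassigned) and `cutHeight` used.
#' @export
detectModules <- function(d, values, minModuleSize = 5L,
                          mergeCutHeight = 0.05, linkage = "average",
                          cutHeightFrac = 0.97, staticCutHeight = NULL) {
    v <- asValues(values)
    stopifnot(nrow(v) == nrow(d))
    hc <- stats::hclust(stats::as.dist(d), method = linkage)
    cutH <- if (is.null(staticCutHeight)) cutHeightFrac * max(hc$height)
            else staticCutHeight
    if (nrow(d) < minModuleSize) {
        modules <- structure(rep(0L, nrow(d)), names = rownames(d))
        return(list(dendrogram = hc, modules = modules, cutHeight = cutH))
    }
    cl <- stats::cutree(hc, h = cutH)
    sizes <- table(cl)
    keep <- as.integer(names(sizes)[sizes >= minModuleSize])
    modules <- ifelse(cl %in% keep, cl, 0L)
    names(modules) <- rownames(d)
    ## iterative eigenprotein merge
    repeat {
        labs <- setdiff(sort(unique(modules)), 0L)
        if (length(labs) < 2L) break
        eig <- moduleEigenproteins(v, modules)$eigenproteins
        cors <- stats::cor(t(eig))
        diag(cors) <- -Inf
        best <- which(cors == max(cors), arr.ind = TRUE)[1L, ]
        if (1 - max(cors) >= mergeCutHeight) break
        from <- labs[max(best)]; to <- labs[min(best)]
        modules[modules == from] <- to
    }
    list(dendrogram = hc, modules = relabelBySize(modules), cutHeight = cutH)
}

#' Module eigenproteins (first principal components)
#'
#' Each member protein is imputed at its own median (missing values only)
#' and standardized to mean 0 / variance 1 over samples; the eigenprotein is
#' the module's first principal-component score vector, scaled to unit
#' variance, with sign chosen so that its correlation with the module's mean
#' standardized profile is non-negative. Variance explained is the first
#' eigenvalue's fraction of the total.
#'
#' @param values proteins x samples matrix (or [ProteinAbundance-class]).
#' @param modules named integer module assignment (0 = unassigned).
#' @return list with `eigenproteins` (modules x samples matrix, rows
#'   `ME<label>`) and `varianceExplained` (named numeric).
#' @export
moduleEigenproteins <- function(values, modules) {
    v <- asValues(values)
    labs <- setdiff(sort(unique(modules)), 0L)
    if (!length(labs))
        return(list(eigenproteins = matrix(0, 0, ncol(v),
                                           dimnames = list(NULL, colnames(v))),
                    varianceExplained = numeric()))
    eig <- matrix(NA_real_, length(labs), ncol(v),
                  dimnames = list(paste0("ME", labs), colnames(v)))
    ve <- structure(numeric(length(labs)), names = paste0("ME", labs))
    for (k in seq_along(labs)) {
        xm <- v[modules == labs[k], , drop = FALSE]
        if (nrow(xm) < 2L)
            stop("module ", labs[k], " has fewer than 2 proteins")
        for (i in seq_len(nrow(xm))) {
            xi <- xm[i, ]
            if (anyNA(xi)) xi[is.na(xi)] <- stats::median(xi, na.rm = TRUE)
            s <- stats::sd(xi)
            if (!is.finite(s) || s == 0)
                stop("constant protein in module ", labs[k], ": ",
                     rownames(xm)[i])
            xm[i, ] <- (xi - mean(xi)) / s
        }
        sv <- svd(xm)
        scores <- sv$v[, 1L]
        scores <- scores / stats::sd(scores)
        meanProfile <- colMeans(xm)
        if (stats::sd(meanProfile) > 0 &&
            stats::cor(scores, meanProfile) < 0)
            scores <- -scores
        eig[k, ] <- scores
        ve[k] <- sv$d[1L]^2 / sum(sv$d^2)
    }
    list(eigenproteins = eig, varianceExplained = ve)
}

#' Intramodular connectivity and hub proteins
#'
#' `kIn_i` is the summed adjacency of protein i to the other members of its
#' module (0 for unassigned proteins). Within each module the
#' `ceiling(hubFrac * size)` proteins with largest kIn are hubs; ties at the
#' cutoff are broken by protein id order. Unassigned proteins are never
#' hubs.
#'
#' @param a adjacency matrix.
#' @param modules named integer module assignment.
#' @param hubFrac hub fraction per module (default 0.10).
#' @return list with `kIn` (named numeric) and `hub` (named logical).
#' @export
intramodularConnectivity <- function(a, modules, hubFrac = 0.10) {
    ids <- names(modules)
    kIn <- structure(numeric(length(modules)), names = ids)
    hub <- structure(logical(length(modules)), names = ids)
    for (lab in setdiff(unique(modules), 0L)) {
        idx <- which(modules == lab)
        am <- a[idx, idx, drop = FALSE]
        kIn[idx] <- rowSums(am) - 1      # exclude the unit self-adjacency
        nHub <- ceiling(hubFrac * length(idx))
        ord <- idx[order(-kIn[idx], ids[idx])]
        hub[ord[seq_len(nHub)]] <- TRUE
    }
    list(kIn = kIn, hub = hub)
}

jaccard <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) return(0)
    length(intersect(a, b)) / u
}

mapModuleLabels <- function(refModules, iterModules) {
    refLabs <- setdiff(unique(refModules), 0L)
    itLabs <- setdiff(unique(iterModules), 0L)
    mapping <- structure(rep(-1L, length(itLabs)), names = itLabs)
    if (length(refLabs) && length(itLabs)) {
        J <- outer(itLabs, refLabs, Vectorize(function(i, r)
            jaccard(names(iterModules)[iterModules == i],
                    names(refModules)[refModules == r])))
        repeat {
            if (all(J < 0)) break
            best <- which(J == max(J), arr.ind = TRUE)[1L, ]
            if (J[best[1L], best[2L]] <= 0) break
            mapping[as.character(itLabs[best[1L]])] <- refLabs[best[2L]]
            J[best[1L], ] <- -1; J[, best[2L]] <- -1
        }
    }
    mapped <- integer(length(iterModules))
    pos <- iterModules > 0L
    mapped[pos] <- mapping[as.character(iterModules[pos])]
    names(mapped) <- names(iterModules)
    mapped
}

#' Leave-one-out module stability
#'
#' For each iteration one uniformly random sample is dropped, the network is
#' rebuilt with the identical configuration, iteration modules are matched
#' to the reference modules (built on all samples) by greedy
#' maximum-Jaccard label matching (unmatched iteration modules map to "no
#' match"), and each protein is scored as matched when its mapped label
#' equals its reference label (unassigned matches unassigned). The stability
#' score is the per-protein fraction of matched iterations. Deterministic
#' given `seed`.
#'
#' @param x [ProteinAbundance-class] or proteins x samples matrix with at
#'   least 5 samples.
#' @param config a [networkConfig()].
#' @param nIter number of leave-one-out iterations (>= 1).
#' @param seed integer seed.
#' @param refModules optional reference assignment; computed from all
#'   samples when NULL.
#' @return named numeric vector of per-protein stability in `[0, 1]`.
#' @export
moduleStability <- function(x, config = networkConfig(), nIter = 20L,
                            seed = 1L, refModules = NULL) {
    v <- asValues(x)
    if (ncol(v) < 5L) stop("need at least 5 samples")
    if (nIter < 1L) stop("nIter must be >= 1")
    buildModules <- function(vals) {
        pc <- pairwiseCorrelation(vals, config$minPairwiseN)
        a <- suppressWarnings(
            signedAdjacency(pc$r, config$beta, config$networkSign))
        d <- networkDissimilarity(a, config$dissimilarityMode)
        detectModules(d, vals, config$minModuleSize, config$mergeCutHeight,
                      config$linkage, config$cutHeightFrac,
                      config$staticCutHeight)$modules
    }
    if (is.null(refModules)) refModules <- buildModules(v)
    withSeed(seed, {
        agree <- matrix(FALSE, nrow(v), nIter)
        for (it in seq_len(nIter)) {
            dropJ <- sample.int(ncol(v), 1L)
            mods <- buildModules(v[, -dropJ, drop = FALSE])
            mapped <- mapModuleLabels(refModules, mods)
            agree[, it] <- mapped == refModules
        }
        structure(rowMeans(agree), names = rownames(v))
    })
}

#' Build the full correlation network
#'
#' Runs [pairwiseCorrelation()], [signedAdjacency()],
#' [networkDissimilarity()], [detectModules()], [moduleEigenproteins()] and
#' [intramodularConnectivity()], optionally followed by [moduleStability()],
#' and assembles a [CorrelationNetwork-class].
#'
#' @param x [ProteinAbundance-class] or proteins x samples matrix (log
#'   scale, normalized).
#' @param config a [networkConfig()].
#' @param stabilityIter leave-one-out iterations (0 = skip stability).
#' @param seed seed for the stability resampling.
#' @return a [CorrelationNetwork-class].
#' @export
buildNetwork <- function(x, config = networkConfig(), stabilityIter = 0L,
                         seed = 1L) {
    v <- asValues(x)
    pc <- pairwiseCorrelation(v, config$minPairwiseN)
    a <- signedAdjacency(pc$r, config$beta, config$networkSign)
    d <- networkDissimilarity(a, config$dissimilarityMode)
    det <- detectModules(d, v, config$minModuleSize, config$mergeCutHeight,
                         config$linkage, config$cutHeightFrac,
                         config$staticCutHeight)
    eig <- moduleEigenproteins(v, det$modules)
    conn <- intramodularConnectivity(a, det$modules, config$hubFrac)
    stab <- if (stabilityIter > 0L)
        moduleStability(v, config, stabilityIter, seed,
                        refModules = det$modules)
    else numeric()
    new("CorrelationNetwork", proteinIds = rownames(v),
        correlation = pc$r, nPairs = pc$n, adjacency = a, dissimilarity = d,
        dendrogram = det$dendrogram, modules = det$modules,
        eigenproteins = eig$eigenproteins,
        varianceExplained = eig$varianceExplained,
        kIn = conn$kIn, hub = conn$hub, stability = stab,
        config = unclass(config))
}

#' Export the network edge list as delimited text
#'
#' One row per protein pair (upper triangle), filtered by an absolute
#' correlation and/or BH-adjusted correlation-test p-value threshold;
#' suitable for external graph tools.
#'
#' @param net a [CorrelationNetwork-class].
#' @param path output TSV path (NULL returns the data.frame only).
#' @param minAbsR keep edges with `|r| >=` this value (default 0, keep all).
#' @param maxAdjP keep edges with BH-adjusted correlation p below this
#'   (default NULL = no p filter).
#' @return invisibly, the edge data.frame.
#' @export
exportEdgeList <- function(net, path = NULL, minAbsR = 0, maxAdjP = NULL) {
    r <- net@correlation; n <- net@nPairs; a <- net@adjacency
    ut <- upper.tri(r)
    idx <- which(ut, arr.ind = TRUE)
    df <- data.frame(protein_a = net@proteinIds[idx[, 1L]],
                     protein_b = net@proteinIds[idx[, 2L]],
                     r = r[ut], n = n[ut], adjacency = a[ut])
    df <- df[!is.na(df$r), ]
    tt <- abs(df$r) * sqrt((df$n - 2) / pmax(1 - df$r^2, 1e-300))
    df$p_adj <- stats::p.adjust(2 * stats::pt(-tt, df$n - 2), "BH")
    keep <- abs(df$r) >= minAbsR
    if (!is.null(maxAdjP)) keep <- keep & df$p_adj < maxAdjP
    df <- df[keep, ]
    if (!is.null(path))
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(df)
}
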