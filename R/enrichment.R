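## Hypergeometric set enrichment (module membership or user gene sets) and
## cross-tabulation module preservation between two networks.

#' Abstract protein identifiers to gene symbols
#'
#' Many-to-one mapping with deduplication; unmapped ids are dropped and
#' counted (attribute `"dropped"`).
#'
#' @param ids character vector of protein ids.
#' @param geneMap named character vector (`geneMap[protein_id] = gene`), as
#'   from [readGeneMap()].
#' @return character vector of unique gene symbols.
#' @export
abstractToGenes <- function(ids, geneMap) {
    genes <- geneMap[ids]
    dropped <- sum(is.na(genes))
    if (dropped > 0L)
        message(dropped, " id(s) without gene mapping dropped")
    out <- unique(unname(genes[!is.na(genes)]))
    attr(out, "dropped") <- dropped
    out
}

#' Gene-level module assignment
#'
#' Genes inherit the module of their protein; when a gene's proteins span
#' modules it is assigned to the module of its highest-kIn protein.
#'
#' @param modules named integer protein module assignment.
#' @param geneMap named character vector protein -> gene.
#' @param kIn named numeric intramodular connectivity (used only to break
#'   multi-module genes; optional, defaults to 0).
#' @return named integer vector gene -> module.
#' @export
geneModuleAssignment <- function(modules, geneMap, kIn = NULL) {
    ids <- intersect(names(modules), names(geneMap))
    if (is.null(kIn)) kIn <- structure(numeric(length(ids)), names = ids)
    df <- data.frame(gene = unname(geneMap[ids]), module = modules[ids],
                     kIn = kIn[ids], stringsAsFactors = FALSE)
    df <- df[order(df$gene, -df$kIn), ]
    df <- df[!duplicated(df$gene), ]
    structure(df$module, names = df$gene)
}

#' Hypergeometric enrichment of a foreground list against gene sets
#'
#' For each set (intersected with the background first), with
#' `N = |background|`, `K = |set|`, `n = |foreground|` and
#' `a = |foreground intersect set|`: upper-tail
#' `p = P(X >= a)`, `X ~ Hypergeometric(N, K, n)`. The odds ratio is the
#' sample odds ratio of the 2x2 table, with 0.5 added to every cell when any
#' cell is zero (Haldane-Anscombe). BH adjustment is applied across sets.
#'
#' @param foreground character vector, a subset of `background`.
#' @param background character vector (the tested universe).
#' @param sets named list of character vectors.
#' @param alpha BH significance threshold (default 0.1).
#' @return data.frame with 2x2 counts, odds ratio, raw and adjusted p and a
#'   `significant` flag, one row per set.
#' @export
hypergeometricEnrichment <- function(foreground, background, sets,
                                     alpha = 0.1) {
    foreground <- unique(foreground); background <- unique(background)
    if (!all(foreground %in% background))
        stop("foreground must be a subset of the background")
    N <- length(background); n <- length(foreground)
    out <- do.call(rbind, lapply(names(sets), function(id) {
        s <- intersect(sets[[id]], background)
        K <- length(s)
        a <- length(intersect(foreground, s))
        b <- n - a; cc <- K - a; d <- N - a - b - cc
        p <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
        cells <- c(a, b, cc, d)
        if (any(cells == 0)) cells <- cells + 0.5
        or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
        data.frame(set_id = id, a = a, b = b, c = cc, d = d,
                   odds_ratio = or, p = p, stringsAsFactors = FALSE)
    }))
    out$p_adj <- bhAdjust(out$p)
    out$significant <- out$p_adj < alpha
    rownames(out) <- NULL
    out
}

#' Cross-tabulation module preservation between two networks
#'
#' On the identifier intersection of two module assignments (optionally
#' after gene abstraction), every (module of A) x (module of B) cell is
#' tested by hypergeometric enrichment with the shared identifiers as
#' background; BH adjustment runs across all cells.
#'
#' @param assignmentA,assignmentB named integer module assignments
#'   (0 = unassigned; unassigned ids stay in the background but form no
#'   foreground/set).
#' @param geneMapA,geneMapB optional protein -> gene maps applied before
#'   intersecting (see [geneModuleAssignment()]).
#' @param alpha BH significance threshold (default 0.1).
#' @return list with `records` (long-format data.frame, one row per module
#'   pair) and `logP` (modules of B x modules of A matrix of -log10 raw p).
#' @export
crossTabulation <- function(assignmentA, assignmentB,
                            geneMapA = NULL, geneMapB = NULL, alpha = 0.1) {
    if (!is.null(geneMapA))
        assignmentA <- geneModuleAssignment(assignmentA, geneMapA)
    if (!is.null(geneMapB))
        assignmentB <- geneModuleAssignment(assignmentB, geneMapB)
    shared <- intersect(names(assignmentA), names(assignmentB))
    if (!length(shared))
        stop("no shared identifiers between the two assignments")
    a <- assignmentA[shared]; b <- assignmentB[shared]
    labsA <- setdiff(sort(unique(a)), 0L)
    labsB <- setdiff(sort(unique(b)), 0L)
    records <- do.call(rbind, lapply(labsA, function(i) {
        fg <- shared[a == i]
        setsB <- lapply(labsB, function(j) shared[b == j])
        names(setsB) <- paste0("B", labsB)
        rec <- hypergeometricEnrichment(fg, shared, setsB, alpha)
        data.frame(module_a = i, module_b = labsB, rec[, -1L],
                   stringsAsFactors = FALSE)
    }))
    records$p_adj <- bhAdjust(records$p)
    records$significant <- records$p_adj < alpha
    rownames(records) <- NULL
    logP <- matrix(NA_real_, length(labsB), length(labsA),
                   dimnames = list(paste0("B", labsB), paste0("A", labsA)))
    logP[cbind(match(records$module_b, labsB),
               match(records$module_a, labsA))] <- -log10(records$p)
    list(records = records, logP = logP)
}
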