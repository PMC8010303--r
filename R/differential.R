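## Module-phenotype testing (Mann-Whitney U on eigenproteins) and
## differential correlation between a disease group and the reference group
## via Fisher's r-to-z, with BH step-up multiple-testing adjustment.

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1,
#' returned in input order.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

mannWhitney <- function(x, y) {
    ## exact null when both groups are small and tie-free; otherwise normal
    ## approximation with tie and continuity correction. All-tied data carry
    ## no evidence: p = 1.
    if (length(unique(c(x, y))) == 1L)
        return(list(U = length(x) * length(y) / 2, p = 1))
    exact <- length(x) <= 12L && length(y) <= 12L &&
        !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Compare module eigenprotein expression between groups
#'
#' Two-sided Mann-Whitney U tests of each module's eigenprotein, each
#' non-reference group against the reference group only. The exact null
#' distribution is used when both group sizes are at most 12 with no ties;
#' otherwise the normal approximation with tie and continuity correction.
#' Raw p-values are reported (the test family is small).
#'
#' @param eigenproteins modules x samples matrix (rows `ME<k>`).
#' @param groups per-sample group labels (factor or character), aligned with
#'   the eigenprotein columns.
#' @param referenceGroup name of the reference (control) group.
#' @return data.frame with one row per (module, group) comparison: medians,
#'   U statistic and two-sided p.
#' @export
eigenproteinGroupTests <- function(eigenproteins, groups, referenceGroup) {
    groups <- as.factor(groups)
    stopifnot(length(groups) == ncol(eigenproteins),
              referenceGroup %in% levels(groups))
    if (any(table(groups) < 2L)) stop("every group needs >= 2 samples")
    others <- setdiff(levels(groups), referenceGroup)
    ref <- groups == referenceGroup
    out <- do.call(rbind, lapply(rownames(eigenproteins), function(me) {
        do.call(rbind, lapply(others, function(g) {
            x <- eigenproteins[me, groups == g]
            y <- eigenproteins[me, ref]
            mw <- mannWhitney(x, y)
            data.frame(module = me, group = g,
                       reference = referenceGroup,
                       median_group = stats::median(x),
                       median_reference = stats::median(y),
                       U = mw$U, p = mw$p, stringsAsFactors = FALSE)
        }))
    }))
    rownames(out) <- NULL
    out
}

#' Within-group pairwise correlation profile
#'
#' [pairwiseCorrelation()] restricted to one group's samples.
#'
#' @param x [ProteinAbundance-class] or proteins x samples matrix.
#' @param groups per-sample group labels.
#' @param group the group to profile.
#' @param minPairwiseN minimum complete pairs (default 10).
#' @return list with `r` and `n` matrices (see [pairwiseCorrelation()]).
#' @export
groupCorrelationProfiles <- function(x, groups, group, minPairwiseN = 10L) {
    v <- asValues(x)
    groups <- as.factor(groups)
    stopifnot(length(groups) == ncol(v))
    idx <- which(groups == group)
    if (length(idx) < minPairwiseN)
        stop("group ", group, " has fewer than minPairwiseN samples")
    pairwiseCorrelation(v[, idx, drop = FALSE], minPairwiseN)
}

#' Differential correlation between two groups via Fisher's r-to-z
#'
#' For each protein pair with defined correlations in both groups and more
#' than 3 complete pairs per group:
#' `Z = (atanh(r_ref) - atanh(r_dis)) / sqrt(1/(n_ref - 3) + 1/(n_dis - 3))`
#' with two-sided standard-normal p, BH-adjusted over all tested pairs.
#' Pairs failing the preconditions are skipped (counted in the
#' `"skipped"` attribute). The full record set is returned, with records at
#' adjusted p below `alpha` flagged significant.
#'
#' @param rRef,nRef reference-group correlation and complete-pair count
#'   matrices (as from [groupCorrelationProfiles()]).
#' @param rDis,nDis same for the disease group.
#' @param alpha BH significance threshold (default 0.1).
#' @param pairs optional two-column matrix/data.frame of protein id pairs to
#'   test (default: all upper-triangle pairs).
#' @return data.frame with per-pair correlations, Fisher transforms, Z, raw
#'   and BH-adjusted p, and a `significant` flag.
#' @export
differentialCorrelation <- function(rRef, nRef, rDis, nDis, alpha = 0.1,
                                    pairs = NULL) {
    stopifnot(identical(dim(rRef), dim(rDis)),
              identical(rownames(rRef), rownames(rDis)))
    ids <- rownames(rRef)
    if (is.null(pairs)) {
        idx <- which(upper.tri(rRef), arr.ind = TRUE)
    } else {
        idx <- cbind(match(pairs[[1L]], ids), match(pairs[[2L]], ids))
    }
    rr <- rRef[idx]; rd <- rDis[idx]
    nr <- nRef[idx]; nd <- nDis[idx]
    ok <- !is.na(rr) & !is.na(rd) & nr > 3L & nd > 3L
    nSkipped <- sum(!ok)
    idx <- idx[ok, , drop = FALSE]
    rr <- rr[ok]; rd <- rd[ok]; nr <- nr[ok]; nd <- nd[ok]
    clamp <- function(r) pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    zr <- atanh(clamp(rr)); zd <- atanh(clamp(rd))
    Z <- (zr - zd) / sqrt(1 / (nr - 3) + 1 / (nd - 3))
    p <- 2 * stats::pnorm(-abs(Z))
    padj <- bhAdjust(p)
    out <- data.frame(protein_i = ids[idx[, 1L]], protein_j = ids[idx[, 2L]],
                      r_ref = rr, n_ref = nr, r_dis = rd, n_dis = nd,
                      z_ref = zr, z_dis = zd, Z = Z, p = p, p_adj = padj,
                      significant = padj < alpha, stringsAsFactors = FALSE)
    attr(out, "skipped") <- nSkipped
    out
}
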