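## Normalization, group-wise missingness filtering and outlier-sample
## detection. The normalization reproduces a "robust mean"-style scheme:
## per-sample centering to the median of a low-variance background protein
## set, then per-sample scaling by the (unscaled) median absolute deviation
## of the same background.

#' Natural-log transform a linear-scale abundance matrix
#'
#' @param x a [ProteinAbundance-class] on the linear scale with all observed
#'   values strictly positive.
#' @return the object with `log()`-transformed values and scale `"log"`;
#'   missingness is untouched.
#' @export
logTransform <- function(x) {
    stopifnot(is(x, "ProteinAbundance"))
    if (abundanceScale(x) != "linear")
        stop("logTransform expects a linear-scale matrix")
    v <- abundanceValues(x)
    if (any(v[!is.na(v)] <= 0))
        stop("non-positive abundance value(s); cannot log-transform")
    assay(x, "abundance") <- log(v)
    x@abundanceScale <- "log"
    validObject(x)
    x
}

sampleGroups <- function(x, groups = NULL) {
    if (is.null(groups)) {
        if (!"group" %in% colnames(colData(x)))
            stop("no group labels: supply `groups` or attach sample metadata")
        groups <- colData(x)$group
    }
    groups <- as.factor(groups)
    if (length(groups) != ncol(x))
        stop("`groups` must have one label per sample")
    if (any(table(groups) == 0L)) groups <- droplevels(groups)
    groups
}

#' Remove proteins with excessive missingness in any group
#'
#' A protein is excluded iff its missing fraction is strictly greater than
#' `maxFrac` in at least one sample group.
#'
#' @param x a [ProteinAbundance-class].
#' @param groups per-sample group labels; defaults to `colData(x)$group`.
#' @param maxFrac maximum tolerated per-group missing fraction (default 0.5).
#' @return list with `abundance` (filtered) and `report` (data.frame of
#'   excluded proteins with worst-group missing fractions).
#' @export
filterMissingByGroup <- function(x, groups = NULL, maxFrac = 0.5) {
    groups <- sampleGroups(x, groups)
    v <- abundanceValues(x)
    fracs <- vapply(levels(groups), function(g)
        rowMeans(is.na(v[, groups == g, drop = FALSE])),
        numeric(nrow(v)))
    worst <- apply(fracs, 1L, max)
    drop <- worst > maxFrac
    report <- data.frame(protein_id = rownames(v)[drop],
                         worst_group = levels(groups)[
                             apply(fracs[drop, , drop = FALSE], 1L,
                                   which.max)],
                         missing_frac = worst[drop],
                         row.names = NULL)
    list(abundance = x[!drop, ], report = report)
}

#' Select the low-variance background protein set
#'
#' The `floor(frac * P)` proteins with the smallest variance of observed
#' values across samples; ties at the cutoff are broken by lexicographic
#' protein id.
#'
#' @param x a [ProteinAbundance-class] with at least 2 proteins and 2
#'   samples.
#' @param frac background fraction (default 0.9).
#' @return character vector of background protein ids.
#' @export
selectBackground <- function(x, frac = 0.9) {
    v <- abundanceValues(x)
    if (nrow(v) < 2L) stop("need at least 2 proteins")
    if (ncol(v) < 2L) stop("need at least 2 samples")
    vars <- apply(v, 1L, stats::var, na.rm = TRUE)
    ord <- order(vars, rownames(v))
    rownames(v)[ord[seq_len(floor(frac * nrow(v)))]]
}

#' Center and scale each sample against the background proteins
#'
#' Per sample: subtract the median of its observed background values, then
#' divide by the median absolute deviation (from that median, without the
#' 1.4826 consistency factor) of the observed background values. Afterwards
#' every sample has background median exactly 0 and background MAD exactly 1.
#' The alternative per-protein axis (center/scale each protein across
#' samples) is available via `axis = "protein"`.
#'
#' @param x a log-scale [ProteinAbundance-class].
#' @param background character vector of background protein ids (subset of
#'   `proteinIds(x)`); each sample must have at least 3 observed background
#'   values.
#' @param axis `"sample"` (default) or `"protein"`.
#' @return list with `abundance` (normalized) and `report` (data.frame of
#'   per-sample/protein offsets and scale factors).
#' @export
normalizeAbundance <- function(x, background, axis = c("sample", "protein")) {
    axis <- match.arg(axis)
    stopifnot(is(x, "ProteinAbundance"))
    if (abundanceScale(x) != "log")
        stop("normalizeAbundance expects log-scale values")
    v <- abundanceValues(x)
    if (axis == "protein") {
        offsets <- apply(v, 1L, stats::median, na.rm = TRUE)
        scales <- apply(abs(v - offsets), 1L, stats::median, na.rm = TRUE)
        if (any(scales == 0, na.rm = TRUE))
            stop("protein(s) with zero MAD: ",
                 paste(rownames(v)[which(scales == 0)], collapse = ", "))
        assay(x, "abundance") <- (v - offsets) / scales
        report <- data.frame(protein_id = rownames(v), offset = offsets,
                             scale_factor = scales, row.names = NULL)
        return(list(abundance = x, report = report))
    }
    if (!all(background %in% rownames(v)))
        stop("background ids not in the matrix")
    bg <- v[background, , drop = FALSE]
    nObs <- colSums(!is.na(bg))
    if (any(nObs < 3L))
        stop("sample(s) with fewer than 3 observed background values: ",
             paste(colnames(v)[nObs < 3L], collapse = ", "))
    offsets <- apply(bg, 2L, stats::median, na.rm = TRUE)
    scales <- apply(abs(sweep(bg, 2L, offsets)), 2L, stats::median,
                    na.rm = TRUE)
    if (any(scales == 0))
        stop("sample(s) with zero background MAD: ",
             paste(colnames(v)[scales == 0], collapse = ", "))
    assay(x, "abundance") <- sweep(sweep(v, 2L, offsets), 2L, scales, "/")
    report <- data.frame(sample_id = colnames(v), offset = offsets,
                         scale_factor = scales, row.names = NULL)
    list(abundance = x, report = report)
}

#' Flag outlier samples by hierarchical clustering of inter-sample distances
#'
#' Samples are clustered on Euclidean distance over shared-observed proteins
#' (missing-aware, rescaled as in [stats::dist()]); a sample is flagged iff
#' the robust z-score (median/MAD) of its mean distance to all other samples
#' exceeds `zCut`. Only positive deviations flag: unusually central samples
#' (e.g. duplicates) never do.
#'
#' @param x a [ProteinAbundance-class] with at least 4 samples.
#' @param linkage linkage for the reported dendrogram (default "average").
#' @param zCut robust z-score threshold (default 3).
#' @return list with `outliers` (character vector of flagged sample ids),
#'   `abundance` (with flagged samples removed), `report` (per-sample mean
#'   distance and robust z) and `dendrogram` (an `hclust`).
#' @export
detectOutlierSamples <- function(x, linkage = "average", zCut = 3.0) {
    if (ncol(x) < 4L) stop("need at least 4 samples")
    v <- abundanceValues(x)
    d <- stats::dist(t(v))
    dm <- as.matrix(d)
    meanDist <- rowSums(dm) / (ncol(x) - 1L)
    med <- stats::median(meanDist)
    madv <- stats::mad(meanDist)
    z <- if (madv > 0) (meanDist - med) / madv else rep(0, length(meanDist))
    flagged <- colnames(v)[z > zCut]
    report <- data.frame(sample_id = colnames(v), mean_distance = meanDist,
                         robust_z = z, flagged = z > zCut, row.names = NULL)
    list(outliers = flagged,
         abundance = x[, setdiff(colnames(v), flagged)],
         report = report,
         dendrogram = stats::hclust(d, method = linkage))
}
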