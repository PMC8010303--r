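#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   colData colData<- rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' ProteinAbundance: a proteins x samples abundance matrix
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' `"abundance"` assay (proteins in rows, samples in columns) plus a scale
#' flag declaring whether values are on the linear (raw, strictly positive)
#' or natural-log scale. Missing values are `NA` in the assay.
#'
#' @slot abundanceScale `"linear"` or `"log"`.
#' @export
setClass("ProteinAbundance",
         contains = "SummarizedExperiment",
         representation(abundanceScale = "character"))

setValidity("ProteinAbundance", function(object) {
    msg <- character()
    if (length(object@abundanceScale) != 1L ||
        !object@abundanceScale %in% c("linear", "log"))
        msg <- c(msg, "abundanceScale must be \"linear\" or \"log\"")
    if (!"abundance" %in% names(assays(object)))
        msg <- c(msg, "assay \"abundance\" is required")
    pid <- rownames(object); sid <- colnames(object)
    if (is.null(pid) || anyDuplicated(pid))
        msg <- c(msg, "protein ids must be present and unique")
    if (is.null(sid) || anyDuplicated(sid))
        msg <- c(msg, "sample ids must be present and unique")
    if (length(msg) == 0L && identical(object@abundanceScale, "linear")) {
        v <- assay(object, "abundance")
        if (any(v[!is.na(v)] <= 0))
            msg <- c(msg, "linear-scale abundances must be > 0")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ProteinAbundance object
#'
#' @param values numeric matrix, proteins in rows, samples in columns, with
#'   `NA` for missing values. Must carry unique dimnames (or pass
#'   `proteinIds`/`sampleIds`).
#' @param scale `"linear"` (strictly positive raw abundances) or `"log"`
#'   (natural-log abundances).
#' @param proteinIds,sampleIds optional identifier vectors overriding the
#'   matrix dimnames.
#' @param sampleInfo optional data.frame of per-sample metadata
#'   (see [readSampleInfo()]) used to populate `colData`.
#' @return A [ProteinAbundance-class] object.
#' @examples
#' m <- matrix(rlnorm(6), 3, 2,
#'             dimnames = list(paste0("P", 1:3), paste0("S", 1:2)))
#' pa <- ProteinAbundance(m, scale = "linear")
#' @export
ProteinAbundance <- function(values, scale = c("linear", "log"),
                             proteinIds = rownames(values),
                             sampleIds = colnames(values),
                             sampleInfo = NULL) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    rownames(values) <- proteinIds
    colnames(values) <- sampleIds
    cd <- if (is.null(sampleInfo)) {
        DataFrame(row.names = sampleIds)
    } else {
        idx <- match(sampleIds, sampleInfo$sample_id)
        if (anyNA(idx))
            stop("sampleInfo is missing rows for samples: ",
                 paste(sampleIds[is.na(idx)], collapse = ", "))
        DataFrame(sampleInfo[idx, , drop = FALSE], row.names = sampleIds)
    }
    new("ProteinAbundance",
        SummarizedExperiment(assays = list(abundance = values), colData = cd),
        abundanceScale = scale)
}

#' @rdname ProteinAbundance
#' @param object,x a `ProteinAbundance`
#' @export
setGeneric("abundanceScale", function(x) standardGeneric("abundanceScale"))

#' @rdname ProteinAbundance
#' @export
setMethod("abundanceScale", "ProteinAbundance", function(x) x@abundanceScale)

#' @rdname ProteinAbundance
#' @export
abundanceValues <- function(x) assay(x, "abundance")

#' @rdname ProteinAbundance
#' @export
proteinIds <- function(x) rownames(x)

#' @rdname ProteinAbundance
#' @export
sampleIds <- function(x) colnames(x)

setMethod("show", "ProteinAbundance", function(object) {
    v <- assay(object, "abundance")
    cat("ProteinAbundance:", nrow(object), "proteins x", ncol(object),
        "samples [", object@abundanceScale, "scale ]\n")
    cat(sprintf("  missing: %d values (%.1f%%)\n", sum(is.na(v)),
                100 * mean(is.na(v))))
    if (ncol(colData(object)))
        cat("  colData:", paste(colnames(colData(object)), collapse = ", "),
            "\n")
})

#' CorrelationNetwork: a signed weighted protein co-correlation network
#'
#' Holds all stage outputs of network construction: the pairwise-complete
#' Pearson correlation matrix and complete-pair counts, the signed soft-power
#' adjacency, the clustering dissimilarity and dendrogram, module assignment
#' (positive integers ordered by decreasing size; 0 = unassigned), module
#' eigenproteins with variance explained, intramodular connectivity (kIn) and
#' hub flags, and (optionally) leave-one-out stability scores.
#'
#' @slot proteinIds character vector of node identifiers.
#' @slot correlation,nPairs,adjacency,dissimilarity square matrices over
#'   `proteinIds`.
#' @slot dendrogram the `hclust` object of the sample-tree of proteins.
#' @slot modules named integer vector (0 = unassigned).
#' @slot eigenproteins modules x samples matrix (rows `ME1`, `ME2`, ...).
#' @slot varianceExplained per-module first-eigenvalue fraction.
#' @slot kIn,hub per-protein intramodular connectivity and hub flag.
#' @slot stability per-protein leave-one-out assignment-agreement proportion
#'   (length 0 when stability was not run).
#' @slot config the `networkConfig()` list used.
#' @export
setClass("CorrelationNetwork",
         representation(proteinIds = "character",
                        correlation = "matrix",
                        nPairs = "matrix",
                        adjacency = "matrix",
                        dissimilarity = "matrix",
                        dendrogram = "ANY",
                        modules = "integer",
                        eigenproteins = "matrix",
                        varianceExplained = "numeric",
                        kIn = "numeric",
                        hub = "logical",
                        stability = "numeric",
                        config = "list"))

setValidity("CorrelationNetwork", function(object) {
    p <- length(object@proteinIds)
    msg <- character()
    for (nm in c("correlation", "nPairs", "adjacency", "dissimilarity")) {
        m <- slot(object, nm)
        if (!all(dim(m) == c(p, p)))
            msg <- c(msg, sprintf("%s must be %d x %d", nm, p, p))
    }
    a <- object@adjacency
    if (length(a) && (any(a < 0 | a > 1, na.rm = TRUE)))
        msg <- c(msg, "adjacency entries must lie in [0, 1]")
    if (length(object@modules) != p)
        msg <- c(msg, "modules must cover every protein")
    if (any(object@modules < 0L))
        msg <- c(msg, "module labels must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname CorrelationNetwork-class
#' @param x a `CorrelationNetwork`
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))

#' @rdname CorrelationNetwork-class
#' @export
setMethod("moduleAssignment", "CorrelationNetwork", function(x) x@modules)

#' @rdname CorrelationNetwork-class
#' @export
setGeneric("eigenproteins", function(x) standardGeneric("eigenproteins"))

#' @rdname CorrelationNetwork-class
#' @export
setMethod("eigenproteins", "CorrelationNetwork", function(x) x@eigenproteins)

#' @rdname CorrelationNetwork-class
#' @export
setGeneric("hubProteins", function(x) standardGeneric("hubProteins"))

#' @rdname CorrelationNetwork-class
#' @export
setMethod("hubProteins", "CorrelationNetwork",
          function(x) x@proteinIds[x@hub])

#' @rdname CorrelationNetwork-class
#' @export
setGeneric("intramodularK", function(x) standardGeneric("intramodularK"))

#' @rdname CorrelationNetwork-class
#' @export
setMethod("intramodularK", "CorrelationNetwork", function(x) x@kIn)

#' @rdname CorrelationNetwork-class
#' @export
setGeneric("stabilityScores", function(x) standardGeneric("stabilityScores"))

#' @rdname CorrelationNetwork-class
#' @export
setMethod("stabilityScores", "CorrelationNetwork", function(x) x@stability)

setMethod("show", "CorrelationNetwork", function(object) {
    m <- object@modules
    sizes <- table(m[m > 0L])
    cat("CorrelationNetwork:", length(object@proteinIds), "proteins,",
        length(sizes), "modules\n")
    if (length(sizes))
        cat("  module sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
    cat("  unassigned:", sum(m == 0L), "proteins;",
        sum(object@hub), "hubs\n")
    if (length(object@stability))
        cat(sprintf("  stability: mean %.3f over assigned proteins\n",
                    mean(object@stability[m > 0L])))
})
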