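## Reading/writing of the delimited formats the pipeline consumes and emits.
## Delimiter is auto-detected from the header line (tab beats comma) unless
## given explicitly; empty cells and configurable sentinel tokens become NA.

detectSep <- function(path, sep = NULL) {
    if (!is.null(sep)) return(sep)
    header <- readLines(path, n = 1L)
    if (grepl("\t", header)) "\t" else ","
}

#' Read a protein abundance matrix from delimited text
#'
#' The file must carry a header row and an identifier first column. Empty
#' cells and sentinel tokens (`""` and `"NA"` by default) are treated as
#' missing; any other non-numeric cell is a format error, as are duplicated
#' protein or sample identifiers.
#'
#' @param path file path (TSV or CSV; delimiter auto-detected unless `sep`
#'   is given).
#' @param orientation `"proteins_in_rows"` (canonical) or
#'   `"proteins_in_columns"`; the returned object is always proteins x
#'   samples.
#' @param scale declared scale of the stored values, `"linear"` or `"log"`.
#' @param na sentinel tokens treated as missing.
#' @param sep optional field separator.
#' @return A [ProteinAbundance-class].
#' @export
readAbundance <- function(path,
                          orientation = c("proteins_in_rows",
                                          "proteins_in_columns"),
                          scale = c("linear", "log"),
                          na = c("", "NA"), sep = NULL) {
    orientation <- match.arg(orientation)
    scale <- match.arg(scale)
    sep <- detectSep(path, sep)
    raw <- utils::read.table(path, sep = sep, header = TRUE,
                             colClasses = "character", check.names = FALSE,
                             quote = "\"", comment.char = "",
                             na.strings = character())
    ids <- raw[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate identifiers in first column: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    other <- colnames(raw)[-1L]
    if (anyDuplicated(other))
        stop("duplicate identifiers in header: ",
             paste(unique(other[duplicated(other)]), collapse = ", "))
    cells <- as.matrix(raw[, -1L, drop = FALSE])
    cells[cells %in% na] <- NA_character_
    num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
    bad <- !is.na(cells) & is.na(num)
    if (any(bad))
        stop("non-numeric cell(s) that are not missing-value sentinels, ",
             "e.g. \"", cells[which(bad)[1L]], "\"")
    dimnames(num) <- list(ids, other)
    if (orientation == "proteins_in_columns") num <- t(num)
    ProteinAbundance(num, scale = scale)
}

#' Write a ProteinAbundance matrix as delimited text (proteins in rows)
#'
#' Missing values are written as empty cells; `readAbundance()` on the
#' result reproduces values, identifiers and missingness exactly.
#'
#' @param x a [ProteinAbundance-class].
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
writeAbundance <- function(x, path, sep = "\t") {
    v <- abundanceValues(x)
    df <- data.frame(protein_id = rownames(v), v, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                       na = "")
    invisible(path)
}

validateSampleInfo <- function(info) {
    required <- c("sample_id", "subject_id", "group", "visit",
                  "months_from_baseline")
    miss <- setdiff(required, colnames(info))
    if (length(miss))
        stop("sample metadata lacks required column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(info$sample_id))
        stop("duplicate sample_id: ",
             paste(unique(info$sample_id[duplicated(info$sample_id)]),
                   collapse = ", "))
    info$visit <- as.integer(info$visit)
    info$months_from_baseline <- as.numeric(info$months_from_baseline)
    if (any(info$visit < 1L))
        stop("visit numbers must be positive integers")
    if (any(info$months_from_baseline < 0))
        stop("months_from_baseline must be non-negative")
    bad1 <- (info$visit == 1L) != (info$months_from_baseline == 0)
    if (any(bad1))
        stop("visit 1 must coincide with months_from_baseline = 0 (samples ",
             paste(info$sample_id[bad1], collapse = ", "), ")")
    for (s in split(info, info$subject_id)) {
        s <- s[order(s$visit), ]
        if (any(diff(s$months_from_baseline) <= 0))
            stop("subject ", s$subject_id[1L],
                 ": months_from_baseline not strictly increasing over visits")
    }
    ## groups enumerated in first-appearance order
    info$group <- factor(info$group, levels = unique(info$group))
    rownames(info) <- NULL
    info
}

#' Read per-sample metadata
#'
#' Requires columns `sample_id`, `subject_id`, `group`, `visit`,
#' `months_from_baseline`. Validates that visit 1 has months 0 and that each
#' subject's visits are strictly increasing in time. Group labels are
#' arbitrary strings, returned as a factor with levels in first-appearance
#' order.
#'
#' @param path file path; delimiter auto-detected unless `sep` given.
#' @param sep optional field separator.
#' @return data.frame of validated sample records.
#' @export
readSampleInfo <- function(path, sep = NULL) {
    sep <- detectSep(path, sep)
    info <- utils::read.table(path, sep = sep, header = TRUE,
                              check.names = FALSE, quote = "\"",
                              colClasses = "character", comment.char = "")
    validateSampleInfo(info)
}

#' @rdname readSampleInfo
#' @param info validated sample metadata data.frame.
#' @export
writeSampleInfo <- function(info, path, sep = "\t") {
    utils::write.table(info, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Attach sample metadata to a ProteinAbundance object
#'
#' Samples present in only one of matrix and metadata ("orphans") are
#' reported with a warning; the returned object is restricted to samples
#' present in both, in matrix order.
#'
#' @param x a [ProteinAbundance-class].
#' @param info validated metadata as from [readSampleInfo()].
#' @return `x` with populated `colData`.
#' @export
attachSampleInfo <- function(x, info) {
    info <- validateSampleInfo(info)
    onlyM <- setdiff(sampleIds(x), info$sample_id)
    onlyI <- setdiff(info$sample_id, sampleIds(x))
    if (length(onlyM) || length(onlyI))
        warning(sprintf("orphan samples: %d in matrix only, %d in metadata only",
                        length(onlyM), length(onlyI)))
    keep <- intersect(sampleIds(x), info$sample_id)
    if (!length(keep)) stop("no samples shared between matrix and metadata")
    out <- x[, keep]
    colData(out) <- DataFrame(info[match(keep, info$sample_id), ,
                                   drop = FALSE],
                              row.names = keep)
    out
}

#' Read a protein-to-gene mapping table
#'
#' Two-column delimited text (`protein_id`, `gene_symbol`), many proteins to
#' one gene allowed; a protein mapped to two different genes is an error.
#'
#' @param path file path.
#' @param sep optional field separator.
#' @return named character vector: `geneMap[protein_id] == gene_symbol`.
#' @export
readGeneMap <- function(path, sep = NULL) {
    sep <- detectSep(path, sep)
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             colClasses = "character", check.names = FALSE)
    if (ncol(tab) < 2L) stop("gene map needs two columns")
    tab <- unique(tab[, 1:2])
    if (anyDuplicated(tab[[1L]]))
        stop("protein mapped to more than one gene: ",
             paste(unique(tab[[1L]][duplicated(tab[[1L]])]), collapse = ", "))
    structure(tab[[2L]], names = tab[[1L]])
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `set_id<TAB>description<TAB>member...`. Members are deduplicated within a
#' set; a line with fewer than three fields (i.e. an empty member list) is a
#' format error.
#'
#' @param path file path.
#' @return named list of character vectors with a `"description"` attribute.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("GMT line(s) with fewer than 3 fields (empty member list): line ",
             paste(which(nf < 3L), collapse = ", "))
    ids <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(ids))
        stop("duplicate set ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- ids
    attr(sets, "description") <-
        structure(vapply(fields, `[[`, "", 2L), names = ids)
    sets
}

#' @rdname readGMT
#' @param sets named list of character vectors (optionally with a
#'   `"description"` attribute).
#' @param path output path.
#' @export
writeGMT <- function(sets, path) {
    desc <- attr(sets, "description")
    if (is.null(desc)) desc <- structure(rep("", length(sets)),
                                         names = names(sets))
    lines <- vapply(names(sets), function(id)
        paste(c(id, desc[[id]], sets[[id]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}
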