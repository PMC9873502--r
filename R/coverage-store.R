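#' @include coverage.R
NULL

#' Build a CoverageSet from a cells-by-bins matrix
#'
#' @param values cells-by-bins numeric matrix (rownames = cell ids), rows
#'   summing to 1 except degenerate all-zero cells.
#' @param counts optional cells-by-bins matrix of raw covered-base counts.
#' @param nReadsUsed optional per-cell read counts.
#' @return a [CoverageSet-class].
#' @export
CoverageSet <- function(values, counts = NULL, nReadsUsed = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        stop("cells must be named (rownames = cell ids)", call. = FALSE)
    nBins <- ncol(values)
    assays <- list(coverage = t(values))
    if (!is.null(counts))
        assays$counts <- t(as.matrix(counts))
    deg <- rowSums(values) == 0
    cd <- S4Vectors::DataFrame(
        nReadsUsed = if (is.null(nReadsUsed)) rep(NA_integer_,
            nrow(values)) else as.integer(nReadsUsed),
        degenerate = deg,
        row.names = rownames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, colData = cd)
    rownames(se) <- paste0("bin", seq_len(nBins))
    new("CoverageSet", se)
}

.coverageSetFromVectors <- function(vectors) {
    ids <- vapply(vectors, function(v) v@cellId, "")
    values <- do.call(rbind, lapply(vectors, function(v) v@values))
    counts <- do.call(rbind, lapply(vectors, function(v) v@rawCounts))
    rownames(values) <- rownames(counts) <- ids
    CoverageSet(values, counts = counts,
        nReadsUsed = vapply(vectors, function(v) v@nReadsUsed, 0L))
}

#' @rdname skewC-accessors
#' @export
setMethod("cellIds", "CoverageSet", function(x) colnames(x))

#' @rdname skewC-accessors
#' @export
setMethod("coverageValues", "CoverageSet", function(x)
    t(SummarizedExperiment::assay(x, "coverage")))

#' @rdname skewC-accessors
#' @export
setMethod("rawCounts", "CoverageSet", function(x) {
    if (!"counts" %in% SummarizedExperiment::assayNames(x))
        return(NULL)
    t(SummarizedExperiment::assay(x, "counts"))
})

#' @rdname skewC-accessors
#' @export
setMethod("isDegenerate", "CoverageSet", function(x)
    stats::setNames(SummarizedExperiment::colData(x)$degenerate,
        colnames(x)))

#' @rdname skewC-accessors
#' @export
setMethod("cellIds", "CoverageVector", function(x) x@cellId)

#' @rdname skewC-accessors
#' @export
setMethod("coverageValues", "CoverageVector", function(x) x@values)

#' @rdname skewC-accessors
#' @export
setMethod("rawCounts", "CoverageVector", function(x) x@rawCounts)

#' @rdname skewC-accessors
#' @export
setMethod("isDegenerate", "CoverageVector", function(x) x@degenerate)

#' Write a coverage store
#'
#' Two on-disk dialects hold the same cells-by-100 content:
#' \code{writeCoverageStore} writes the native tab-separated dialect (one
#' line per cell: cell id then 100 values); \code{writeCoverageR} writes
#' the compatibility dialect mirroring the workflow's \code{coverage.r}
#' file, one \code{`cellid` <- c(v1,...,v100)} assignment per cell.
#' [readCoverageStore()] accepts either.
#'
#' @param covset a [CoverageSet-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCoverageStore <- function(covset, path) {
    v <- coverageValues(covset)
    lines <- vapply(seq_len(nrow(v)), function(i)
        paste(c(rownames(v)[i], .num(v[i, ])), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeCoverageStore
#' @export
writeCoverageR <- function(covset, path) {
    v <- coverageValues(covset)
    lines <- vapply(seq_len(nrow(v)), function(i)
        paste0("`", rownames(v)[i], "` <- c(",
            paste(.num(v[i, ]), collapse = ","), ")"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Read a coverage store into a CoverageSet
#'
#' Auto-detects the dialect (native TSV or \code{coverage.r}-style
#' assignments) and assembles the coverage matrix: conceptually 101
#' columns, the cell id plus 100 gene-body bins, one row per cell, in
#' store order. Duplicate cell ids and rows with a value count other than
#' \code{nBins} are format errors naming the cell. Degenerate (all-zero)
#' cells are carried and flagged, not dropped.
#'
#' @param path a store written by [writeCoverageStore()] or
#'   [writeCoverageR()].
#' @param nBins expected number of bins (default 100).
#' @return a [CoverageSet-class].
#' @export
readCoverageStore <- function(path, nBins = 100L) {
    lines <- .readTextLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
        stop("empty coverage store: ", path, call. = FALSE)
    isR <- grepl("<-\\s*c\\(", lines[1])
    if (isR) {
        m <- regmatches(lines,
            regexec("^\\s*`?([^`]+?)`?\\s*<-\\s*c\\((.*)\\)\\s*$", lines))
        bad <- which(lengths(m) != 3L)
        if (length(bad) > 0)
            stop("coverage.r format error at line ", bad[1], call. = FALSE)
        ids <- vapply(m, `[[`, "", 2)
        vals <- lapply(m, function(x)
            as.numeric(strsplit(x[[3]], ",", fixed = TRUE)[[1]]))
    } else {
        f <- strsplit(lines, "\t", fixed = TRUE)
        ids <- vapply(f, `[[`, "", 1)
        vals <- lapply(f, function(x) as.numeric(x[-1]))
    }
    nv <- lengths(vals)
    if (any(nv != nBins))
        stop("coverage store format error: cell '", ids[nv != nBins][1],
            "' has ", nv[nv != nBins][1], " values (expected ", nBins,
            ")", call. = FALSE)
    if (anyDuplicated(ids))
        stop("duplicate cell id in store: ", ids[duplicated(ids)][1],
            call. = FALSE)
    values <- do.call(rbind, vals)
    rownames(values) <- ids
    CoverageSet(values)
}

#' @rdname readCoverageStore
#' @export
assembleCoverageMatrix <- readCoverageStore

#' @rdname decileMeans
#' @export
setMethod("decileMeans", "CoverageSet", function(x, dropDegenerate = TRUE) {
    decileMeans(coverageValues(x), dropDegenerate = dropDegenerate)
})

#' @rdname decileMeans
#' @export
setMethod("decileMeans", "matrix", function(x, dropDegenerate = TRUE) {
    stopifnot(ncol(x) %% 10L == 0L)
    deg <- rowSums(x) == 0
    if (dropDegenerate && any(deg)) {
        message(sum(deg), " degenerate (all-zero) cell(s) dropped from ",
            "the mean coverage matrix: ",
            paste(rownames(x)[deg], collapse = ", "))
        x <- x[!deg, , drop = FALSE]
    }
    if (nrow(x) == 0L)
        stop("no usable cells: every cell is degenerate", call. = FALSE)
    g <- ncol(x) / 10L
    out <- vapply(seq_len(10L), function(j)
        rowMeans(x[, ((j - 1) * g + 1):(j * g), drop = FALSE]),
        numeric(nrow(x)))
    if (nrow(x) == 1L)
        out <- matrix(out, nrow = 1L, dimnames = list(rownames(x), NULL))
    colnames(out) <- paste0("pmean", seq_len(10L) * 10L)
    rownames(out) <- rownames(x)
    out
})

setMethod("show", "CoverageSet", function(object) {
    cat("CoverageSet:", ncol(object), "cell(s) x", nrow(object),
        "gene-body bins\n")
    deg <- sum(SummarizedExperiment::colData(object)$degenerate)
    if (deg > 0)
        cat("  ", deg, "degenerate (all-zero) cell(s)\n")
    cat("  assays:", paste(SummarizedExperiment::assayNames(object),
        collapse = ", "), "\n")
})
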