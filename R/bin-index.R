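#' @include gene-model.R
NULL

# Map transcript-oriented intervals to genomic intervals through the exon
# structure of one transcript.
#
# exons:  IRanges of genomic exon blocks, ascending (1-based closed)
# strand: "+" or "-"
# tcS0/tcE0: 0-based half-open transcript-coordinate intervals (5'->3')
#
# Returns a data.frame with one row per genomic piece: `q` (which input
# interval), `gstart`, `gend` (1-based closed). Pieces of one interval come
# out in ascending transcript order, i.e. genomically ascending on "+",
# descending on "-".
.mapTcIntervals <- function(exons, strand, tcS0, tcE0) {
    w <- BiocGenerics::width(exons)
    ord <- if (strand == "+") seq_along(exons) else rev(seq_along(exons))
    wTc <- w[ord]
    cum <- cumsum(wTc)
    tcExonStart0 <- c(0L, utils::head(cum, -1))
    keep <- tcE0 > tcS0
    query <- IRanges::IRanges(start = tcS0[keep] + 1L, end = tcE0[keep])
    exTc <- IRanges::IRanges(start = tcExonStart0 + 1L, end = cum)
    ov <- IRanges::findOverlaps(query, exTc)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    piece <- IRanges::pintersect(query[qh], exTc[sh])
    off0 <- BiocGenerics::start(piece) - 1L - tcExonStart0[sh]
    len <- BiocGenerics::width(piece)
    gIdx <- ord[sh]
    if (strand == "+") {
        gstart <- BiocGenerics::start(exons)[gIdx] + off0
        gend <- gstart + len - 1L
    } else {
        gend <- BiocGenerics::end(exons)[gIdx] - off0
        gstart <- gend - len + 1L
    }
    data.frame(q = which(keep)[qh], gstart = gstart, gend = gend)
}

#' Build the 100-bin gene-body index
#'
#' Partitions the exonic (mRNA) bases of every transcript into \code{nBins}
#' contiguous bins of near-equal size, walked 5' to 3' in transcript
#' orientation: transcript-oriented base \code{i} (0-based, \code{i < L})
#' goes to bin \code{floor(i * nBins / L) + 1}, so each bin receives either
#' \code{floor(L/nBins)} or \code{ceiling(L/nBins)} bases. Transcripts with
#' mRNA length below \code{minMrnaLength} are skipped (their count is
#' reported). The index records a checksum of the source model so a stale
#' persisted index is rejected on load.
#'
#' @param model a [GeneModel-class]; must retain at least one transcript
#'   after length filtering.
#' @param nBins number of gene-body bins (default 100).
#' @param minMrnaLength minimum mRNA length to index (default 100, i.e. at
#'   least one base per bin at the default bin count).
#' @return a [BinIndex-class].
#' @examples
#' model <- makeGeneModel(nTranscripts = 4, seed = 7)$model
#' idx <- buildBinIndex(model)
#' idx
#' @export
buildBinIndex <- function(model, nBins = 100L, minMrnaLength = 100L) {
    stopifnot(is(model, "GeneModel"))
    nBins <- as.integer(nBins)
    minMrnaLength <- as.integer(minMrnaLength)
    .stopIfNot(nBins >= 1L, "nBins must be >= 1")
    gr <- model@transcripts
    L <- vapply(S4Vectors::mcols(gr)$blocks,
        function(b) sum(BiocGenerics::width(b)), 0L)
    keep <- which(L >= minMrnaLength)
    nSkipped <- length(gr) - length(keep)
    if (nSkipped > 0)
        message(nSkipped, " transcript(s) below minimum mRNA length ",
            minMrnaLength, " skipped")
    if (length(keep) == 0L)
        stop("empty model: no transcript passes the mRNA length filter",
            call. = FALSE)
    pieces <- vector("list", length(keep))
    b <- seq_len(nBins)
    for (j in seq_along(keep)) {
        i <- keep[j]
        Li <- L[i]
        # bin b covers transcript bases [ceil((b-1)L/nBins), ceil(bL/nBins))
        s0 <- as.integer(ceiling((b - 1) * Li / nBins))
        e0 <- as.integer(ceiling(b * Li / nBins))
        mp <- .mapTcIntervals(S4Vectors::mcols(gr)$blocks[[i]],
            as.character(GenomicRanges::strand(gr))[i], s0, e0)
        mp$bin <- mp$q
        mp$txId <- i
        pieces[[j]] <- mp
    }
    all <- do.call(rbind, pieces)
    bins <- GenomicRanges::GRanges(
        seqnames = as.character(GenomicRanges::seqnames(gr))[all$txId],
        ranges = IRanges::IRanges(start = all$gstart, end = all$gend),
        strand = as.character(GenomicRanges::strand(gr))[all$txId])
    S4Vectors::mcols(bins)$txId <- all$txId
    S4Vectors::mcols(bins)$txName <- S4Vectors::mcols(gr)$name[all$txId]
    S4Vectors::mcols(bins)$bin <- as.integer(all$bin)
    src <- if (nzchar(model@sourcePath))
        sub("\\.(bed|bed\\.gz)$", "", basename(model@sourcePath))
    else "genemodel"
    new("BinIndex", bins = bins, nBins = nBins,
        minMrnaLength = minMrnaLength, nSkipped = as.integer(nSkipped),
        checksum = .geneModelChecksum(model), sourceName = src)
}

#' Bin ranges of an index
#'
#' @param x a [BinIndex-class].
#' @return the underlying \code{GRanges} with \code{txId}, \code{txName}
#'   and \code{bin} metadata columns.
#' @export
binRanges <- function(x) {
    stopifnot(is(x, "BinIndex"))
    x@bins
}

#' Persist and reload a gene-body bin index
#'
#' The index is stored as a versioned, tab-separated text file
#' (\code{<refDir>/<sourceName>.idx}) whose header lines carry the format
#' version, the source-model checksum, the bin count and the length
#' threshold. On reload the stored checksum is compared against the model
#' (or an explicit checksum); a mismatch raises a stale-index error
#' instructing a rebuild.
#'
#' @param index a [BinIndex-class].
#' @param refDir reference directory (created if missing); default
#'   \code{"reference"}, matching the workflow's folder layout.
#' @return \code{writeBinIndex}: the index file path, invisibly.
#' @export
writeBinIndex <- function(index, refDir = "reference") {
    stopifnot(is(index, "BinIndex"))
    dir.create(refDir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(refDir, paste0(index@sourceName, ".idx"))
    b <- index@bins
    hdr <- c(
        "# skewC-bin-index v1",
        paste0("# checksum: ", index@checksum),
        paste0("# n_bins: ", index@nBins),
        paste0("# min_mrna_length: ", index@minMrnaLength),
        paste0("# n_skipped: ", index@nSkipped),
        paste0("# source: ", index@sourceName))
    body <- paste(
        as.character(GenomicRanges::seqnames(b)),
        BiocGenerics::start(b) - 1L,
        BiocGenerics::end(b),
        S4Vectors::mcols(b)$txId,
        S4Vectors::mcols(b)$txName,
        as.character(GenomicRanges::strand(b)),
        S4Vectors::mcols(b)$bin,
        sep = "\t")
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' @rdname writeBinIndex
#' @param path index file written by [writeBinIndex()].
#' @param model the source [GeneModel-class] to validate against (or NULL
#'   to skip validation when \code{checksum} is also NULL).
#' @param checksum explicit checksum to validate against instead of a model.
#' @return \code{readBinIndex}: the reloaded [BinIndex-class].
#' @export
readBinIndex <- function(path, model = NULL, checksum = NULL) {
    lines <- .readTextLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    if (length(hdr) == 0 || !grepl("skewC-bin-index", hdr[1]))
        stop("not a skewC bin index file: ", path, call. = FALSE)
    getH <- function(key) {
        x <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
        sub(paste0("^# ", key, ": "), "", x[1])
    }
    storedSum <- getH("checksum")
    if (!is.null(model))
        checksum <- .geneModelChecksum(model)
    if (!is.null(checksum) && !identical(checksum, storedSum))
        stop("stale index: checksum of ", path, " does not match the ",
            "current gene model; rebuild it with buildBinIndex()/",
            "writeBinIndex()", call. = FALSE)
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    f <- strsplit(body, "\t", fixed = TRUE)
    col <- function(k) vapply(f, `[[`, "", k)
    bins <- GenomicRanges::GRanges(
        seqnames = col(1),
        ranges = IRanges::IRanges(start = as.integer(col(2)) + 1L,
            end = as.integer(col(3))),
        strand = col(6))
    S4Vectors::mcols(bins)$txId <- as.integer(col(4))
    S4Vectors::mcols(bins)$txName <- col(5)
    S4Vectors::mcols(bins)$bin <- as.integer(col(7))
    new("BinIndex", bins = bins,
        nBins = as.integer(getH("n_bins")),
        minMrnaLength = as.integer(getH("min_mrna_length")),
        nSkipped = as.integer(getH("n_skipped")),
        checksum = storedSum,
        sourceName = getH("source"))
}

# load a fresh persisted index or (re)build and persist it; used by
# batchCoverage so the index exists before any worker starts
.getOrBuildBinIndex <- function(model, refDir = "reference", nBins = 100L,
    minMrnaLength = 100L) {
    src <- if (nzchar(model@sourcePath))
        sub("\\.(bed|bed\\.gz)$", "", basename(model@sourcePath))
    else "genemodel"
    path <- file.path(refDir, paste0(src, ".idx"))
    if (file.exists(path)) {
        idx <- tryCatch(
            readBinIndex(path, model = model),
            error = function(e) NULL)
        if (!is.null(idx) && idx@nBins == nBins &&
            idx@minMrnaLength == minMrnaLength)
            return(idx)
    }
    idx <- buildBinIndex(model, nBins = nBins,
        minMrnaLength = minMrnaLength)
    writeBinIndex(idx, refDir)
    idx
}

setMethod("show", "BinIndex", function(object) {
    cat("BinIndex:", length(unique(S4Vectors::mcols(object@bins)$txId)),
        "transcript(s) x", object@nBins, "bins\n")
    cat("  min mRNA length:", object@minMrnaLength,
        "(", object@nSkipped, "transcript(s) skipped )\n")
    cat("  checksum:", object@checksum, "\n")
})
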