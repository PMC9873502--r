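#' @include bin-index.R
#' @importFrom GenomicAlignments readGAlignments cigarRangesAlongReferenceSpace
#'   cigar
#' @importFrom parallel mclapply
NULL

#' Compute one cell's gene body coverage from its BAM
#'
#' For every eligible alignment (primary, mapped, not duplicate-flagged;
#' secondary and supplementary alignments are excluded to avoid
#' double-counting multi-mappers), every aligned reference base (CIGAR
#' \code{M}/\code{=}/\code{X}; \code{N} and \code{D} segments cover no
#' exonic base and are skipped) that falls on an indexed exonic base
#' increments that base's gene-body bin for that transcript; bases lying on
#' exons of several indexed transcripts increment all of them. Raw bin
#' counts are summed over transcripts and normalized to sum to one
#' (relative gene body coverage). Sorted and unsorted BAMs are both
#' accepted; read order does not affect the result.
#'
#' A BAM whose contigs share no name with the index's contigs yields a
#' degenerate all-zero vector with a loud warning — this is the classic
#' "empty gene body coverage plot" failure mode, surfaced early.
#'
#' @param bam path to the cell's BAM file.
#' @param index a [BinIndex-class].
#' @param cellId cell identifier (default: BAM filename stem).
#' @param minMapq minimum mapping quality (default 0, i.e. no filter).
#' @param logFile optional path; a one-line log (\code{cell, reads seen,
#'   reads used, bases counted}) is written there.
#' @return a [CoverageVector-class].
#' @export
computeCellCoverage <- function(bam, index, cellId = NULL, minMapq = 0L,
    logFile = NULL) {
    stopifnot(is(index, "BinIndex"))
    if (is.null(cellId))
        cellId <- sub("\\.bam$", "", basename(bam))
    hdr <- tryCatch(Rsamtools::scanBamHeader(bam),
        error = function(e) stop("unreadable BAM: ", bam, call. = FALSE))
    nBins <- index@nBins
    raw <- numeric(nBins)
    bamContigs <- names(hdr[[1]]$targets)
    idxContigs <- unique(as.character(GenomicRanges::seqnames(index@bins)))
    nSeen <- Rsamtools::countBam(bam)$records
    nUsed <- 0L
    if (length(intersect(bamContigs, idxContigs)) == 0L) {
        warning("no contig of ", bam, " matches the gene model index; ",
            "coverage for cell '", cellId, "' is empty", call. = FALSE)
    } else {
        flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
            isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
            isDuplicate = FALSE)
        param <- Rsamtools::ScanBamParam(flag = flag,
            mapqFilter = as.integer(minMapq))
        gal <- GenomicAlignments::readGAlignments(bam, param = param)
        nUsed <- length(gal)
        if (nUsed > 0) {
            irl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
                GenomicAlignments::cigar(gal),
                pos = BiocGenerics::start(gal),
                ops = c("M", "=", "X"))
            nb <- S4Vectors::elementNROWS(irl)
            blockGR <- GenomicRanges::GRanges(
                seqnames = rep(GenomicRanges::seqnames(gal), nb),
                ranges = unlist(irl, use.names = FALSE))
            ov <- GenomicRanges::findOverlaps(blockGR, index@bins,
                ignore.strand = TRUE)
            if (length(ov) > 0) {
                w <- BiocGenerics::width(IRanges::pintersect(
                    BiocGenerics::unstrand(
                        blockGR[S4Vectors::queryHits(ov)]),
                    BiocGenerics::unstrand(
                        index@bins[S4Vectors::subjectHits(ov)])))
                binId <- S4Vectors::mcols(index@bins)$bin[
                    S4Vectors::subjectHits(ov)]
                agg <- rowsum(w, binId)
                raw[as.integer(rownames(agg))] <- agg[, 1]
            }
        }
    }
    tot <- sum(raw)
    values <- if (tot > 0) raw / tot else numeric(nBins)
    cv <- new("CoverageVector", cellId = cellId, values = values,
        rawCounts = raw, nReadsUsed = as.integer(nUsed),
        degenerate = tot == 0)
    line <- paste(cellId, nSeen, nUsed, tot, sep = "\t")
    if (!is.null(logFile))
        writeLines(c("cell\treads_seen\treads_used\tbases_counted", line),
            logFile)
    cv
}

setMethod("show", "CoverageVector", function(object) {
    cat("CoverageVector for cell '", object@cellId, "': ",
        length(object@values), " bins, ", object@nReadsUsed,
        " reads used", if (object@degenerate) " [degenerate]", "\n",
        sep = "")
})

#' Batch gene body coverage over a directory of per-cell BAMs
#'
#' Computes [computeCellCoverage()] for every \code{*.bam} in \code{indir}
#' (cell ID = filename stem) and writes a coverage store under
#' \code{outdir}: \code{coverage.tsv} (one line per cell: id then 100
#' values), the \code{coverage.r} compatibility dialect, one \code{.log}
#' file per cell, and a \code{failures.tsv} manifest. A corrupt BAM fails
#' only its own cell and is recorded in the manifest. If a
#' [GeneModel-class] is passed instead of a prebuilt index, the index is
#' built (and persisted under \code{refDir}) once, serially, before any
#' worker starts. Output is deterministic: cells are processed and written
#' in sorted filename order regardless of \code{workers}.
#'
#' @param indir directory containing per-cell BAM files (conventionally
#'   \code{"input"}).
#' @param index a [BinIndex-class], or a [GeneModel-class] to index first.
#' @param outdir output directory (conventionally \code{"coverage"}).
#' @param workers parallel workers (forked; 1 = serial).
#' @param refDir where a freshly built index is persisted.
#' @param minMapq passed to [computeCellCoverage()].
#' @return invisibly, a list with \code{store} (TSV path), \code{coverageR}
#'   (compatibility dialect path), \code{failures} (data.frame cell/error),
#'   and \code{covset} (a [CoverageSet-class] of the successful cells).
#' @export
batchCoverage <- function(indir, index, outdir = "coverage", workers = 1L,
    refDir = "reference", minMapq = 0L) {
    bams <- sort(list.files(indir, pattern = "\\.bam$", full.names = TRUE))
    if (length(bams) == 0L)
        stop("no BAM files in ", indir, call. = FALSE)
    if (is(index, "GeneModel"))
        index <- .getOrBuildBinIndex(index, refDir = refDir)
    stopifnot(is(index, "BinIndex"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    stems <- sub("\\.bam$", "", basename(bams))
    runOne <- function(i) {
        tryCatch(
            computeCellCoverage(bams[i], index, cellId = stems[i],
                minMapq = minMapq,
                logFile = file.path(outdir, paste0(stems[i], ".log"))),
            error = function(e) conditionMessage(e))
    }
    res <- if (workers > 1L)
        parallel::mclapply(seq_along(bams), runOne,
            mc.cores = as.integer(workers))
    else
        lapply(seq_along(bams), runOne)
    failed <- vapply(res, is.character, FALSE)
    failures <- data.frame(cell = stems[failed],
        error = unlist(res[failed], use.names = FALSE) %||% character(0),
        stringsAsFactors = FALSE)
    utils::write.table(failures, file.path(outdir, "failures.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    vectors <- res[!failed]
    if (length(vectors) == 0L)
        stop("coverage failed for every cell in ", indir, call. = FALSE)
    covset <- .coverageSetFromVectors(vectors)
    store <- file.path(outdir, "coverage.tsv")
    writeCoverageStore(covset, store)
    coverageR <- file.path(outdir, "coverage.r")
    writeCoverageR(covset, coverageR)
    if (nrow(failures) > 0)
        warning(nrow(failures), " cell(s) failed; see ",
            file.path(outdir, "failures.tsv"), call. = FALSE)
    invisible(list(store = store, coverageR = coverageR,
        failures = failures, covset = covset))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
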