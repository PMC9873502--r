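#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a gene model from parsed transcript fields
#'
#' Low-level constructor used by [readBed12()] and the synthetic model
#' generator. Coordinates follow the BED convention: \code{start} 0-based
#' inclusive, \code{end} 0-based exclusive; internally transcripts are held
#' as 1-based closed \link[GenomicRanges]{GRanges}.
#'
#' @param chrom,start,end,name,strand per-transcript vectors (BED semantics).
#' @param blockSizes,blockStarts lists of integer vectors: exon block sizes
#'   and block offsets from \code{start}, per transcript.
#' @param sourcePath,speciesLabel provenance strings.
#' @return a [GeneModel-class].
#' @export
GeneModel <- function(chrom, start, end, name, strand, blockSizes,
    blockStarts, sourcePath = "", speciesLabel = "") {
    n <- length(chrom)
    blocks <- IRanges::IRangesList(lapply(seq_len(n), function(i) {
        s <- start[i] + blockStarts[[i]] + 1L   # genomic 1-based
        IRanges::IRanges(start = s, width = blockSizes[[i]])
    }))
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = start + 1L, end = end),
        strand = strand)
    S4Vectors::mcols(gr)$name <- as.character(name)
    S4Vectors::mcols(gr)$blocks <- blocks
    new("GeneModel", transcripts = gr,
        sourcePath = as.character(sourcePath),
        speciesLabel = as.character(speciesLabel))
}

#' Read a BED12 gene model
#'
#' Parses a (optionally gzip-compressed) BED12 file into a
#' [GeneModel-class]. Lines starting with \code{track}, \code{browser} or
#' \code{#} and empty lines are skipped. Every data line must have at least
#' 12 tab-separated fields; fewer is an error naming the line, because
#' gene-body binning needs the exon block structure.
#'
#' @param path BED12 file (plain or .gz).
#' @param speciesLabel optional free label stored with the model.
#' @return a [GeneModel-class] with records in file order.
#' @examples
#' bed <- makeGeneModel(nTranscripts = 3, seed = 1,
#'     bedPath = tempfile(fileext = ".bed"))
#' model <- readBed12(bed$bedPath)
#' length(transcripts(model))
#' @export
readBed12 <- function(path, speciesLabel = "") {
    lines <- .readTextLines(path)
    keep <- !grepl("^\\s*$", lines) &
        !grepl("^(track|browser|#)", lines)
    lineNo <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L)
        return(GeneModel(character(0), integer(0), integer(0), character(0),
            character(0), list(), list(), sourcePath = path,
            speciesLabel = speciesLabel))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 12L))
        stop("BED12 format error: line ", lineNo[which(nf < 12L)[1]],
            " has ", nf[which(nf < 12L)[1]],
            " columns (12 required)", call. = FALSE)
    f <- function(k) vapply(fields, `[[`, "", k)
    chrom <- f(1); name <- f(4); strand <- f(6)
    start <- as.integer(f(2)); end <- as.integer(f(3))
    if (anyNA(start) || anyNA(end))
        stop("BED12 format error: non-numeric coordinates at line ",
            lineNo[which(is.na(start) | is.na(end))[1]], call. = FALSE)
    if (!all(strand %in% c("+", "-")))
        stop("BED12 format error: strand must be '+' or '-' at line ",
            lineNo[which(!strand %in% c("+", "-"))[1]], call. = FALSE)
    blockCount <- as.integer(f(10))
    parseCSV <- function(x) lapply(strsplit(x, ",", fixed = TRUE),
        function(v) as.integer(v[nzchar(v)]))
    blockSizes <- parseCSV(f(11))
    blockStarts <- parseCSV(f(12))
    for (i in seq_along(lines)) {
        if (length(blockSizes[[i]]) != blockCount[i] ||
            length(blockStarts[[i]]) != blockCount[i])
            stop("BED12 format error: line ", lineNo[i],
                ": block list lengths disagree with blockCount",
                call. = FALSE)
        k <- blockCount[i]
        if (start[i] + blockStarts[[i]][k] + blockSizes[[i]][k] != end[i] ||
            blockStarts[[i]][1] != 0L)
            stop("BED12 format error: line ", lineNo[i],
                ": block arithmetic inconsistent with start/end",
                call. = FALSE)
    }
    GeneModel(chrom, start, end, name, strand, blockSizes, blockStarts,
        sourcePath = path, speciesLabel = speciesLabel)
}

#' Write a gene model as BED12
#'
#' Canonical writer (tab-separated, score 0, thickStart/thickEnd equal to
#' the transcript span, itemRgb 0, no trailing commas) so that
#' write-read-write round trips are byte-identical.
#'
#' @param model a [GeneModel-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBed12 <- function(model, path) {
    gr <- model@transcripts
    lines <- vapply(seq_along(gr), function(i) {
        b <- S4Vectors::mcols(gr)$blocks[[i]]
        s0 <- BiocGenerics::start(gr)[i] - 1L
        paste(
            as.character(GenomicRanges::seqnames(gr)[i]),
            s0,
            BiocGenerics::end(gr)[i],
            S4Vectors::mcols(gr)$name[i],
            0L,
            as.character(GenomicRanges::strand(gr)[i]),
            s0,
            BiocGenerics::end(gr)[i],
            0L,
            length(b),
            paste(BiocGenerics::width(b), collapse = ","),
            paste(BiocGenerics::start(b) - 1L - s0, collapse = ","),
            sep = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' @rdname skewC-accessors
#' @export
setMethod("mrnaLengths", "GeneModel", function(x) {
    stats::setNames(
        vapply(S4Vectors::mcols(x@transcripts)$blocks,
            function(b) sum(BiocGenerics::width(b)), 0L),
        S4Vectors::mcols(x@transcripts)$name)
})

#' Transcript ranges of a gene model
#'
#' @param x a [GeneModel-class].
#' @return the underlying \code{GRanges} (one range per transcript, with
#'   \code{name} and exon \code{blocks} metadata columns).
#' @export
transcripts <- function(x) {
    stopifnot(is(x, "GeneModel"))
    x@transcripts
}

# digest of the transcript tuples + block structure; keys persisted indices
.geneModelChecksum <- function(model) {
    gr <- model@transcripts
    digest::digest(list(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = BiocGenerics::start(gr),
        end = BiocGenerics::end(gr),
        name = S4Vectors::mcols(gr)$name,
        strand = as.character(GenomicRanges::strand(gr)),
        blocks = lapply(S4Vectors::mcols(gr)$blocks, function(b)
            rbind(BiocGenerics::start(b), BiocGenerics::width(b)))
    ), algo = "md5")
}

# all exon blocks of a model as one stranded GRanges, tagged by record row
.exonBlocks <- function(model) {
    gr <- model@transcripts
    blocks <- S4Vectors::mcols(gr)$blocks
    nb <- lengths(blocks)
    if (length(gr) == 0L || sum(nb) == 0L)
        return(GenomicRanges::GRanges())
    out <- GenomicRanges::GRanges(
        seqnames = rep(GenomicRanges::seqnames(gr), nb),
        ranges = unlist(blocks, use.names = FALSE),
        strand = rep(GenomicRanges::strand(gr), nb))
    S4Vectors::mcols(out)$txId <- rep(seq_along(gr), nb)
    out
}

#' Remove transcripts with exon overlap against an exclusion model
#'
#' Strand-aware, exon-block-resolved subtraction of records, with the
#' semantics of \code{intersectBed -split -v -s -wa}: a transcript of
#' \code{model} is removed when at least one base of one of its exon blocks
#' overlaps an exon block of any \code{exclusion} record on the same strand.
#' Intron-only overlap does not remove a record; surviving records are
#' returned unmodified, in their original order. The canonical use is
#' stripping rRNA/tRNA loci from a gene model before coverage computation.
#'
#' @param model a [GeneModel-class] to filter.
#' @param exclusion a [GeneModel-class] of loci to exclude (e.g. rRNA/tRNA).
#' @return the filtered [GeneModel-class].
#' @export
excludeOverlapping <- function(model, exclusion) {
    stopifnot(is(model, "GeneModel"), is(exclusion, "GeneModel"))
    if (length(exclusion@transcripts) == 0L ||
        length(model@transcripts) == 0L)
        return(model)
    mb <- .exonBlocks(model)
    eb <- .exonBlocks(exclusion)
    hit <- IRanges::overlapsAny(mb, eb, minoverlap = 1L,
        ignore.strand = FALSE)
    bad <- unique(S4Vectors::mcols(mb)$txId[hit])
    keep <- setdiff(seq_along(model@transcripts), bad)
    out <- model
    out@transcripts <- model@transcripts[sort(keep)]
    out
}

setMethod("show", "GeneModel", function(object) {
    gr <- object@transcripts
    cat("GeneModel with", length(gr), "transcript record(s)\n")
    if (nzchar(object@speciesLabel))
        cat("  species label:", object@speciesLabel, "\n")
    if (nzchar(object@sourcePath))
        cat("  source:", object@sourcePath, "\n")
    if (length(gr) > 0) {
        L <- mrnaLengths(object)
        cat("  mRNA length range:", min(L), "-", max(L), "bases\n")
    }
})
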