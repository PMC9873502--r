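#' @include utils.R
#' @importFrom Rsamtools BamFile ScanBamParam scanBam scanBamFlag scanBamHeader
#'   filterBam countBam indexBam asBam sortBam
NULL

#' Read a cell barcode whitelist
#'
#' Reads a \code{barcodes.tsv} / \code{barcodes.tsv.gz} file (one barcode
#' per line, e.g. the Cell Ranger \code{filtered_feature_bc_matrix}
#' whitelist). Trailing whitespace is stripped; order is preserved.
#'
#' @param path plain or gzip-compressed text file.
#' @return character vector of barcodes, in file order.
#' @export
readBarcodes <- function(path) {
    lines <- sub("\\s+$", "", .readTextLines(path))
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        stop("no barcodes in ", path, call. = FALSE)
    if (any(grepl("\\s", lines)))
        stop("barcode contains whitespace: ",
            lines[grepl("\\s", lines)][1], call. = FALSE)
    if (anyDuplicated(lines))
        stop("duplicate barcode in ", path, ": ",
            lines[duplicated(lines)][1], call. = FALSE)
    lines
}

#' Split a barcoded BAM into one BAM per cell barcode
#'
#' Partitions a 10x-style barcoded BAM (cell barcode in the \code{CB} tag,
#' or \code{CR} via \code{tag}) into per-cell BAM files named
#' \code{<barcode>.bam} under \code{outdir} — the downstream cell ID is the
#' filename stem. For every listed barcode an output BAM is written (empty
#' if the barcode never occurs) containing exactly the input alignments
#' whose barcode tag equals it, original header preserved; alignments with
#' absent or unlisted barcodes are counted and skipped. A barcode-coverage
#' summary comparing the whitelist against the barcodes actually seen is
#' attached to the result; a mismatch is a warning with counts, not an
#' error, but a whitelist with \emph{no} barcode present in the BAM aborts
#' (it would make every downstream coverage plot empty).
#'
#' Unmapped, secondary and supplementary alignments pass through unchanged:
#' splitting is lossless per barcode, and alignment eligibility is the
#' coverage engine's concern. When the input is coordinate-sorted, each
#' per-cell BAM is indexed.
#'
#' @param bam path to the barcoded BAM.
#' @param barcodes character vector from [readBarcodes()] (or a file path).
#' @param outdir output directory (default \code{"input"}, the workflow's
#'   conventional split-BAM folder).
#' @param tag BAM tag holding the cell barcode (default \code{"CB"}).
#' @return data.frame with one row per listed barcode: \code{barcode},
#'   \code{path}, \code{nReads}; attributes \code{nSkipped} (reads with
#'   absent/unlisted barcode), \code{nSeenBarcodes} (distinct tagged
#'   barcodes in the BAM).
#' @export
splitBamByBarcode <- function(bam, barcodes, outdir = "input", tag = "CB") {
    if (length(barcodes) == 1L && file.exists(barcodes))
        barcodes <- readBarcodes(barcodes)
    hdr <- tryCatch(Rsamtools::scanBamHeader(bam),
        error = function(e) stop("unreadable BAM (no header): ", bam,
            call. = FALSE))
    sorted <- identical(hdr[[1]]$text[["@HD"]][2], "SO:coordinate") ||
        any(vapply(hdr[[1]]$text, function(x) any(x == "SO:coordinate"),
            FALSE))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

    # census of barcode tags over the whole BAM
    p <- Rsamtools::ScanBamParam(what = character(0), tag = tag)
    tags <- Rsamtools::scanBam(bam, param = p)[[1]]$tag[[tag]]
    nTotal <- Rsamtools::countBam(bam)$records
    if (is.null(tags))
        tags <- rep(NA_character_, nTotal)
    seen <- table(tags[!is.na(tags)])
    present <- intersect(barcodes, names(seen))
    if (length(present) == 0L)
        stop("none of the ", length(barcodes), " listed barcodes occurs ",
            "in ", bam, " (tag ", tag, "); check that the barcode formats ",
            "match or the coverage plots will be empty", call. = FALSE)
    if (length(seen) != length(barcodes))
        warning(length(barcodes), " barcode(s) listed but ", length(seen),
            " distinct barcode(s) seen in the BAM", call. = FALSE)

    out <- data.frame(barcode = barcodes,
        path = file.path(outdir,
            paste0(.sanitizeFilename(barcodes), ".bam")),
        nReads = as.integer(ifelse(barcodes %in% names(seen),
            seen[barcodes], 0L)),
        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(out))) {
        keepBc <- out$barcode[i]
        param <- Rsamtools::ScanBamParam(
            tagFilter = stats::setNames(list(keepBc), tag),
            what = character(0))
        Rsamtools::filterBam(bam, destination = out$path[i], param = param,
            indexDestination = FALSE)
        if (sorted && out$nReads[i] > 0)
            tryCatch(Rsamtools::indexBam(out$path[i]),
                error = function(e) NULL)
    }
    nListed <- sum(out$nReads)
    nSkipped <- nTotal - nListed
    message("split ", nTotal, " reads: ", nListed, " written across ",
        nrow(out), " barcodes, ", nSkipped,
        " skipped (absent or unlisted barcode); ", length(seen),
        " distinct barcode(s) seen in BAM vs ", length(barcodes),
        " listed")
    attr(out, "nSkipped") <- nSkipped
    attr(out, "nSeenBarcodes") <- length(seen)
    out
}
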