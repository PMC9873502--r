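#' @include coverage-store.R bin-index.R
NULL

#' Prototypical gene body coverage profile
#'
#' Mildly mid-gene-peaked 100-bin profile (a scaled symmetric beta density)
#' summing to one, used as the typical-cell target of the synthetic
#' cohort generator.
#'
#' @return numeric 100-vector.
#' @export
prototypeProfile <- function() {
    x <- (seq_len(100L) - 0.5) / 100
    w <- stats::dbeta(x, 1.6, 1.6)
    w / sum(w)
}

# geometric end-loaded profile: mass concentrated at the 3' (bin 100) or
# 5' (bin 1) end, the canonical degradation signature
.endProfile <- function(skewKind, ratio = 0.94) {
    g <- ratio^(99:0)
    if (skewKind == "five_prime")
        g <- rev(g)
    g / sum(g)
}

#' Construct a synthetic coverage profile specification
#'
#' @param skewKind \code{"three_prime"} (default; degradation-like 3'
#'   loading) or \code{"five_prime"}.
#' @param skewStrength mixing weight in [0, 1] of the geometric end-loaded
#'   profile into the prototype; 0 generates typical cells.
#' @param noiseConcentration Dirichlet concentration scale for per-cell
#'   perturbation (larger = less noisy); default 200.
#' @param prototype base 100-bin profile; default [prototypeProfile()].
#' @return a [SkewProfileSpec-class].
#' @export
skewProfileSpec <- function(skewKind = "three_prime", skewStrength = 0.5,
    noiseConcentration = 200, prototype = prototypeProfile()) {
    new("SkewProfileSpec", prototype = prototype, skewKind = skewKind,
        skewStrength = skewStrength,
        noiseConcentration = noiseConcentration)
}

# target profile of a spec (before per-cell noise)
.targetProfile <- function(spec) {
    (1 - spec@skewStrength) * spec@prototype +
        spec@skewStrength * .endProfile(spec@skewKind)
}

# one Dirichlet draw around the spec's target; assumes RNG already seeded
.drawCellProfile <- function(spec) {
    shape <- spec@noiseConcentration * .targetProfile(spec)
    g <- stats::rgamma(100L, shape = pmax(shape, 1e-6))
    s <- sum(g)
    if (s <= 0)
        g <- .targetProfile(spec)
    else
        g <- g / s
    g
}

#' Generate a labelled synthetic coverage cohort
#'
#' Draws \code{nTypical} cells from the typical profile family and
#' \code{nSkewed} cells from the skewed family (Dirichlet perturbation
#' around each family's target profile), in that order, with ids
#' \code{typ001.., skw001..}. Every generated vector is non-negative and
#' sums to one. When \code{dir} is given the cohort is written in both
#' store dialects plus a truth-label table, so planted-outlier recovery
#' can be scored.
#'
#' @param nTypical,nSkewed cohort composition; their sum must be at least
#'   12 (enough cells to fit a 10-dimensional Gaussian after trimming).
#' @param specTypical profile family of typical cells (default: prototype,
#'   \code{skewStrength = 0}).
#' @param specSkewed profile family of skewed cells (default 3'-loaded at
#'   \code{skewStrength = 0.5}).
#' @param seed RNG seed (full determinism per seed).
#' @param dir optional output directory.
#' @return list with \code{covset} ([CoverageSet-class]), \code{labels}
#'   (named factor typical/skewed), and when \code{dir} is given
#'   \code{store}, \code{coverageR}, \code{truth} paths.
#' @export
makeCoverageCohort <- function(nTypical = 90L, nSkewed = 10L,
    specTypical = skewProfileSpec(skewStrength = 0),
    specSkewed = skewProfileSpec(skewStrength = 0.5),
    seed = 1L, dir = NULL) {
    stopifnot(is(specTypical, "SkewProfileSpec"),
        is(specSkewed, "SkewProfileSpec"))
    .stopIfNot(nTypical + nSkewed >= 12L,
        "cohort too small: nTypical + nSkewed must be >= 12")
    ids <- c(sprintf("typ%03d", seq_len(nTypical)),
        sprintf("skw%03d", seq_len(nSkewed)))
    labels <- factor(rep(c("typical", "skewed"), c(nTypical, nSkewed)),
        levels = c("typical", "skewed"))
    names(labels) <- ids
    values <- .withSeed(seed, {
        rows <- c(
            lapply(seq_len(nTypical), function(i)
                .drawCellProfile(specTypical)),
            lapply(seq_len(nSkewed), function(i)
                .drawCellProfile(specSkewed)))
        do.call(rbind, rows)
    })
    rownames(values) <- ids
    covset <- CoverageSet(values)
    out <- list(covset = covset, labels = labels)
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        out$store <- writeCoverageStore(covset,
            file.path(dir, "coverage.tsv"))
        out$coverageR <- writeCoverageR(covset,
            file.path(dir, "coverage.r"))
        truth <- file.path(dir, "truth_labels.tsv")
        utils::write.table(
            data.frame(cell_id = ids, label = as.character(labels)),
            truth, sep = "\t", quote = FALSE, row.names = FALSE)
        out$truth <- truth
    }
    out
}

#' Generate a toy gene model
#'
#' Packs non-overlapping multi-exon transcripts onto one or two synthetic
#' contigs (\code{chrT1}, \code{chrT2}; 100 kb each), deterministic per
#' seed. Exon and intron sizes are drawn so each transcript has an mRNA
#' length comfortably above the default indexing threshold.
#'
#' @param nTranscripts number of transcripts (>= 1).
#' @param lengthRange range of per-exon sizes (bases), default c(120, 300).
#' @param nExonRange range of exon counts per transcript, default c(1, 4).
#' @param strandMix probability a transcript is on the plus strand.
#' @param nContigs 1 or 2 toy contigs.
#' @param seed RNG seed.
#' @param bedPath optional path; the model is also written as BED12.
#' @return list with \code{model} ([GeneModel-class]) and, when written,
#'   \code{bedPath}.
#' @export
makeGeneModel <- function(nTranscripts = 5L, lengthRange = c(120L, 300L),
    nExonRange = c(1L, 4L), strandMix = 0.5, nContigs = 1L, seed = 1L,
    bedPath = NULL) {
    .stopIfNot(nTranscripts >= 1L, "nTranscripts must be >= 1")
    .stopIfNot(nContigs %in% c(1L, 2L), "nContigs must be 1 or 2")
    contigs <- paste0("chrT", seq_len(nContigs))
    contigLen <- 100000L
    .withSeed(seed, {
        cursor <- stats::setNames(rep(1000L, nContigs), contigs)
        chrom <- character(nTranscripts)
        start <- integer(nTranscripts)
        end <- integer(nTranscripts)
        strand <- character(nTranscripts)
        sizes <- vector("list", nTranscripts)
        starts <- vector("list", nTranscripts)
        for (i in seq_len(nTranscripts)) {
            ctg <- sample(contigs, 1L)
            k <- sample(seq(nExonRange[1], nExonRange[2]), 1L)
            exonSizes <- sample(seq(lengthRange[1], lengthRange[2]), k,
                replace = TRUE)
            intronSizes <- if (k > 1L)
                sample(50:400, k - 1L, replace = TRUE) else integer(0)
            span <- sum(exonSizes) + sum(intronSizes)
            if (cursor[ctg] + span + 500L > contigLen)
                stop("infeasible packing: transcripts exceed toy contig ",
                    "length; reduce nTranscripts or sizes", call. = FALSE)
            s0 <- cursor[ctg]
            offs <- cumsum(c(0L, utils::head(exonSizes, -1) +
                intronSizes))
            chrom[i] <- ctg
            start[i] <- s0
            end[i] <- s0 + span
            strand[i] <- if (stats::runif(1) < strandMix) "+" else "-"
            sizes[[i]] <- as.integer(exonSizes)
            starts[[i]] <- as.integer(offs)
            cursor[ctg] <- cursor[ctg] + span + sample(200:600, 1L)
        }
        model <- GeneModel(chrom, start, end,
            sprintf("tx%03d", seq_len(nTranscripts)), strand, sizes,
            starts, speciesLabel = "toy")
        out <- list(model = model)
        if (!is.null(bedPath)) {
            writeBed12(model, bedPath)
            out$model@sourcePath <- bedPath
            out$bedPath <- bedPath
        }
        out
    })
}

#' Generate a barcoded BAM with known per-cell read placements
#'
#' Places reads along the transcripts of a toy [GeneModel-class] by
#' sampling a gene-body bin from each cell's profile and laying a read of
#' \code{readLength} transcript bases from a position inside that bin;
#' reads crossing introns get spliced (\code{M}/\code{N}) CIGARs. Each
#' read carries its cell barcode in the \code{CB} tag. A truth table
#' records every read's cell, transcript and transcript-coordinate
#' interval, enabling exact per-base pileup oracles. The SAM text is
#' converted to a coordinate-sorted, indexed BAM.
#'
#' @param model a [GeneModel-class] on the toy contigs.
#' @param barcodes character vector of unique cell barcodes.
#' @param readsPerCell reads per barcode (single value or per-cell vector).
#' @param profiles a [SkewProfileSpec-class] shared by all cells, or a
#'   list of one spec per barcode.
#' @param readLength read length in transcript bases (default 60).
#' @param seed RNG seed.
#' @param outPath output BAM path (\code{.bam}).
#' @return list with \code{bam} (path) and \code{truth} (data.frame:
#'   \code{qname, cell, txId, txName, tcStart0, tcEnd0}).
#' @export
makeBarcodedBam <- function(model, barcodes, readsPerCell = 100L,
    profiles = skewProfileSpec(skewStrength = 0), readLength = 60L,
    seed = 1L, outPath = tempfile(fileext = ".bam")) {
    stopifnot(is(model, "GeneModel"))
    .stopIfNot(!anyDuplicated(barcodes), "barcodes must be unique")
    nCells <- length(barcodes)
    if (length(readsPerCell) == 1L)
        readsPerCell <- rep(readsPerCell, nCells)
    .stopIfNot(sum(readsPerCell) > 0, "zero reads requested")
    if (is(profiles, "SkewProfileSpec"))
        profiles <- rep(list(profiles), nCells)
    .stopIfNot(length(profiles) == nCells,
        "profiles must match the number of barcodes")
    gr <- model@transcripts
    blocks <- S4Vectors::mcols(gr)$blocks
    L <- vapply(blocks, function(b) sum(BiocGenerics::width(b)), 0L)
    strands <- as.character(GenomicRanges::strand(gr))
    contigs <- unique(as.character(GenomicRanges::seqnames(gr)))

    rows <- .withSeed(seed, {
        recs <- list()
        truth <- list()
        q <- 0L
        for (ci in seq_len(nCells)) {
            prof <- .drawCellProfile(profiles[[ci]])
            for (r in seq_len(readsPerCell[ci])) {
                q <- q + 1L
                ti <- sample.int(length(gr), 1L, prob = L)
                Li <- L[ti]
                b <- sample.int(100L, 1L, prob = prof)
                # transcript bases of bin b: [ceil((b-1)L/100), ceil(bL/100))
                lo <- as.integer(ceiling((b - 1) * Li / 100))
                hi <- as.integer(ceiling(b * Li / 100)) - 1L
                if (hi < lo) { lo <- 0L; hi <- Li - 1L }
                tc0 <- lo + sample.int(hi - lo + 1L, 1L) - 1L
                tcEnd0 <- min(tc0 + readLength, Li)
                mp <- .mapTcIntervals(blocks[[ti]], strands[ti],
                    tc0, tcEnd0)
                mp <- mp[order(mp$gstart), , drop = FALSE]
                cig <- character(0)
                for (j in seq_len(nrow(mp))) {
                    if (j > 1L)
                        cig <- c(cig, paste0(
                            mp$gstart[j] - mp$gend[j - 1L] - 1L, "N"))
                    cig <- c(cig,
                        paste0(mp$gend[j] - mp$gstart[j] + 1L, "M"))
                }
                qlen <- sum(mp$gend - mp$gstart + 1L)
                recs[[q]] <- paste(
                    sprintf("read%06d", q),
                    if (strands[ti] == "-") 16L else 0L,
                    as.character(GenomicRanges::seqnames(gr)[ti]),
                    mp$gstart[1L],
                    60L,
                    paste(cig, collapse = ""),
                    "*", 0L, 0L,
                    strrep("A", qlen),
                    "*",
                    paste0("CB:Z:", barcodes[ci]),
                    sep = "\t")
                truth[[q]] <- data.frame(
                    qname = sprintf("read%06d", q),
                    cell = barcodes[ci], txId = ti,
                    txName = S4Vectors::mcols(gr)$name[ti],
                    tcStart0 = tc0, tcEnd0 = tcEnd0,
                    stringsAsFactors = FALSE)
            }
        }
        list(recs = unlist(recs), truth = do.call(rbind, truth))
    })
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
        paste0("@SQ\tSN:", contigs, "\tLN:100000"))
    sam <- tempfile(fileext = ".sam")
    writeLines(c(hdr, rows$recs), sam)
    dest <- sub("\\.bam$", "", outPath)
    bam <- Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
        indexDestination = TRUE)
    unlink(sam)
    list(bam = bam, truth = rows$truth)
}
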