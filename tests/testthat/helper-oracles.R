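# Independent brute-force oracles. Everything here recomputes expected
# values from first principles, per base / per subset, without touching the
# package's internals.

suppressPackageStartupMessages({
    library(S4Vectors)
    library(IRanges)
    library(GenomicRanges)
})

# bin of transcript-oriented base i (0-based) for mRNA length L
oracleBinOf <- function(i, L, nBins = 100L) {
    floor(i * nBins / L) + 1L
}

# per-bin base counts from a per-base walk
oracleBinSizes <- function(L, nBins = 100L) {
    tabulate(oracleBinOf(seq_len(L) - 1L, L, nBins), nbins = nBins)
}

# every exonic genomic position of a transcript, in 5'->3' transcript order
oracleTxPositions <- function(blockStartsG, blockEndsG, strand) {
    pos <- unlist(lapply(seq_along(blockStartsG), function(j)
        seq(blockStartsG[j], blockEndsG[j])))
    if (strand == "-") rev(pos) else pos
}

# genomic position -> bin lookup for one transcript (named integer vector)
oracleBaseBins <- function(blockStartsG, blockEndsG, strand, nBins = 100L) {
    pos <- oracleTxPositions(blockStartsG, blockEndsG, strand)
    L <- length(pos)
    bins <- oracleBinOf(seq_len(L) - 1L, L, nBins)
    stats::setNames(bins, pos)
}

# exon-block fields of a GeneModel as plain per-record lists
modelBlocksOf <- function(model) {
    gr <- transcripts(model)
    lapply(seq_along(gr), function(i) {
        b <- S4Vectors::mcols(gr)$blocks[[i]]
        list(chrom = as.character(GenomicRanges::seqnames(gr)[i]),
            strand = as.character(GenomicRanges::strand(gr)[i]),
            starts = BiocGenerics::start(b), ends = BiocGenerics::end(b))
    })
}

# brute-force strand-aware per-base exon intersection: which records of
# `model` share >= 1 exonic base (same strand, same chrom) with any record
# of `exclusion`?
oracleOverlapHits <- function(model, exclusion) {
    mb <- modelBlocksOf(model)
    eb <- modelBlocksOf(exclusion)
    exclBases <- list()
    for (e in eb) {
        key <- paste(e$chrom, e$strand)
        bases <- unlist(mapply(seq, e$starts, e$ends, SIMPLIFY = FALSE))
        exclBases[[key]] <- c(exclBases[[key]], bases)
    }
    vapply(mb, function(m) {
        key <- paste(m$chrom, m$strand)
        if (is.null(exclBases[[key]])) return(FALSE)
        bases <- unlist(mapply(seq, m$starts, m$ends, SIMPLIFY = FALSE))
        any(bases %in% exclBases[[key]])
    }, FALSE)
}

# exact pileup oracle: expected per-bin covered-base counts for one cell,
# recomputed per base from the fixture truth table (transcript-coordinate
# read intervals), never from BAM or index
oraclePileupFromTruth <- function(truth, model, cell, nBins = 100L) {
    gr <- transcripts(model)
    L <- vapply(S4Vectors::mcols(gr)$blocks,
        function(b) sum(BiocGenerics::width(b)), 0L)
    counts <- numeric(nBins)
    rows <- truth[truth$cell == cell, , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
        ti <- rows$txId[r]
        for (i in seq(rows$tcStart0[r], rows$tcEnd0[r] - 1L)) {
            b <- oracleBinOf(i, L[ti], nBins)
            counts[b] <- counts[b] + 1
        }
    }
    counts
}

# independent eigenvalue-ratio restriction: clamp eigenvalues into
# [t, c * t], scanning all clamp-pattern breakpoints for the
# likelihood-optimal t
oracleRestrict <- function(S, restr) {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    pos <- lam[lam > 0]
    stopifnot(length(pos) > 0)
    cand <- sort(unique(c(pos, pos / restr)))
    vals <- vapply(cand, function(t) {
        lt <- pmin(pmax(lam, t), restr * t)
        sum(log(lt) + lam / lt)
    }, 0)
    t <- cand[which.min(vals)]
    lt <- pmin(pmax(lam, t), restr * t)
    e$vectors %*% (lt * t(e$vectors))
}

oracleLogLik <- function(X, mu, S) {
    d <- ncol(X)
    Sinv <- solve(S)
    centered <- sweep(X, 2, mu)
    md2 <- rowSums((centered %*% Sinv) * centered)
    sum(-0.5 * (d * log(2 * pi) + determinant(S)$modulus[1] + md2))
}

# exhaustive-subset trimmed MLE: the optimal trimmed log-likelihood over
# every size-m subset, each scored at its own restricted MLE
oracleTrimmedMLE <- function(X, alpha, restr = 50) {
    X <- as.matrix(X)
    n <- nrow(X)
    m <- floor(n * (1 - alpha))
    subsets <- utils::combn(n, m)
    best <- -Inf
    bestSubset <- NULL
    for (j in seq_len(ncol(subsets))) {
        idx <- subsets[, j]
        Xi <- X[idx, , drop = FALSE]
        mu <- colMeans(Xi)
        S <- crossprod(sweep(Xi, 2, mu)) / m
        S <- tryCatch(oracleRestrict(S, restr), error = function(e) NULL)
        if (is.null(S)) next
        ll <- oracleLogLik(Xi, mu, S)
        if (ll > best) {
            best <- ll
            bestSubset <- idx
        }
    }
    list(objective = best, retained = bestSubset)
}

# small deterministic toy model used by several suites:
# tx1 +: exons [100,150)+[250,300) ; tx2 -: single exon [400,600)
toyModel <- function() {
    GeneModel(
        chrom = c("chrT1", "chrT1"),
        start = c(100L, 400L),
        end = c(300L, 600L),
        name = c("tx1", "tx2"),
        strand = c("+", "-"),
        blockSizes = list(c(50L, 50L), 200L),
        blockStarts = list(c(0L, 150L), 0L))
}

# write a tiny BAM from explicit alignment rows (SAM columns + CB tag)
writeToyBam <- function(rows, contigs = "chrT1", contigLen = 100000L,
    path = tempfile(fileext = ".bam"), sort = TRUE) {
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
        paste0("@SQ\tSN:", contigs, "\tLN:", contigLen))
    sam <- tempfile(fileext = ".sam")
    writeLines(c(hdr, rows), sam)
    bam <- Rsamtools::asBam(sam, destination = sub("\\.bam$", "", path),
        overwrite = TRUE, indexDestination = sort)
    unlink(sam)
    bam
}

samRow <- function(qname, chrom, pos, cigar, flag = 0L, cb = NULL,
    mapq = 60L) {
    qlen <- sum(as.integer(
        regmatches(cigar, gregexpr("[0-9]+(?=[MIX=S])", cigar,
            perl = TRUE))[[1]]))
    paste(c(qname, flag, chrom, pos, mapq, cigar, "*", 0L, 0L,
        strrep("A", max(qlen, 1L)), "*",
        if (!is.null(cb)) paste0("CB:Z:", cb)), collapse = "\t")
}
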