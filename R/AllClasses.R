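#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom stats rgamma runif setNames dbeta
#' @importFrom utils write.table
NULL

#' Gene model backed by BED12 transcript records
#'
#' A \code{GeneModel} holds an ordered collection of transcript records as a
#' \link[GenomicRanges]{GRanges} (one range per transcript span) whose
#' metadata columns carry the transcript \code{name} and the exon
#' \code{blocks} (an \link[IRanges]{IRangesList} of genomic, 1-based closed
#' exon intervals). It is the coordinate substrate on which gene body
#' coverage is computed.
#'
#' @slot transcripts \code{GRanges} with mcols \code{name} (character) and
#'   \code{blocks} (\code{IRangesList}, genomic exon intervals, sorted,
#'   non-overlapping, spanning the transcript range).
#' @slot sourcePath path the model was read from ("" if built in memory).
#' @slot speciesLabel free label such as \code{"hg38"} or \code{"mm10"}.
#'
#' @seealso [readBed12()], [excludeOverlapping()], [buildBinIndex()]
#' @exportClass GeneModel
setClass("GeneModel",
    slots = c(
        transcripts = "GRanges",
        sourcePath = "character",
        speciesLabel = "character"
    )
)

setValidity("GeneModel", function(object) {
    gr <- object@transcripts
    mc <- S4Vectors::mcols(gr)
    if (!all(c("name", "blocks") %in% colnames(mc)))
        return("transcripts must carry 'name' and 'blocks' metadata columns")
    if (length(gr) == 0L)
        return(TRUE)
    if (!all(as.character(GenomicRanges::strand(gr)) %in% c("+", "-")))
        return("transcript strand must be '+' or '-'")
    blocks <- mc$blocks
    for (i in seq_along(gr)) {
        b <- blocks[[i]]
        if (length(b) < 1L)
            return(sprintf("record %d has no exon blocks", i))
        if (is.unsorted(BiocGenerics::start(b), strictly = TRUE) ||
            any(BiocGenerics::start(b)[-1] <= BiocGenerics::end(b)[-length(b)]))
            return(sprintf("record %d has unsorted or overlapping blocks", i))
        if (BiocGenerics::start(b)[1] != BiocGenerics::start(gr)[i] ||
            BiocGenerics::end(b)[length(b)] != BiocGenerics::end(gr)[i])
            return(sprintf(
                "record %d block arithmetic inconsistent with transcript span", i))
    }
    key <- paste(GenomicRanges::seqnames(gr), BiocGenerics::start(gr),
        BiocGenerics::end(gr), mc$name, GenomicRanges::strand(gr))
    if (anyDuplicated(key))
        return(sprintf("duplicate transcript record(s): %s",
            paste(unique(mc$name[duplicated(key)]), collapse = ", ")))
    TRUE
})

#' Gene-body bin index
#'
#' Maps every exonic (mRNA) base of each indexed transcript to one of
#' \code{nBins} contiguous gene-body bins, numbered 1..\code{nBins} from the
#' transcript 5' end to its 3' end. For a plus-strand transcript bin 1 holds
#' the genomically leftmost exonic bases; for a minus-strand transcript bin 1
#' holds the genomically rightmost. Bin sizes within a transcript differ by
#' at most one base. The index is keyed to its source model by a checksum so
#' a persisted index for a changed BED is rejected on load.
#'
#' @slot bins \code{GRanges} of maximal runs of equally-binned exonic bases,
#'   with mcols \code{txId} (record row in the source model), \code{txName}
#'   and \code{bin}.
#' @slot nBins number of gene-body bins (100 throughout this package).
#' @slot minMrnaLength transcripts with mRNA length below this were skipped.
#' @slot nSkipped number of transcripts skipped at build time.
#' @slot checksum digest of the source [GeneModel-class].
#' @slot sourceName basename stem of the source model, used for the
#'   persisted index filename.
#'
#' @seealso [buildBinIndex()], [writeBinIndex()], [readBinIndex()]
#' @exportClass BinIndex
setClass("BinIndex",
    slots = c(
        bins = "GRanges",
        nBins = "integer",
        minMrnaLength = "integer",
        nSkipped = "integer",
        checksum = "character",
        sourceName = "character"
    )
)

setValidity("BinIndex", function(object) {
    mc <- S4Vectors::mcols(object@bins)
    if (!all(c("txId", "txName", "bin") %in% colnames(mc)))
        return("bins must carry 'txId', 'txName' and 'bin' metadata columns")
    if (length(object@bins) > 0 &&
        (min(mc$bin) < 1L || max(mc$bin) > object@nBins))
        return("bin ids must lie in 1..nBins")
    if (object@nBins < 1L)
        return("nBins must be >= 1")
    TRUE
})

#' One cell's gene body coverage vector
#'
#' @slot cellId cell identifier (BAM filename stem or barcode).
#' @slot values numeric vector of length \code{nBins}: relative coverage per
#'   gene-body bin, summing to 1 unless the cell is degenerate (no counted
#'   bases), in which case all values are 0 and \code{degenerate} is TRUE.
#' @slot rawCounts integer-valued vector of covered-base counts per bin,
#'   pre-normalization.
#' @slot nReadsUsed number of eligible alignments that contributed.
#' @slot degenerate TRUE when no exonic base was covered.
#'
#' @seealso [computeCellCoverage()]
#' @exportClass CoverageVector
setClass("CoverageVector",
    slots = c(
        cellId = "character",
        values = "numeric",
        rawCounts = "numeric",
        nReadsUsed = "integer",
        degenerate = "logical"
    )
)

setValidity("CoverageVector", function(object) {
    if (length(object@values) != length(object@rawCounts))
        return("values and rawCounts must have equal length")
    if (any(object@values < 0) || any(object@rawCounts < 0))
        return("coverage values must be non-negative")
    s <- sum(object@values)
    if (!object@degenerate && abs(s - 1) > 1e-9)
        return("non-degenerate coverage values must sum to 1")
    if (object@degenerate && s != 0)
        return("degenerate coverage values must all be zero")
    TRUE
})

#' Cells-by-bins coverage container
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with one column per
#' cell and one row per gene-body bin (bin1..bin100, 5' to 3'). The
#' \code{"coverage"} assay holds relative (sum-to-one) coverage; when built
#' directly from BAMs a \code{"counts"} assay holds the raw covered-base
#' counts. Column data carry \code{nReadsUsed} and the \code{degenerate}
#' flag. Together with the cell identifiers (the column names) this is the
#' 101-column coverage matrix of the workflow: 100 bins plus the ID.
#'
#' @seealso [assembleCoverageMatrix()], [decileMeans()], [batchCoverage()]
#' @exportClass CoverageSet
setClass("CoverageSet", contains = "SummarizedExperiment")

setValidity("CoverageSet", function(object) {
    if (!"coverage" %in% SummarizedExperiment::assayNames(object))
        return("a CoverageSet needs a 'coverage' assay")
    if (is.null(colnames(object)) && ncol(object) > 0)
        return("cells must be named (column names = cell ids)")
    if (anyDuplicated(colnames(object)))
        return(sprintf("duplicate cell id(s): %s",
            paste(unique(colnames(object)[duplicated(colnames(object))]),
                collapse = ", ")))
    if (!"degenerate" %in%
        colnames(SummarizedExperiment::colData(object)))
        return("colData must carry a 'degenerate' flag")
    cov <- SummarizedExperiment::assay(object, "coverage")
    s <- colSums(cov)
    deg <- SummarizedExperiment::colData(object)$degenerate
    bad <- !deg & abs(s - 1) > 1e-9
    if (any(bad))
        return(sprintf("non-degenerate cell(s) not summing to 1: %s",
            paste(colnames(object)[bad], collapse = ", ")))
    TRUE
})

#' Trimmed-Gaussian (TCLUST, k = 1) clustering result
#'
#' Fit of a single Gaussian component to the best-fitting
#' \code{floor(n * (1 - alpha))} cells, with the remaining cells trimmed.
#' Retained cells are labelled \code{"typical"}, trimmed cells
#' \code{"skewed"}.
#'
#' @slot alpha trimming proportion in [0, 1).
#' @slot k number of clusters (fixed at 1).
#' @slot center fitted mean vector (length d, the decile means).
#' @slot covariance fitted d x d covariance, eigenvalue-ratio constrained.
#' @slot objective trimmed Gaussian log-likelihood of the retained set.
#' @slot labels factor with levels \code{typical}, \code{skewed}, named by
#'   cell id, in input row order.
#' @slot restrFactor eigenvalue-ratio bound applied to the covariance.
#' @slot seed,nStarts,nIter run metadata (seed, random restarts, iterations
#'   of the best start).
#'
#' @seealso [tclustK1()], [classifyCells()]
#' @exportClass ClusterResult
setClass("ClusterResult",
    slots = c(
        alpha = "numeric",
        k = "integer",
        center = "numeric",
        covariance = "matrix",
        objective = "numeric",
        labels = "factor",
        restrFactor = "numeric",
        seed = "integer",
        nStarts = "integer",
        nIter = "integer"
    )
)

setValidity("ClusterResult", function(object) {
    if (!identical(levels(object@labels), c("typical", "skewed")))
        return("labels must be a factor with levels typical, skewed")
    n <- length(object@labels)
    want <- floor(n * (1 - object@alpha))
    if (sum(object@labels == "typical") != want)
        return("number of typical cells must equal floor(n * (1 - alpha))")
    if (object@k != 1L)
        return("only k = 1 is supported")
    TRUE
})

#' Classification trimmed likelihood curve
#'
#' The optimal trimmed log-likelihood of the single-component fit as a
#' function of the trimming level alpha, plus the alpha selected from it.
#'
#' @slot alphas candidate trimming levels (ascending).
#' @slot objectives trimmed log-likelihood attained at each alpha.
#' @slot selectedAlpha the chosen trimming level.
#' @slot selectionRule identifier of the selection rule applied.
#'
#' @seealso [selectAlpha()]
#' @exportClass AlphaCurve
setClass("AlphaCurve",
    slots = c(
        alphas = "numeric",
        objectives = "numeric",
        selectedAlpha = "numeric",
        selectionRule = "character"
    )
)

setValidity("AlphaCurve", function(object) {
    if (length(object@alphas) != length(object@objectives))
        return("alphas and objectives must have equal length")
    if (length(object@alphas) == 0L)
        return("empty alpha grid")
    if (is.unsorted(object@alphas, strictly = TRUE))
        return("alphas must be strictly ascending")
    if (!object@selectedAlpha %in% object@alphas)
        return("selectedAlpha must be one of the grid values")
    TRUE
})

#' Per-cell profile specification for the synthetic coverage generator
#'
#' Describes a family of gene body coverage profiles: a prototype (mildly
#' mid-gene-peaked, summing to 1) optionally mixed toward a geometric
#' end-loaded profile (3' or 5'), with per-cell Dirichlet noise.
#'
#' @slot prototype 100-vector of non-negative values summing to 1.
#' @slot skewKind \code{"three_prime"} or \code{"five_prime"}.
#' @slot skewStrength mixing weight in [0, 1] toward the end-loaded profile
#'   (0 = pure prototype, i.e. a typical cell).
#' @slot noiseConcentration Dirichlet concentration scale; larger values give
#'   cells closer to the target profile.
#'
#' @seealso [skewProfileSpec()], [makeCoverageCohort()]
#' @exportClass SkewProfileSpec
setClass("SkewProfileSpec",
    slots = c(
        prototype = "numeric",
        skewKind = "character",
        skewStrength = "numeric",
        noiseConcentration = "numeric"
    )
)

setValidity("SkewProfileSpec", function(object) {
    if (length(object@prototype) != 100L)
        return("prototype must have 100 values")
    if (any(object@prototype < 0) || abs(sum(object@prototype) - 1) > 1e-9)
        return("prototype must be non-negative and sum to 1")
    if (!object@skewKind %in% c("three_prime", "five_prime"))
        return("skewKind must be 'three_prime' or 'five_prime'")
    if (object@skewStrength < 0 || object@skewStrength > 1)
        return("skewStrength must lie in [0, 1]")
    if (!is.finite(object@noiseConcentration) ||
        object@noiseConcentration <= 0)
        return("noiseConcentration must be a positive real")
    TRUE
})
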