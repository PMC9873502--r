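#' @include alpha.R
#' @importFrom grDevices png pdf dev.off adjustcolor
#' @importFrom graphics matlines matplot plot mtext legend title points axis
NULL

# open a deterministic plot device; cairo PNGs carry no timestamps, so
# re-rendering identical input yields identical bytes
.openDevice <- function(file, format, width = 7, height = 5) {
    if (format == "pdf") {
        grDevices::pdf(file, width = width, height = height,
            useDingbats = FALSE)
    } else {
        type <- if (capabilities("cairo")) "cairo" else NULL
        grDevices::png(file, width = width * 96, height = height * 96,
            res = 96, type = type %||% "quartz")
    }
}

#' Plot gene body coverage curves
#'
#' One curve per cell over the 100 gene-body bins (x: gene body percentile,
#' 5' to 3'; y: relative coverage). \code{subset} selects all cells, the
#' typical cells or the skewed cells of a clustering result; subset counts
#' are rendered in the caption in the \code{"n = typical : total"} style.
#' Requesting an empty subset is an error naming the subset (an empty plot
#' almost always means mismatched barcodes upstream).
#'
#' @param covset a [CoverageSet-class].
#' @param subset \code{"all"}, \code{"typical"} or \code{"skewed"}.
#' @param labels named typical/skewed factor (from [cellLabels()]);
#'   required for the typical/skewed subsets.
#' @param prjname project name stamped on the title.
#' @param file output file; default \code{<prjname>_<subset>_coverage.<fmt>}
#'   in the working directory.
#' @param format \code{"png"} (default) or \code{"pdf"}.
#' @param width,height device size in inches.
#' @return the plot file path, invisibly.
#' @export
plotGeneBodyCoverage <- function(covset, subset = c("all", "typical",
    "skewed"), labels = NULL, prjname = "COV", file = NULL,
    format = c("png", "pdf"), width = 7, height = 5) {
    subset <- match.arg(subset)
    format <- match.arg(format)
    v <- coverageValues(covset)
    nAll <- nrow(v)
    if (subset != "all") {
        .stopIfNot(!is.null(labels),
            "labels are required for the typical/skewed subsets")
        keep <- names(labels)[labels == subset]
        v <- v[rownames(v) %in% keep, , drop = FALSE]
    }
    if (nrow(v) == 0L)
        stop("empty subset '", subset, "': no cells to plot (check the ",
            "barcode/cell-id match upstream)", call. = FALSE)
    if (is.null(file))
        file <- paste0(.sanitizeFilename(prjname), "_", subset,
            "_coverage.", format)
    col <- switch(subset,
        all = grDevices::adjustcolor("steelblue4", 0.35),
        typical = grDevices::adjustcolor("#CC0000", 0.35),
        skewed = grDevices::adjustcolor("#202020", 0.5))
    .openDevice(file, format, width, height)
    on.exit(grDevices::dev.off())
    graphics::matplot(seq_len(ncol(v)), t(v), type = "l", lty = 1,
        col = col, xlab = "Gene body percentile (5' -> 3')",
        ylab = "Relative coverage",
        main = paste0(prjname, " gene body coverage (", subset, ")"))
    cap <- if (subset == "all") paste0("n = ", nrow(v))
        else paste0("n = ", nrow(v), " : ", nAll)
    graphics::mtext(cap, side = 3, line = 0.2, cex = 0.9)
    invisible(file)
}

#' Plot the mean (decile) coverage curves
#'
#' One curve per cell over the 10 decile means pmean10..pmean100.
#'
#' @param x a [CoverageSet-class] or a cells-by-10 decile-mean matrix.
#' @inheritParams plotGeneBodyCoverage
#' @return the plot file path, invisibly.
#' @export
plotMeanCoverage <- function(x, prjname = "COV", file = NULL,
    format = c("png", "pdf"), width = 7, height = 5) {
    format <- match.arg(format)
    m <- if (is(x, "CoverageSet")) suppressMessages(decileMeans(x))
        else as.matrix(x)
    if (nrow(m) == 0L)
        stop("empty subset 'all': no cells to plot", call. = FALSE)
    if (is.null(file))
        file <- paste0(.sanitizeFilename(prjname), "_mean_coverage.",
            format)
    .openDevice(file, format, width, height)
    on.exit(grDevices::dev.off())
    graphics::matplot(seq_len(10L), t(m), type = "l", lty = 1,
        col = grDevices::adjustcolor("steelblue4", 0.35), xaxt = "n",
        xlab = "Gene body decile", ylab = "Mean relative coverage",
        main = paste0(prjname, " mean gene body coverage"))
    graphics::axis(1, at = seq_len(10L), labels = colnames(m), las = 2,
        cex.axis = 0.8)
    graphics::mtext(paste0("n = ", nrow(m)), side = 3, line = 0.2,
        cex = 0.9)
    invisible(file)
}

#' Plot a clustering result in decile-mean space
#'
#' 2-D scatter of the first two decile-mean coordinates: typical cells as
#' red circles, skewed (trimmed) cells as black circles; alpha and k
#' stamped in the subtitle.
#'
#' @param result a [ClusterResult-class].
#' @param meanmat the decile-mean matrix the fit was run on (row-aligned
#'   with the result's labels).
#' @inheritParams plotGeneBodyCoverage
#' @return the plot file path, invisibly.
#' @export
plotClusterResult <- function(result, meanmat, prjname = "COV",
    file = NULL, format = c("png", "pdf"), width = 6, height = 6) {
    format <- match.arg(format)
    labels <- cellLabels(result)
    if (!identical(rownames(meanmat), names(labels)))
        stop("misaligned inputs: decile-mean rows and cluster labels ",
            "disagree", call. = FALSE)
    if (is.null(file))
        file <- paste0(.sanitizeFilename(prjname), "_cluster_alpha",
            result@alpha, ".", format)
    .openDevice(file, format, width, height)
    on.exit(grDevices::dev.off())
    col <- ifelse(labels == "typical", "#CC0000", "#202020")
    graphics::plot(meanmat[, 1L], meanmat[, 2L], col = col, pch = 1,
        xlab = colnames(meanmat)[1L], ylab = colnames(meanmat)[2L],
        main = paste0(prjname, " trimmed clustering result"))
    graphics::mtext(paste0("k = 1, alpha = ", result@alpha), side = 3,
        line = 0.2, cex = 0.9)
    graphics::legend("topright", legend = c("typical", "skewed"),
        col = c("#CC0000", "#202020"), pch = 1, bty = "n")
    invisible(file)
}
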