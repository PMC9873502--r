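#' @include plots.R filter.R
#' @importFrom jsonlite write_json toJSON
NULL

#' Write typical/skewed annotation tables for one clustering run
#'
#' Writes \code{TypicalCells.tsv} and \code{SkewedCells.tsv} (columns
#' \code{cell_id}, \code{annotation}, \code{alpha}) plus a JSON twin of
#' the annotation object (\code{annotation.json}: labels, fit parameters
#' and run metadata). With \code{suffix} the filenames gain
#' \code{_alpha<value>} so multi-alpha runs do not collide.
#'
#' @param result a [ClusterResult-class].
#' @param outdir output directory (created if missing).
#' @param suffix logical: append \code{_alpha<value>} to filenames.
#' @return named character vector of the three file paths.
#' @export
writeAnnotationTables <- function(result, outdir = "skewc",
    suffix = FALSE) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    tag <- if (suffix) paste0("_alpha", result@alpha) else ""
    labels <- cellLabels(result)
    mk <- function(which) {
        ids <- names(labels)[labels == which]
        data.frame(cell_id = ids, annotation = rep(which, length(ids)),
            alpha = rep(result@alpha, length(ids)),
            stringsAsFactors = FALSE)
    }
    paths <- c(
        typical = file.path(outdir, paste0("TypicalCells", tag, ".tsv")),
        skewed = file.path(outdir, paste0("SkewedCells", tag, ".tsv")),
        json = file.path(outdir, paste0("annotation", tag, ".json")))
    utils::write.table(mk("typical"), paths["typical"], sep = "\t",
        quote = FALSE, row.names = FALSE)
    utils::write.table(mk("skewed"), paths["skewed"], sep = "\t",
        quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
        alpha = result@alpha,
        k = result@k,
        n_typical = nTypical(result),
        n_skewed = nSkewed(result),
        objective = result@objective,
        center = result@center,
        covariance = result@covariance,
        restr_factor = result@restrFactor,
        seed = result@seed,
        n_starts = result@nStarts,
        n_iter = result@nIter,
        cells = data.frame(cell_id = names(labels),
            annotation = as.character(labels))),
        paths["json"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths
}

#' Build the HTML index of a report directory
#'
#' Writes a self-contained \code{index.html} linking the coverage plots,
#' the cluster scatter and the downloadable annotation tables. Every
#' listed component must exist; missing components raise an error naming
#' the gaps. Regeneration over unchanged inputs is byte-identical.
#'
#' @param outdir report directory.
#' @param files named character vector of component paths (relative to or
#'   inside \code{outdir}).
#' @param prjname project name for the page title.
#' @return path to \code{index.html}, invisibly.
#' @export
buildIndexHtml <- function(outdir, files, prjname = "COV") {
    missing <- files[!file.exists(files)]
    if (length(missing) > 0)
        stop("cannot build index.html; missing component(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
    rel <- basename(files)
    isImg <- grepl("\\.(png)$", rel)
    item <- function(name, f, img) {
        if (img)
            paste0("<h2>", name, "</h2>\n<img src=\"", f,
                "\" alt=\"", name, "\" style=\"max-width:100%\"/>")
        else
            paste0("<li><a href=\"", f, "\" download>", f, "</a></li>")
    }
    html <- c(
        "<!DOCTYPE html>",
        "<html><head><meta charset=\"utf-8\"/>",
        paste0("<title>", prjname, " gene body coverage QC</title>"),
        "<style>body{font-family:sans-serif;max-width:60em;margin:auto}",
        "</style></head><body>",
        paste0("<h1>", prjname,
            " &mdash; gene body coverage quality control</h1>"),
        unlist(lapply(which(isImg), function(i)
            item(names(files)[i], rel[i], TRUE))),
        "<h2>Downloads</h2>", "<ul>",
        unlist(lapply(which(!isImg), function(i)
            item(names(files)[i], rel[i], FALSE))),
        "</ul>", "</body></html>")
    path <- file.path(outdir, "index.html")
    writeLines(html, path)
    invisible(path)
}

#' Run coverage-matrix assembly, clustering and reporting end to end
#'
#' The analysis stage of the workflow: reads a coverage store, classifies
#' cells at the requested (or auto-selected) trimming level(s), and
#' populates \code{outdir} with the full report bundle — the all-cells
#' coverage plot, the mean-coverage plot, per-run typical and skewed
#' coverage plots, the cluster scatter, \code{TypicalCells.tsv} /
#' \code{SkewedCells.tsv} / \code{annotation.json} per run, and an
#' \code{index.html} linking everything. Either every component is
#' produced or the run fails loudly.
#'
#' @param store path to a coverage store (either dialect), or a
#'   [CoverageSet-class].
#' @param outdir report directory (default \code{"skewc"}).
#' @param prjname project name stamped on plots (default \code{"COV"}).
#' @param alphas trimming levels; empty for auto selection.
#' @param seed RNG seed for the clustering.
#' @param format plot format, \code{"png"} (default) or \code{"pdf"}.
#' @param ... further arguments for [classifyCells()].
#' @return invisibly, a list: \code{results} (the [classifyCells()]
#'   output), \code{files} (every artifact path), \code{index}.
#' @export
runSkewC <- function(store, outdir = "skewc", prjname = "COV",
    alphas = numeric(0), seed = 1L, format = c("png", "pdf"), ...) {
    format <- match.arg(format)
    covset <- if (is(store, "CoverageSet")) store
        else readCoverageStore(store)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    results <- classifyCells(covset, alphas = alphas, prjname = prjname,
        seed = seed, ...)
    meanmat <- suppressMessages(decileMeans(covset))
    multi <- length(results) > 1L
    files <- c(
        "Full gene body coverage (all cells)" = plotGeneBodyCoverage(
            covset, "all", prjname = prjname, format = format,
            file = file.path(outdir,
                paste0("coverage_all.", format))),
        "Mean gene body coverage" = plotMeanCoverage(covset,
            prjname = prjname, format = format,
            file = file.path(outdir, paste0("coverage_mean.", format))))
    for (i in seq_along(results)) {
        res <- results[[i]]
        tag <- if (multi) paste0("_alpha", res@alpha) else ""
        labels <- cellLabels(res)
        tables <- writeAnnotationTables(res, outdir, suffix = multi)
        fs <- c(
            plotClusterResult(res, meanmat, prjname = prjname,
                format = format,
                file = file.path(outdir,
                    paste0("cluster_result", tag, ".", format))),
            plotGeneBodyCoverage(covset, "typical", labels = labels,
                prjname = prjname, format = format,
                file = file.path(outdir,
                    paste0("coverage_typical", tag, ".", format))),
            if (nSkewed(res) > 0)
                plotGeneBodyCoverage(covset, "skewed", labels = labels,
                    prjname = prjname, format = format,
                    file = file.path(outdir,
                        paste0("coverage_skewed", tag, ".", format))))
        names(fs) <- paste0(
            c("Trimmed clustering result", "Typical cells coverage",
                if (nSkewed(res) > 0) "Skewed cells coverage"),
            if (multi) paste0(" (alpha = ", res@alpha, ")") else "")
        names(tables) <- paste0(c("Typical cells (TSV)",
            "Skewed cells (TSV)", "Annotation (JSON)"),
            if (multi) paste0(" (alpha = ", res@alpha, ")") else "")
        files <- c(files, fs, tables)
    }
    index <- buildIndexHtml(outdir, files, prjname = prjname)
    invisible(list(results = results, files = files, index = index))
}
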