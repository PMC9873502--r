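#' @include coverage-store.R
NULL

#' Pre-filter a coverage store by a cell-ID list
#'
#' Splits a coverage store into cells whose id appears in a plain-text
#' filter list (one id per line) and cells that do not: matching cells go
#' to \code{matchdir}, the rest to \code{unmatchdir} (both written in both
#' store dialects). The unmatch store is what a subsequent clustering run
#' consumes when unwanted cells — e.g. flagged by another QC method — are
#' removed before classification. Listed ids absent from the store are
#' reported with a warning.
#'
#' @param store path to a coverage store (either dialect).
#' @param filterList path to the id list; an empty list is an error.
#' @param matchdir,unmatchdir output directories (defaults \code{"match"}
#'   and \code{"unmatch"}).
#' @return named integer vector \code{c(matched, unmatched)}.
#' @export
filterCells <- function(store, filterList, matchdir = "match",
    unmatchdir = "unmatch") {
    ids <- sub("\\s+$", "", .readTextLines(filterList))
    ids <- ids[nzchar(ids)]
    if (length(ids) == 0L)
        stop("empty filter file: ", filterList, call. = FALSE)
    covset <- readCoverageStore(store)
    cells <- cellIds(covset)
    unknown <- setdiff(ids, cells)
    if (length(unknown) > 0)
        warning("filter id(s) absent from the store: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    hit <- cells %in% ids
    writeSubset <- function(sel, dir) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        if (any(sel)) {
            sub <- covset[, sel]
            writeCoverageStore(sub, file.path(dir, "coverage.tsv"))
            writeCoverageR(sub, file.path(dir, "coverage.r"))
        }
    }
    writeSubset(hit, matchdir)
    writeSubset(!hit, unmatchdir)
    c(matched = sum(hit), unmatched = sum(!hit))
}
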