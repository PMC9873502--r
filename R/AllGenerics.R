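#' @include AllClasses.R
NULL

#' Accessors for skewC classes
#'
#' Small accessor generics: \code{cellIds} returns the cell identifiers of a
#' container; \code{coverageValues} the cells-by-bins matrix of relative
#' coverage; \code{rawCounts} the cells-by-bins matrix of covered-base
#' counts (or NULL when unavailable); \code{isDegenerate} the per-cell
#' degeneracy flags; \code{cellLabels}, \code{typicalCells} and
#' \code{skewedCells} the typical/skewed annotation of a clustering result;
#' \code{nTypical}/\code{nSkewed} its class sizes; \code{selectedAlpha} the
#' trimming level chosen from a CTL curve; \code{mrnaLengths} the exonic
#' length of every transcript in a gene model.
#'
#' @param x a skewC object.
#' @return See each generic's description.
#' @name skewC-accessors
#' @aliases cellIds coverageValues rawCounts isDegenerate cellLabels
#'   typicalCells skewedCells nTypical nSkewed selectedAlpha mrnaLengths
NULL

#' @rdname skewC-accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname skewC-accessors
#' @export
setGeneric("coverageValues", function(x) standardGeneric("coverageValues"))

#' @rdname skewC-accessors
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))

#' @rdname skewC-accessors
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname skewC-accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname skewC-accessors
#' @export
setGeneric("typicalCells", function(x) standardGeneric("typicalCells"))

#' @rdname skewC-accessors
#' @export
setGeneric("skewedCells", function(x) standardGeneric("skewedCells"))

#' @rdname skewC-accessors
#' @export
setGeneric("nTypical", function(x) standardGeneric("nTypical"))

#' @rdname skewC-accessors
#' @export
setGeneric("nSkewed", function(x) standardGeneric("nSkewed"))

#' @rdname skewC-accessors
#' @export
setGeneric("selectedAlpha", function(x) standardGeneric("selectedAlpha"))

#' @rdname skewC-accessors
#' @export
setGeneric("mrnaLengths", function(x) standardGeneric("mrnaLengths"))

#' Decile means of gene body coverage
#'
#' Reduces each cell's 100-bin coverage vector to the 10 decile means
#' \code{pmean10..pmean100}, where \code{pmean10j} is the mean of bins
#' \code{10(j-1)+1 .. 10j}. This 10-dimensional summary is the feature
#' space in which cells are clustered.
#'
#' @param x a [CoverageSet-class] (or cells-by-100 numeric matrix).
#' @param dropDegenerate drop all-zero (degenerate) cells before reduction
#'   (default TRUE; their census is reported via a message). An error is
#'   raised when no usable cell remains.
#' @return cells-by-10 numeric matrix with columns pmean10..pmean100 and
#'   rownames the cell ids.
#' @examples
#' covset <- makeCoverageCohort(nTypical = 8, nSkewed = 4, seed = 1)$covset
#' dm <- decileMeans(covset)
#' dim(dm)  # 12 x 10
#' @export
setGeneric("decileMeans",
    function(x, dropDegenerate = TRUE) standardGeneric("decileMeans"))
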