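#' @include tclust.R coverage-store.R
NULL

#' Default trimming-level grid
#'
#' Candidate alphas used by auto mode: 0 to 0.30 in steps of 0.05.
#' @return numeric vector.
#' @export
defaultAlphaGrid <- function() seq(0, 0.30, by = 0.05)

#' Classification trimmed likelihood curve and alpha selection
#'
#' Computes the trimmed likelihood of the single-component fit
#' ([tclustK1()]) at every alpha of the grid (shared seed) — the k = 1
#' classification trimmed likelihood (CTL) curve. The curve records the
#' \emph{per-retained-cell} (mean) trimmed log-likelihood,
#' \code{objective / floor(n(1-alpha))}: trimming the worst-fitting cells
#' can never lower this quantity, so the curve is non-decreasing in alpha
#' regardless of the data's scale (the raw sum is not, because removing a
#' point with positive log-density lowers it). Because the curve is
#' non-decreasing, its literal maximum is uninformative (always the
#' largest alpha); the selection rule is therefore the point of maximum
#' discrete
#' curvature (the elbow where additional trimming stops paying): with
#' slopes \eqn{s_i} between consecutive grid points, the interior alpha
#' maximizing \eqn{s_{i-1} - s_i} is chosen, ties broken toward the
#' smaller alpha. Grids with fewer than three points fall back to the
#' smallest alpha attaining the maximal objective; a one-point grid
#' selects its value. The rule id \code{"curvature-elbow-v1"} is recorded
#' in the result.
#'
#' @param X n-by-d matrix of clustering features (decile means).
#' @param alphaGrid candidate trimming levels (each admissible for
#'   [tclustK1()]); default [defaultAlphaGrid()].
#' @param restrFactor,nStarts,maxIter,seed passed to [tclustK1()].
#' @return an [AlphaCurve-class].
#' @export
selectAlpha <- function(X, alphaGrid = defaultAlphaGrid(),
    restrFactor = 50, nStarts = 64L, maxIter = 100L, seed = 1L) {
    .stopIfNot(length(alphaGrid) > 0, "empty alpha grid")
    alphaGrid <- sort(unique(as.numeric(alphaGrid)))
    n <- nrow(as.matrix(X))
    obj <- vapply(alphaGrid, function(a)
        tclustK1(X, alpha = a, restrFactor = restrFactor,
            nStarts = nStarts, maxIter = maxIter,
            seed = seed)@objective / floor(n * (1 - a)),
        0)
    L <- length(alphaGrid)
    if (L < 3L) {
        sel <- alphaGrid[which.max(obj)]
    } else {
        slopes <- diff(obj) / diff(alphaGrid)
        curv <- utils::head(slopes, -1) - utils::tail(slopes, -1)
        # interior points alphaGrid[2..L-1]; ties toward smaller alpha
        sel <- alphaGrid[1L + which.max(curv)]
    }
    new("AlphaCurve", alphas = alphaGrid, objectives = obj,
        selectedAlpha = sel, selectionRule = "curvature-elbow-v1")
}

#' @rdname skewC-accessors
#' @export
setMethod("selectedAlpha", "AlphaCurve", function(x) x@selectedAlpha)

setMethod("show", "AlphaCurve", function(object) {
    cat("AlphaCurve (k = 1 classification trimmed likelihood)\n")
    print(stats::setNames(object@objectives, object@alphas))
    cat("  selected alpha:", object@selectedAlpha,
        "(rule:", object@selectionRule, ")\n")
})

#' Classify cells as typical or skewed
#'
#' Dispatches the three trimming-level modes of the workflow over the
#' decile-mean feature matrix: an empty \code{alphas} runs auto mode
#' ([selectAlpha()] on \code{alphaGrid}, then one fit at the selected
#' alpha); one value runs a single fit; several values run one independent
#' fit per alpha. All requested alphas are validated for admissibility
#' before any fit executes. Degenerate (all-zero) cells cannot be scored
#' and are excluded before clustering; their ids are reported in the
#' result's metadata as skewed-by-degeneracy.
#'
#' @param x a [CoverageSet-class], or an n-by-10 decile-mean matrix.
#' @param alphas numeric vector of trimming levels; empty for auto mode.
#' @param prjname project name stamped on outputs (default \code{"COV"}).
#' @param seed RNG seed shared by every fit.
#' @param alphaGrid auto-mode candidate grid.
#' @param restrFactor,nStarts,maxIter passed to [tclustK1()].
#' @return a \link[S4Vectors]{SimpleList} of [ClusterResult-class], one per
#'   run, named by alpha. Metadata fields: \code{prjname},
#'   \code{alphaCurve} (auto mode only), \code{degenerateCells},
#'   \code{seed}.
#' @examples
#' cohort <- makeCoverageCohort(nTypical = 45, nSkewed = 5, seed = 3)
#' res <- classifyCells(cohort$covset, alphas = 0.1)
#' nSkewed(res[[1]])  # floor(0.1 * 50) = 5
#' @export
classifyCells <- function(x, alphas = numeric(0), prjname = "COV",
    seed = 1L, alphaGrid = defaultAlphaGrid(), restrFactor = 50,
    nStarts = 64L, maxIter = 100L) {
    degenerate <- character(0)
    if (is(x, "CoverageSet")) {
        degenerate <- colnames(x)[isDegenerate(x)]
        X <- suppressMessages(decileMeans(x))
    } else {
        X <- as.matrix(x)
    }
    n <- nrow(X)
    d <- ncol(X)
    .stopIfNot(n > 0, "no cells to classify")
    checkAlphas <- if (length(alphas) == 0L) alphaGrid else alphas
    for (a in checkAlphas) {
        .stopIfNot(a >= 0 && a < 1,
            sprintf("inadmissible alpha %g: must lie in [0, 1)", a))
        .stopIfNot(floor(n * (1 - a)) >= d + 1L,
            sprintf("inadmissible alpha %g: floor(n(1-alpha)) < d+1", a))
    }
    curve <- NULL
    if (length(alphas) == 0L) {
        curve <- selectAlpha(X, alphaGrid = alphaGrid,
            restrFactor = restrFactor, nStarts = nStarts,
            maxIter = maxIter, seed = seed)
        alphas <- selectedAlpha(curve)
    }
    results <- lapply(alphas, function(a)
        tclustK1(X, alpha = a, restrFactor = restrFactor,
            nStarts = nStarts, maxIter = maxIter, seed = seed))
    out <- S4Vectors::SimpleList(results)
    names(out) <- as.character(alphas)
    S4Vectors::metadata(out) <- list(prjname = prjname,
        alphaCurve = curve, degenerateCells = degenerate,
        seed = as.integer(seed))
    out
}
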