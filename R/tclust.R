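#' @include AllClasses.R AllGenerics.R utils.R
NULL

# Gaussian log-density of rows of X at (mu, Sigma), via Cholesky.
.mvnLogDensity <- function(X, mu, Sigma) {
    d <- ncol(X)
    R <- chol(Sigma)
    centered <- sweep(X, 2L, mu)
    z <- backsolve(R, t(centered), transpose = TRUE)
    md2 <- colSums(z^2)
    -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) + md2)
}

# Optimal eigenvalue-ratio restriction for a single covariance: truncate
# eigenvalues to [t, c*t], choosing t to maximize the Gaussian likelihood
# (equivalently minimize sum(log(lt) + l/lt)). For one component the
# optimal constrained covariance shares the eigenvectors of S, so only the
# truncation level t needs searching; candidates are the points where the
# clamp pattern changes: {l_i, l_i / c}.
.restrictEigen <- function(S, restrFactor) {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    if (max(lam) <= .Machine$double.xmin)
        stop("degenerate data: covariance of the retained set is zero ",
            "(all points identical?)", call. = FALSE)
    if (min(lam) > 0 && max(lam) / min(lam) <= restrFactor)
        return(S)
    cand <- sort(unique(c(lam[lam > 0], lam[lam > 0] / restrFactor)))
    best <- NULL
    bestVal <- Inf
    for (t in cand) {
        lt <- pmin(pmax(lam, t), restrFactor * t)
        val <- sum(log(lt) + lam / lt)
        if (val < bestVal) {
            bestVal <- val
            best <- lt
        }
    }
    e$vectors %*% (best * t(e$vectors))
}

#' Trimmed Gaussian clustering with a single component (TCLUST, k = 1)
#'
#' Fits one Gaussian to the best-fitting \code{floor(n * (1 - alpha))}
#' rows of \code{X} by concentration steps: starting from a random
#' \code{(d+1)}-row subset's mean and covariance, every row is scored under
#' the current fit, the \code{floor(n * (1 - alpha))} highest-density rows
#' are retained, and center/covariance are re-estimated from them with the
#' covariance eigenvalues clipped so their ratio is at most
#' \code{restrFactor}; the cycle repeats until the retained set is stable
#' (or \code{maxIter}). The best of \code{nStarts} restarts by trimmed
#' log-likelihood wins. Retained rows are labelled \code{typical}, trimmed
#' rows \code{skewed}.
#'
#' The solver is deterministic given \code{seed} and row-order invariant:
#' rows are canonicalized (lexicographic sort) before any random draw, and
#' labels are mapped back to the input order, so permuting the input
#' permutes the labels identically.
#'
#' With \code{alpha = 0} the fit reduces to the (eigenvalue-clipped)
#' maximum-likelihood Gaussian and every row is typical.
#'
#' @param X numeric n-by-d matrix (rownames become cell ids); in this
#'   workflow the 10 decile means of the coverage profiles.
#' @param alpha trimming proportion, \code{0 <= alpha < 1}; the precondition
#'   \code{floor(n(1-alpha)) >= d + 1} must hold.
#' @param restrFactor eigenvalue-ratio bound (>= 1), default 50.
#' @param nStarts random restarts, default 64.
#' @param maxIter concentration-step cap per start, default 100.
#' @param seed RNG seed, default 1.
#' @return a [ClusterResult-class].
#' @examples
#' set.seed(42)
#' X <- rbind(matrix(rnorm(90 * 2), ncol = 2),
#'            matrix(rnorm(10 * 2, mean = 8), ncol = 2))
#' rownames(X) <- sprintf("c%03d", 1:100)
#' fit <- tclustK1(X, alpha = 0.1)
#' nSkewed(fit)  # 10
#' @export
tclustK1 <- function(X, alpha, restrFactor = 50, nStarts = 64L,
    maxIter = 100L, seed = 1L) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    n <- nrow(X)
    d <- ncol(X)
    .stopIfNot(is.numeric(alpha) && length(alpha) == 1L &&
        alpha >= 0 && alpha < 1, "alpha must lie in [0, 1)")
    .stopIfNot(restrFactor >= 1, "restrFactor must be >= 1")
    m <- floor(n * (1 - alpha))
    .stopIfNot(m >= d + 1L,
        sprintf("too few retained points: floor(n(1-alpha)) = %d < d+1 = %d",
            m, d + 1L))
    if (all(apply(X, 2L, function(col) diff(range(col)) == 0)))
        stop("degenerate data: all points identical", call. = FALSE)
    ids <- rownames(X) %||% sprintf("row%d", seq_len(n))

    # order-canonicalized internals: all randomness acts on sorted rows
    ord <- do.call(order, lapply(seq_len(d), function(j) X[, j]))
    Xc <- X[ord, , drop = FALSE]

    fitFrom <- function(mu, Sigma) {
        retained <- integer(0)
        iter <- 0L
        repeat {
            iter <- iter + 1L
            dens <- .mvnLogDensity(Xc, mu, Sigma)
            newRet <- sort(order(dens, decreasing = TRUE)[seq_len(m)])
            mu <- colMeans(Xc[newRet, , drop = FALSE])
            centered <- sweep(Xc[newRet, , drop = FALSE], 2L, mu)
            Sigma <- .restrictEigen(crossprod(centered) / m, restrFactor)
            if (identical(newRet, retained) || iter >= maxIter) {
                retained <- newRet
                break
            }
            retained <- newRet
        }
        obj <- sum(.mvnLogDensity(Xc[retained, , drop = FALSE], mu, Sigma))
        list(mu = mu, Sigma = Sigma, retained = retained, obj = obj,
            iter = iter)
    }

    best <- NULL
    .withSeed(seed, {
        for (s in seq_len(nStarts)) {
            if (s == 1L) {
                # deterministic start from the full-sample fit
                mu <- colMeans(Xc)
                centered <- sweep(Xc, 2L, mu)
                S0 <- crossprod(centered) / n
            } else {
                sub <- sample.int(n, d + 1L)
                mu <- colMeans(Xc[sub, , drop = FALSE])
                centered <- sweep(Xc[sub, , drop = FALSE], 2L, mu)
                S0 <- crossprod(centered) / (d + 1L)
            }
            fit <- tryCatch(
                fitFrom(mu, .restrictEigen(S0 +
                    diag(1e-12, d), restrFactor)),
                error = function(e) NULL)
            if (!is.null(fit) &&
                (is.null(best) || fit$obj > best$obj))
                best <- fit
        }
    })
    if (is.null(best))
        stop("degenerate data: no start produced a valid fit",
            call. = FALSE)
    lab <- rep("skewed", n)
    lab[ord[best$retained]] <- "typical"
    labels <- factor(lab, levels = c("typical", "skewed"))
    names(labels) <- ids
    new("ClusterResult", alpha = alpha, k = 1L, center = best$mu,
        covariance = best$Sigma, objective = best$obj, labels = labels,
        restrFactor = restrFactor, seed = as.integer(seed),
        nStarts = as.integer(nStarts), nIter = best$iter)
}

#' @rdname skewC-accessors
#' @export
setMethod("cellLabels", "ClusterResult", function(x) x@labels)

#' @rdname skewC-accessors
#' @export
setMethod("typicalCells", "ClusterResult", function(x)
    names(x@labels)[x@labels == "typical"])

#' @rdname skewC-accessors
#' @export
setMethod("skewedCells", "ClusterResult", function(x)
    names(x@labels)[x@labels == "skewed"])

#' @rdname skewC-accessors
#' @export
setMethod("nTypical", "ClusterResult", function(x)
    sum(x@labels == "typical"))

#' @rdname skewC-accessors
#' @export
setMethod("nSkewed", "ClusterResult", function(x)
    sum(x@labels == "skewed"))

#' Trimmed log-likelihood of a fit
#'
#' @param x a [ClusterResult-class] or [AlphaCurve-class].
#' @return the trimmed Gaussian log-likelihood (for a curve, one value per
#'   grid alpha).
#' @export
objective <- function(x) {
    if (is(x, "ClusterResult")) return(x@objective)
    if (is(x, "AlphaCurve")) return(x@objectives)
    stop("no objective for this object")
}

setMethod("show", "ClusterResult", function(object) {
    cat("ClusterResult (TCLUST, k = 1): alpha =", object@alpha, "\n")
    cat("  ", nTypical(object), "typical /", nSkewed(object),
        "skewed of", length(object@labels), "cells\n")
    cat("  trimmed log-likelihood:", format(object@objective), "\n")
    cat("  restrFactor =", object@restrFactor, ", nStarts =",
        object@nStarts, ", seed =", object@seed, "\n")
})
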