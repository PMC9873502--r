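cohortWithFit <- function(nTypical = 18, nSkewed = 2, seed = 23) {
    coh <- makeCoverageCohort(nTypical, nSkewed, seed = seed)
    res <- classifyCells(coh$covset, alphas = 0.1, seed = 1)
    list(covset = coh$covset, fit = res[[1]],
        meanmat = suppressMessages(decileMeans(coh$covset)))
}

test_that("coverage plots are written for each subset and the subsets
    partition the cohort", {
    x <- cohortWithFit()
    labels <- cellLabels(x$fit)
    d <- tempfile(); dir.create(d)
    fAll <- plotGeneBodyCoverage(x$covset, "all",
        file = file.path(d, "all.png"))
    fTyp <- plotGeneBodyCoverage(x$covset, "typical", labels = labels,
        file = file.path(d, "typ.png"))
    fSkw <- plotGeneBodyCoverage(x$covset, "skewed", labels = labels,
        file = file.path(d, "skw.png"))
    fMean <- plotMeanCoverage(x$covset, file = file.path(d, "mean.png"))
    expect_true(all(file.exists(c(fAll, fTyp, fSkw, fMean))))
    expect_equal(nTypical(x$fit) + nSkewed(x$fit),
        length(cellIds(x$covset)))
    # pdf flavor also renders
    fPdf <- plotGeneBodyCoverage(x$covset, "all", format = "pdf",
        file = file.path(d, "all.pdf"))
    expect_true(file.exists(fPdf))
})

test_that("an empty subset errors instead of writing an empty plot", {
    coh <- makeCoverageCohort(14, 2, seed = 24)
    fit0 <- classifyCells(coh$covset, alphas = 0, seed = 1)[[1]]
    expect_error(
        plotGeneBodyCoverage(coh$covset, "skewed",
            labels = cellLabels(fit0), file = tempfile()),
        "empty subset 'skewed'")
    expect_error(
        plotGeneBodyCoverage(coh$covset, "typical", file = tempfile()),
        "labels")
})

test_that("cluster scatter checks alignment and renders
    deterministically", {
    x <- cohortWithFit()
    f1 <- tempfile(fileext = ".png")
    f2 <- tempfile(fileext = ".png")
    plotClusterResult(x$fit, x$meanmat, file = f1)
    plotClusterResult(x$fit, x$meanmat, file = f2)
    expect_identical(readBin(f1, "raw", 9e6), readBin(f2, "raw", 9e6))

    expect_error(
        plotClusterResult(x$fit, x$meanmat[rev(seq_len(20)), ],
            file = tempfile()),
        "misaligned")
})

test_that("annotation tables and their JSON twin reflect the fit", {
    x <- cohortWithFit()
    d <- tempfile()
    paths <- writeAnnotationTables(x$fit, d)
    typ <- read.delim(paths["typical"])
    skw <- read.delim(paths["skewed"])
    expect_equal(nrow(typ), nTypical(x$fit))
    expect_equal(nrow(skw), nSkewed(x$fit))
    expect_equal(unique(typ$annotation), "typical")
    expect_equal(unique(typ$alpha), 0.1)
    js <- jsonlite::read_json(paths["json"], simplifyVector = TRUE)
    expect_equal(js$n_typical, nrow(typ))
    expect_equal(js$alpha, 0.1)
    expect_setequal(js$cells$cell_id, names(cellLabels(x$fit)))
})

test_that("index.html links every component or fails naming the gaps", {
    d <- tempfile(); dir.create(d)
    good <- file.path(d, c("a.png", "b.tsv"))
    file.create(good)
    names(good) <- c("Plot A", "Table B")
    idx <- buildIndexHtml(d, good)
    html <- readLines(idx)
    expect_true(any(grepl("a.png", html)))
    expect_true(any(grepl("b.tsv", html)))
    # regeneration is byte-identical
    before <- readLines(idx)
    buildIndexHtml(d, good)
    expect_identical(readLines(idx), before)

    bad <- c(good, "Missing" = file.path(d, "ghost.png"))
    expect_error(buildIndexHtml(d, bad), "ghost.png")
})

test_that("runSkewC produces the complete report bundle", {
    coh <- makeCoverageCohort(18, 2, seed = 25, dir = tempfile())
    out <- tempfile()
    bundle <- runSkewC(coh$store, outdir = out, prjname = "TOY",
        alphas = 0.1, seed = 1)
    files <- list.files(out)
    for (want in c("coverage_all.png", "coverage_mean.png",
        "coverage_typical.png", "coverage_skewed.png",
        "cluster_result.png", "TypicalCells.tsv", "SkewedCells.tsv",
        "annotation.json", "index.html"))
        expect_true(want %in% files, info = want)
    expect_true(all(file.exists(unname(bundle$files))))
    # multi-alpha runs emit one table set per alpha
    out2 <- tempfile()
    runSkewC(coh$store, outdir = out2, alphas = c(0.1, 0.2), seed = 1)
    expect_true(all(c("TypicalCells_alpha0.1.tsv",
        "TypicalCells_alpha0.2.tsv") %in% list.files(out2)))
})
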