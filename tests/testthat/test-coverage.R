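test_that("a read across the 5' half of a plus transcript fills bins
    1-50", {
    # single + transcript, one exon of 200 bases at [1000, 1200)
    model <- GeneModel("chrT1", 1000L, 1200L, "tx1", "+", list(200L),
        list(0L))
    idx <- buildBinIndex(model)
    # one 100-base read at transcript bases 0-99 (genomic 1001..1100)
    bam <- writeToyBam(samRow("r1", "chrT1", 1001L, "100M"))
    cv <- computeCellCoverage(bam, idx, cellId = "c1")
    expect_equal(rawCounts(cv), rep(c(2, 0), each = 50))
    expect_equal(coverageValues(cv), rep(c(0.02, 0), each = 50))
    expect_false(isDegenerate(cv))

    # identical read, minus-strand transcript: genomic left = 3' end
    modelM <- GeneModel("chrT1", 1000L, 1200L, "tx1", "-", list(200L),
        list(0L))
    cvM <- computeCellCoverage(bam, buildBinIndex(modelM), cellId = "c1")
    expect_equal(rawCounts(cvM), rep(c(0, 2), each = 50))
})

test_that("empty and contig-mismatched BAMs yield flagged degenerate
    vectors", {
    model <- GeneModel("chrT1", 1000L, 1200L, "tx1", "+", list(200L),
        list(0L))
    idx <- buildBinIndex(model)

    bam0 <- writeToyBam(character(0))
    cv0 <- computeCellCoverage(bam0, idx, cellId = "empty")
    expect_true(isDegenerate(cv0))
    expect_equal(sum(coverageValues(cv0)), 0)

    bamX <- writeToyBam(samRow("r1", "chrX", 10L, "20M"),
        contigs = "chrX")
    expect_warning(cvX <- computeCellCoverage(bamX, idx, cellId = "x"),
        "no contig")
    expect_true(isDegenerate(cvX))

    expect_error(computeCellCoverage(tempfile(), idx), "unreadable BAM")
})

test_that("N and D CIGAR segments cover no exonic base", {
    model <- GeneModel("chrT1", 1000L, 1200L, "tx1", "+", list(200L),
        list(0L))
    idx <- buildBinIndex(model)
    # 10M over bases 0-9, skip 20, 10M over bases 30-39; 4-base deletion
    # inside the second block consumes reference but must not count
    bam <- writeToyBam(samRow("r1", "chrT1", 1001L, "10M20N6M4D4M"))
    cv <- computeCellCoverage(bam, idx, cellId = "c1")
    covered <- c(0:9, 30:35, 40:43)  # transcript bases with M
    expected <- tabulate(oracleBinOf(covered, 200L), nbins = 100L)
    expect_equal(rawCounts(cv), expected)
})

test_that("binned raw counts equal the per-base pileup oracle on random
    fixtures", {
    for (seed in 1:6) {
        gm <- makeGeneModel(nTranscripts = sample(2:5, 1),
            nExonRange = c(1, 4), seed = seed)$model
        idx <- buildBinIndex(gm)
        bc <- "CELL-1"
        fix <- makeBarcodedBam(gm, bc, readsPerCell = sample(30:150, 1),
            profiles = skewProfileSpec(skewStrength = runif(1)),
            seed = seed + 50, outPath = tempfile(fileext = ".bam"))
        cv <- computeCellCoverage(fix$bam, idx, cellId = bc)
        expect_equal(rawCounts(cv),
            oraclePileupFromTruth(fix$truth, gm, bc),
            info = paste("seed", seed))
        # mass conservation: total counted bases = covered exonic bases
        expect_equal(sum(rawCounts(cv)),
            sum(fix$truth$tcEnd0 - fix$truth$tcStart0))
    }
})

test_that("coverage is invariant to read order and to sortedness", {
    model <- GeneModel("chrT1", 1000L, 1600L, "tx1", "+", list(600L),
        list(0L))
    idx <- buildBinIndex(model)
    set.seed(4)
    rows <- vapply(1:40, function(i) samRow(paste0("r", i), "chrT1",
        1001L + sample(0:550, 1), "50M"), "")
    bamSorted <- writeToyBam(rows)
    bamShuffled <- writeToyBam(sample(rows), sort = FALSE)
    a <- computeCellCoverage(bamSorted, idx, cellId = "c")
    b <- computeCellCoverage(bamShuffled, idx, cellId = "c")
    expect_equal(rawCounts(a), rawCounts(b))
    expect_equal(sum(coverageValues(a)), 1, tolerance = 1e-12)
})

test_that("a base shared by two overlapping transcripts increments both", {
    # two + transcripts sharing exon bases 1100..1199
    model <- GeneModel(c("chrT1", "chrT1"), c(1000L, 1100L),
        c(1200L, 1300L), c("txA", "txB"), c("+", "+"),
        list(200L, 200L), list(0L, 0L))
    idx <- buildBinIndex(model)
    bam <- writeToyBam(samRow("r1", "chrT1", 1101L, "10M"))
    cv <- computeCellCoverage(bam, idx, cellId = "c")
    # 10 bases on txA (transcript bases 100-109) + 10 on txB (bases 0-9)
    expect_equal(sum(rawCounts(cv)), 20)
})

test_that("batchCoverage is a deterministic, fault-tolerant census", {
    gm <- makeGeneModel(nTranscripts = 3, seed = 31)$model
    idx <- buildBinIndex(gm)
    bcs <- sprintf("CELL%02d-1", 1:5)
    indir <- tempfile(); dir.create(indir)
    for (b in bcs) {
        makeBarcodedBam(gm, b, readsPerCell = 40,
            seed = match(b, bcs) + 60,
            outPath = file.path(indir, paste0(b, ".bam")))
    }
    out1 <- tempfile()
    r1 <- suppressMessages(batchCoverage(indir, idx, outdir = out1))
    expect_equal(cellIds(r1$covset), sort(bcs))
    expect_equal(nrow(r1$failures), 0L)
    expect_true(all(file.exists(file.path(out1,
        paste0(bcs, ".log")))))

    # worker count must not change the store bytes
    out4 <- tempfile()
    r4 <- suppressMessages(batchCoverage(indir, idx, outdir = out4,
        workers = 4))
    expect_identical(readLines(r1$store), readLines(r4$store))
    expect_identical(readLines(r1$coverageR), readLines(r4$coverageR))

    # a corrupt BAM fails only its own cell and lands in the manifest
    writeLines("this is not a BAM", file.path(indir, "broken.bam"))
    outB <- tempfile()
    expect_warning(
        rB <- suppressMessages(batchCoverage(indir, idx, outdir = outB)),
        "1 cell")
    expect_equal(rB$failures$cell, "broken")
    expect_equal(length(cellIds(rB$covset)), 5L)

    expect_error(batchCoverage(tempfile(), idx, outdir = tempfile()),
        "no BAM files")
})
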