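test_that("equal-length single-exon transcripts divide evenly into bins", {
    model <- GeneModel("chrT1", 1000L, 1200L, "tx1", "+", list(200L),
        list(0L))
    idx <- buildBinIndex(model)
    b <- binRanges(idx)
    expect_equal(length(b), 100L)
    expect_true(all(BiocGenerics::width(b) == 2L))
    # bin 1 is the genomically leftmost pair on the plus strand
    b1 <- b[S4Vectors::mcols(b)$bin == 1L]
    expect_equal(BiocGenerics::start(b1), 1001L)
    expect_equal(BiocGenerics::end(b1), 1002L)

    # minus strand: bin 1 sits at the genomic right (transcript 5' end)
    modelM <- GeneModel("chrT1", 1000L, 1200L, "tx1", "-", list(200L),
        list(0L))
    bM <- binRanges(buildBinIndex(modelM))
    b1M <- bM[S4Vectors::mcols(bM)$bin == 1L]
    expect_equal(BiocGenerics::start(b1M), 1199L)
    expect_equal(BiocGenerics::end(b1M), 1200L)
})

test_that("uneven lengths split per the per-base walk (L = 253 case)", {
    # exons of 130 and 123 bases -> 53 bins of 3 and 47 bins of 2
    model <- GeneModel("chrT1", 0L, 400L, "tx1", "+", list(c(130L, 123L)),
        list(c(0L, 277L)))
    idx <- buildBinIndex(model)
    b <- binRanges(idx)
    sizes <- vapply(1:100, function(k)
        sum(BiocGenerics::width(b[S4Vectors::mcols(b)$bin == k])), 0L)
    expect_equal(sizes, oracleBinSizes(253L))
    expect_equal(sum(sizes == 3L), 53L)
    expect_equal(sum(sizes == 2L), 47L)
})

test_that("bin balance, conservation and strand reflection hold on random
    models", {
    for (seed in 1:5) {
        gm <- makeGeneModel(nTranscripts = 6, nExonRange = c(1, 5),
            seed = seed)$model
        idx <- buildBinIndex(gm)
        b <- binRanges(idx)
        L <- unname(mrnaLengths(gm))
        for (t in unique(S4Vectors::mcols(b)$txId)) {
            bt <- b[S4Vectors::mcols(b)$txId == t]
            sizes <- vapply(1:100, function(k) sum(BiocGenerics::width(
                bt[S4Vectors::mcols(bt)$bin == k])), 0L)
            expect_equal(sum(sizes), L[t])                 # conservation
            expect_lte(max(sizes) - min(sizes), 1L)        # balance
            expect_equal(sizes, oracleBinSizes(L[t]))      # per-base walk
        }

        # flipping every strand reverses each transcript's bin order
        gr <- transcripts(gm)
        flipped <- gm
        flipped@transcripts <- {
            g2 <- gr
            GenomicRanges::strand(g2) <- ifelse(
                as.character(GenomicRanges::strand(gr)) == "+", "-", "+")
            g2
        }
        bF <- binRanges(buildBinIndex(flipped))
        for (t in unique(S4Vectors::mcols(b)$txId)) {
            bt <- b[S4Vectors::mcols(b)$txId == t]
            btF <- bF[S4Vectors::mcols(bF)$txId == t]
            Lt <- L[t]
            for (k in c(1L, 37L, 100L)) {
                fwd <- bt[S4Vectors::mcols(bt)$bin == k]
                # genomic bases of bin k forward = bin 101-k reflected,
                # when bin sizes agree (they do: size(k) vs size(101-k)
                # may differ by 1 base, so compare base sets via the
                # per-base oracle instead)
                blocks <- S4Vectors::mcols(gr)$blocks[[t]]
                ob <- oracleBaseBins(BiocGenerics::start(blocks),
                    BiocGenerics::end(blocks),
                    as.character(GenomicRanges::strand(gr))[t])
                obF <- oracleBaseBins(BiocGenerics::start(blocks),
                    BiocGenerics::end(blocks),
                    ifelse(as.character(
                        GenomicRanges::strand(gr))[t] == "+", "-", "+"))
                basesFwd <- as.integer(names(ob)[ob == k])
                basesRevIdx <- as.integer(names(obF)[obF == k])
                gotFwd <- unlist(mapply(seq, BiocGenerics::start(fwd),
                    BiocGenerics::end(fwd), SIMPLIFY = FALSE))
                expect_setequal(gotFwd, basesFwd)
                revBin <- btF[S4Vectors::mcols(btF)$bin == k]
                gotRev <- unlist(mapply(seq, BiocGenerics::start(revBin),
                    BiocGenerics::end(revBin), SIMPLIFY = FALSE))
                expect_setequal(gotRev, basesRevIdx)
            }
        }
    }
})

test_that("length filtering and empty-model errors behave as specified", {
    model <- GeneModel(c("chrT1", "chrT1"), c(0L, 1000L), c(50L, 1200L),
        c("short", "long"), c("+", "+"), list(50L, 200L), list(0L, 0L))
    expect_message(idx <- buildBinIndex(model), "1 transcript")
    expect_equal(unique(S4Vectors::mcols(binRanges(idx))$txName), "long")
    expect_error(
        suppressMessages(buildBinIndex(model, minMrnaLength = 1000L)),
        "empty model")
})

test_that("a persisted index reloads identically and rejects stale
    checksums", {
    gm <- makeGeneModel(nTranscripts = 4, seed = 9,
        bedPath = tempfile(fileext = ".bed"))
    model <- readBed12(gm$bedPath)
    idx <- buildBinIndex(model)
    refDir <- tempfile()
    path <- writeBinIndex(idx, refDir)
    back <- readBinIndex(path, model = model)
    expect_equal(back@checksum, idx@checksum)
    expect_equal(back@nBins, idx@nBins)
    expect_equal(S4Vectors::mcols(back@bins)$bin,
        S4Vectors::mcols(idx@bins)$bin)
    expect_equal(BiocGenerics::start(back@bins),
        BiocGenerics::start(idx@bins))

    # a changed model must reject the old index and instruct a rebuild
    other <- makeGeneModel(nTranscripts = 4, seed = 10)$model
    expect_error(readBinIndex(path, model = other), "stale index.*rebuild")
})
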