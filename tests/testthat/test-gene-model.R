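test_that("readBed12 parses records, coordinates and block structure", {
    bed <- tempfile(fileext = ".bed")
    writeLines(paste("chr1", 100, 300, "tx1", 0, "+", 100, 300, 0, 2,
        "50,50", "0,150", sep = "\t"), bed)
    model <- readBed12(bed)
    gr <- transcripts(model)
    expect_length(gr, 1L)
    expect_equal(BiocGenerics::start(gr), 101L)  # 1-based internal
    expect_equal(BiocGenerics::end(gr), 300L)
    expect_equal(unname(mrnaLengths(model)), 100L)

    # empty file is a valid, empty model
    empty <- tempfile(fileext = ".bed")
    writeLines(character(0), empty)
    expect_length(transcripts(readBed12(empty)), 0L)

    # track/browser/comment lines are skipped
    withHdr <- tempfile(fileext = ".bed")
    writeLines(c("track name=test", "# comment",
        paste("chr1", 0, 100, "a", 0, "-", 0, 100, 0, 1, "100", "0",
            sep = "\t")), withHdr)
    expect_length(transcripts(readBed12(withHdr)), 1L)

    # gzip input is transparent
    gz <- tempfile(fileext = ".bed.gz")
    con <- gzfile(gz, "wt")
    writeLines(paste("chr1", 100, 300, "tx1", 0, "+", 100, 300, 0, 2,
        "50,50", "0,150", sep = "\t"), con)
    close(con)
    expect_equal(unname(mrnaLengths(readBed12(gz))), 100L)
})

test_that("readBed12 rejects malformed input with line numbers", {
    expect_error(readBed12(tempfile()), "not found")

    short <- tempfile(fileext = ".bed")
    writeLines(c(
        paste("chr1", 0, 100, "ok", 0, "+", 0, 100, 0, 1, "100", "0",
            sep = "\t"),
        paste("chr1", 200, 300, "bad", 0, "+", sep = "\t")), short)
    expect_error(readBed12(short), "line 2.*columns")

    badArith <- tempfile(fileext = ".bed")
    writeLines(paste("chr1", 100, 300, "tx1", 0, "+", 100, 300, 0, 2,
        "50,40", "0,150", sep = "\t"), badArith)
    expect_error(readBed12(badArith), "block arithmetic")

    dup <- tempfile(fileext = ".bed")
    line <- paste("chr1", 100, 300, "tx1", 0, "+", 100, 300, 0, 1, "200",
        "0", sep = "\t")
    writeLines(c(line, line), dup)
    expect_error(readBed12(dup), "duplicate")

    # duplicated names with distinct coordinates are tolerated
    dupName <- tempfile(fileext = ".bed")
    writeLines(c(line,
        paste("chr1", 500, 700, "tx1", 0, "+", 500, 700, 0, 1, "200",
            "0", sep = "\t")), dupName)
    expect_length(transcripts(readBed12(dupName)), 2L)
})

test_that("fixture BED round trip write -> read -> write is byte-identical", {
    gm <- makeGeneModel(nTranscripts = 5, seed = 11,
        bedPath = tempfile(fileext = ".bed"))
    model <- readBed12(gm$bedPath)
    again <- tempfile(fileext = ".bed")
    writeBed12(model, again)
    expect_identical(readLines(again), readLines(gm$bedPath))
})

test_that("readBed12 agrees with the rtracklayer importer on fixtures", {
    skip_if_not_installed("rtracklayer")
    gm <- makeGeneModel(nTranscripts = 6, nContigs = 2, seed = 3,
        bedPath = tempfile(fileext = ".bed"))
    model <- readBed12(gm$bedPath)
    ref <- rtracklayer::import(gm$bedPath, format = "bed")
    gr <- transcripts(model)
    expect_equal(as.character(GenomicRanges::seqnames(gr)),
        as.character(GenomicRanges::seqnames(ref)))
    expect_equal(BiocGenerics::start(gr), BiocGenerics::start(ref))
    expect_equal(BiocGenerics::end(gr), BiocGenerics::end(ref))
    expect_equal(S4Vectors::mcols(gr)$name, ref$name)
    # exon blocks match rtracklayer's parsed blocks (relative -> genomic)
    for (i in seq_along(gr)) {
        refBlocks <- IRanges::shift(ref$blocks[[i]],
            BiocGenerics::start(ref)[i] - 1L)
        expect_equal(BiocGenerics::start(
            S4Vectors::mcols(gr)$blocks[[i]]),
            BiocGenerics::start(refBlocks))
        expect_equal(BiocGenerics::width(
            S4Vectors::mcols(gr)$blocks[[i]]),
            BiocGenerics::width(refBlocks))
    }
})

test_that("excludeOverlapping implements split, strand-aware, whole-record
    subtraction", {
    model <- toyModel()  # tx1 +: [100,150)+[250,300); tx2 -: [400,600)

    # empty exclusion: identity
    empty <- GeneModel(character(0), integer(0), integer(0), character(0),
        character(0), list(), list())
    expect_identical(transcripts(excludeOverlapping(model, empty)),
        transcripts(model))

    # exclusion exon covering only tx1's intron: record kept (-split)
    intronic <- GeneModel("chrT1", 150L, 250L, "rRNA1", "+", list(100L),
        list(0L))
    kept <- excludeOverlapping(model, intronic)
    expect_equal(S4Vectors::mcols(transcripts(kept))$name,
        c("tx1", "tx2"))

    # same interval as an exon hit on the wrong strand: kept (-s)
    minusHit <- GeneModel("chrT1", 120L, 130L, "rRNA2", "-", list(10L),
        list(0L))
    expect_equal(
        S4Vectors::mcols(transcripts(
            excludeOverlapping(model, minusHit)))$name,
        c("tx1", "tx2"))

    # matching strand: tx1 removed whole (-wa semantics), order preserved
    plusHit <- GeneModel("chrT1", 120L, 130L, "rRNA2", "+", list(10L),
        list(0L))
    expect_equal(
        S4Vectors::mcols(transcripts(
            excludeOverlapping(model, plusHit)))$name,
        "tx2")
})

test_that("excludeOverlapping matches the per-base set oracle on random
    models", {
    for (seed in 1:8) {
        gm <- makeGeneModel(nTranscripts = 10, nContigs = 2,
            seed = seed)$model
        excl <- makeGeneModel(nTranscripts = 4, nContigs = 2,
            seed = seed + 100)$model
        hits <- oracleOverlapHits(gm, excl)
        got <- excludeOverlapping(gm, excl)
        expect_equal(
            S4Vectors::mcols(transcripts(got))$name,
            S4Vectors::mcols(transcripts(gm))$name[!hits],
            info = paste("seed", seed))
    }
})
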