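Package: skewC
Title: Gene Body Coverage Quality Control for Single-Cell RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quality assessment of single-cell RNA-seq data from gene body
    coverage. Each cell's aligned reads are summarized as a normalized
    100-bin coverage profile along the gene body (5' to 3', over exonic
    bases of a BED12 gene model), and cells are classified as "typical"
    (prototypical coverage) or "skewed" (distorted, e.g. 3'-loaded,
    coverage) by trimmed Gaussian clustering (TCLUST with k = 1) of the
    10 decile means of the profile. Includes barcoded-BAM splitting by
    cell barcode, a batchable coverage engine, trimming-level (alpha)
    selection from classification trimmed likelihood curves, plotting,
    an HTML report, and a synthetic-data generator for gene models,
    barcoded BAMs and coverage cohorts with controllable skew.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    parallel,
    digest,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
biocViews: SingleCell, QualityControl, RNASeq, Coverage, Clustering
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'gene-model.R'
    'bin-index.R'
    'coverage.R'
    'coverage-store.R'
    'utils.R'
    'tclust.R'
    'alpha.R'
    'barcode-split.R'
    'filter.R'
    'fixtures.R'
    'plots.R'
    'report.R'
    'skewC-package.R'
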