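Package: rohscan
Title: Runs of Homozygosity, Inbreeding and Population Structure for
    Composite Livestock Breeds
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide assessment of composite (synthetic)
    livestock breeds from SNP-array genotypes: PLINK text/binary input and
    output, staged quality control (call rate, minor allele frequency,
    linkage-disequilibrium pruning), observed/expected heterozygosity and
    homozygosity-based inbreeding (F_HOM), principal component analysis,
    supervised two-way ancestry estimation, sliding-window detection of
    runs of homozygosity (ROH) with L-parameter thresholds, ROH-based
    inbreeding (F_ROH), ROH size-class spectra, ROH-island scans with
    incidence z-scores, concatenated-region and parental-overlap interval
    algebra, and gene/QTL annotation of island bins. A pedigree gene-drop
    simulator with ancestry-tract truth emulates a two-founder crossing
    scheme (two divergent founder breeds, F1, F2 and a composite F3) so
    every stage of the pipeline can be verified on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SNP, Genetics, PopulationGenetics, QualityControl
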