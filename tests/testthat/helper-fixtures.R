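# Shared fixtures.  Simulations are cached per test run so several test
# files can reuse them without recomputation.

.fixtureCache <- new.env(parent = emptyenv())

# small 4-chromosome world: fast enough for unit/property tests, dense
# enough (40 kb SNP spacing) for the ROH density rule
smallGenome <- function() genomeInfo(setNames(rep(20e6, 4), as.character(1:4)))

smallSim <- function() {
    if (is.null(.fixtureCache$small)) {
        cfg <- simConfig(nSnps = 2000, genome = smallGenome(),
                         cohortSizes = c(DUC = 30, KNP = 30, F1 = 15,
                                         F2 = 30, WRH = 60),
                         neDuc = 50, neKnp = 6, burninGenerations = 10,
                         seed = 42)
        .fixtureCache$small <- simulateStudy(cfg)
    }
    .fixtureCache$small
}

# the default-scale stated world (18 autosomes, 2,262.6 Mb, 56,498 SNPs,
# 850 animals); built once, consumed by the acceptance tests
defaultSim <- function(seed = 20260917) {
    key <- paste0("default", seed)
    if (is.null(.fixtureCache[[key]]))
        .fixtureCache[[key]] <- simulateStudy(simConfig(seed = seed))
    .fixtureCache[[key]]
}

defaultRohScan <- function(seed = 20260917) {
    key <- paste0("roh", seed)
    if (is.null(.fixtureCache[[key]])) {
        sim <- defaultSim(seed)
        rohSub <- filterCallRate(sim$genotypes)$data
        pops <- c("DUC", "KNP", "F1", "F2", "WRH")
        segs <- lapply(pops, function(pp)
            suppressWarnings(detectRoh(rohSub, rohParamsFor(rohSub, pp),
                                       population = pp)))
        .fixtureCache[[key]] <- list(
            rohSub = rohSub,
            segments = do.call(rbind, c(segs, make.row.names = FALSE)))
    }
    .fixtureCache[[key]]
}

# per-population ROH scan over the small simulation, cached
smallScanFixture <- function() {
    if (is.null(.fixtureCache$smallScan)) {
        sim <- smallSim()
        rohSub <- filterCallRate(sim$genotypes)$data
        pops <- unique(populations(rohSub))
        segs <- lapply(pops, function(pp)
            suppressWarnings(detectRoh(rohSub, rohParamsFor(rohSub, pp),
                                       population = pp)))
        .fixtureCache$smallScan <- list(
            rohSub = rohSub,
            segments = do.call(rbind, c(segs, make.row.names = FALSE)))
    }
    .fixtureCache$smallScan
}

# hand-buildable dataset: dosage given variants x samples
toyDataset <- function(dosage, chrom = NULL, pos = NULL,
                       pops = NULL, spacingBp = 50000L) {
    m <- nrow(dosage); n <- ncol(dosage)
    if (is.null(chrom)) chrom <- rep("1", m)
    if (is.null(pos)) pos <- seq_len(m) * spacingBp
    if (is.null(pops)) pops <- rep("POP", n)
    genotypeData(dosage,
                 data.frame(snp_id = paste0("snp", seq_len(m)),
                            chrom = chrom, pos = pos,
                            allele_a = "A", allele_b = "G",
                            stringsAsFactors = FALSE),
                 sampleId = paste0("s", seq_len(n)), population = pops)
}

# single-sample dataset from a genotype vector, default 40 kb spacing
singleSampleDataset <- function(g, pos = NULL, chrom = "1") {
    toyDataset(matrix(as.integer(g), ncol = 1), chrom = rep(chrom, length(g)),
               pos = if (is.null(pos)) seq_along(g) * 40000L else pos)
}
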