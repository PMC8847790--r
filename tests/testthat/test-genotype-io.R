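# PLINK I/O, the data container, and coordinate remapping.

test_that("hand-written .ped/.map transcribes to the expected dosages", {
    dir <- withr::local_tempdir()
    writeLines(c("1\trs1\t0\t100", "1\trs2\t0\t200",
                 "1\trs3\t0\t300", "2\trs4\t0\t150"),
               file.path(dir, "toy.map"))
    writeLines(c(
        "DUC s1 0 0 0 -9  A A  G G  A G  C C",
        "DUC s2 0 0 0 -9  A G  G G  0 0  C T",
        "KNP s3 0 0 0 -9  G G  G G  A A  T T"),
        file.path(dir, "toy.ped"))
    ds <- readPlink(file.path(dir, "toy"), "text")
    expect_equal(nVariants(ds), 4L)
    expect_equal(populations(ds), c("DUC", "DUC", "KNP"))
    info <- snpInfo(ds)
    # rs1: alleles A<G, dosage counts G
    expect_equal(info$allele_b[info$snp_id == "rs1"], "G")
    expect_equal(unname(dosages(ds)["rs1", ]), c(0L, 1L, 2L))
    # rs2 monomorphic G: sole observed allele sits in allele_a, dosage 0
    expect_equal(info$allele_a[info$snp_id == "rs2"], "G")
    expect_equal(info$allele_b[info$snp_id == "rs2"], "0")
    expect_equal(unname(dosages(ds)["rs2", ]), c(0L, 0L, 0L))
    # rs3: "0 0" is missing
    expect_equal(unname(dosages(ds)["rs3", ]), c(1L, NA_integer_, 0L))
    # rs4 on chrom 2 sorts after chrom 1
    expect_equal(info$snp_id, c("rs1", "rs2", "rs3", "rs4"))
    expect_equal(unname(dosages(ds)["rs4", ]), c(0L, 1L, 2L))
})

test_that("mismatched .ped field count is a format error", {
    dir <- withr::local_tempdir()
    writeLines(c("1\trs1\t0\t100", "1\trs2\t0\t200"),
               file.path(dir, "bad.map"))
    writeLines("DUC s1 0 0 0 -9 A A", file.path(dir, "bad.ped"))
    expect_error(readPlink(file.path(dir, "bad"), "text"), "format error")
})

test_that("binary and text encodings of one dataset read back identically", {
    sim <- smallSim()
    # restrict to polymorphic SNPs so the .ped layout can represent alleles
    ds <- filterMaf(sim$genotypes, qcParams(mafMin = 0.01))$data
    ds <- ds[seq_len(300), seq_len(40)]
    dir <- withr::local_tempdir()
    writePlink(ds, file.path(dir, "bin"), "binary")
    writePlink(ds, file.path(dir, "txt"), "text")
    dsBin <- readPlink(file.path(dir, "bin"), "binary")
    dsTxt <- readPlink(file.path(dir, "txt"), "text")
    for (back in list(dsBin, dsTxt)) {
        expect_identical(dosages(back), dosages(ds))
        expect_identical(snpInfo(back), snpInfo(ds))
        expect_identical(sampleIds(back), sampleIds(ds))
        expect_identical(populations(back), populations(ds))
    }
})

test_that("binary round-trip preserves missing cells and allele labels", {
    sim <- smallSim()
    ds <- sim$genotypes[1:500, 1:60]
    expect_gt(sum(is.na(dosages(ds))), 0)  # simulator injects missingness
    dir <- withr::local_tempdir()
    writePlink(ds, file.path(dir, "rt"), "binary")
    back <- readPlink(file.path(dir, "rt"))  # auto-detect
    expect_identical(dosages(back), dosages(ds))
    expect_identical(snpInfo(back), snpInfo(ds))
})

test_that("an empty-variant dataset writes and reads as zero variant lines", {
    ds <- genotypeData(matrix(integer(0), 0, 2),
                       data.frame(snp_id = character(0), chrom = character(0),
                                  pos = integer(0), allele_a = character(0),
                                  allele_b = character(0)),
                       sampleId = c("a", "b"), population = c("P", "P"))
    dir <- withr::local_tempdir()
    writePlink(ds, file.path(dir, "empty"), "text")
    expect_equal(length(readLines(file.path(dir, "empty.map"))), 0L)
    back <- readPlink(file.path(dir, "empty"), "text")
    expect_equal(nVariants(back), 0L)
    expect_equal(sampleIds(back), c("a", "b"))
})

test_that("container invariants: sorting, duplicate rejection, dosage codes", {
    vr <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = c(200L, 100L),
                     allele_a = "A", allele_b = "G")
    ds <- genotypeData(matrix(c(2L, 0L), 2, 1), vr, "s1", "P")
    expect_equal(snpInfo(ds)$snp_id, c("b", "a"))     # sorted by pos
    expect_equal(unname(dosages(ds)[, 1]), c(0L, 2L)) # dosages follow snps
    vr$pos <- c(100L, 100L)
    expect_error(genotypeData(matrix(0L, 2, 1), vr, "s1", "P"), "duplicate")
    vr$pos <- c(100L, 200L)
    expect_error(genotypeData(matrix(c(3L, 0L), 2, 1), vr, "s1", "P"),
                 "dosage")
    # non-autosomal chromosomes are retained but flagged
    vr2 <- data.frame(snp_id = c("a", "b"), chrom = c("1", "X"),
                      pos = c(100L, 100L), allele_a = "A", allele_b = "G")
    dsx <- genotypeData(matrix(0L, 2, 1), vr2, "s1", "P")
    expect_equal(snpInfo(dsx)$flagged, c(FALSE, TRUE))
})

test_that("updateCoordinates remaps, flags unmapped, and re-sorts", {
    ds <- toyDataset(matrix(rep(c(0L, 1L, 2L), 4), nrow = 4, byrow = TRUE),
                     chrom = c("3", "5", "5", "5"),
                     pos = c(500L, 100L, 200L, 300L))
    info <- snpInfo(ds)
    # move snp2 (chrom 5) to chrom 3, drop snp3 from the map, zero out snp4
    remap <- data.frame(snp_id = c("snp1", "snp2", "snp4"),
                        chrom = c("3", "3", "0"),
                        pos = c(500L, 100L, 0L))
    res <- updateCoordinates(ds, remap)
    expect_equal(unname(res$report["remapped"]), 1L)
    expect_equal(unname(res$report["unmapped"]), 2L)  # snp3 absent, snp4 zeroed
    expect_equal(unname(res$report["unchanged"]), 1L)
    out <- snpInfo(res$data)
    expect_true(all(out$flagged[out$snp_id %in% c("snp3", "snp4")]))
    expect_equal(out$chrom[out$snp_id == "snp2"], "3")
    # re-sorted: snp2 now at 3:100 precedes snp1 at 3:500
    expect_lt(which(out$snp_id == "snp2"), which(out$snp_id == "snp1"))
})

test_that("a remap swapping two positions permutes dosage columns with the map", {
    d <- matrix(c(0L, 0L, 2L, 2L, 1L, 1L), nrow = 3, byrow = TRUE)
    ds <- toyDataset(d, chrom = rep("1", 3), pos = c(100L, 200L, 300L))
    remap <- data.frame(snp_id = c("snp1", "snp2", "snp3"),
                        chrom = "1", pos = c(200L, 100L, 300L))
    res <- updateCoordinates(ds, remap)
    out <- snpInfo(res$data)
    expect_equal(out$snp_id, c("snp2", "snp1", "snp3"))
    expect_equal(unname(dosages(res$data)["snp1", ]), c(0L, 0L))
    expect_equal(unname(dosages(res$data)["snp2", ]), c(2L, 2L))
})

test_that("a remap creating duplicate coordinates errors with the collision", {
    ds <- toyDataset(matrix(0L, 2, 2), pos = c(100L, 200L))
    remap <- data.frame(snp_id = c("snp1", "snp2"), chrom = "1",
                        pos = c(300L, 300L))
    expect_error(updateCoordinates(ds, remap), "duplicate")
})

test_that("simulator datasets round-trip through both layouts (scale check)", {
    sim <- smallSim()
    ds <- filterMaf(sim$genotypes, qcParams(mafMin = 0.001))$data
    dir <- withr::local_tempdir()
    t0 <- Sys.time()
    writePlink(ds, file.path(dir, "a"), "binary")
    b <- readPlink(file.path(dir, "a"), "binary")
    writePlink(ds, file.path(dir, "b"), "text")
    tx <- readPlink(file.path(dir, "b"), "text")
    expect_identical(dosages(b), dosages(ds))
    expect_identical(dosages(tx), dosages(ds))
    expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 120)
})
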