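# ROH detection: L-parameter, sliding-window scan vs brute-force oracle,
# size classes, F_ROH.

test_that("L-parameter closed form and algebraic behaviour", {
    expect_equal(lParam(50000, 500, 0.35, 0.05), 47L)
    # independent evaluation of the closed form on random inputs
    set.seed(5)
    for (i in 1:20) {
        ns <- sample(1000:100000, 1); ni <- sample(10:2000, 1)
        het <- runif(1, 0.05, 0.9); a <- runif(1, 0.01, 0.2)
        expect_equal(lParam(ns, ni, het, a),
                     max(1, as.integer(ceiling(log(a / (ns * ni)) /
                                               log(1 - het)))))
    }
    # monotone decreasing in heterozygosity; small near het -> 1
    hets <- seq(0.05, 0.95, by = 0.05)
    ls <- vapply(hets, function(h) lParam(10000, 100, h), integer(1))
    expect_true(all(diff(ls) <= 0))
    expect_lte(lParam(10000, 100, 0.999), 3L)
    # doubling individuals adds ln2/|ln(1-het)| before the ceiling
    het <- 0.3
    raw <- function(ni) log(0.05 / (20000 * ni)) / log(1 - het)
    expect_equal(raw(800) - raw(400), log(2) / abs(log(1 - het)))
    expect_error(lParam(1000, 10, 0), "meanHet")
})

test_that("a clean homozygous run is reported once with exact bounds", {
    # 60 homozygous SNPs spanning ~2.36 Mb at 40 kb spacing
    g <- rep(0L, 60)
    ds <- singleSampleDataset(g)
    p <- rohParams(windowSnp = 50L, minSnp = 50L)
    seg <- detectRoh(ds, p)
    expect_equal(nrow(seg), 1L)
    expect_equal(seg$n_snp, 60L)
    expect_equal(seg$start_bp, 40000L)
    expect_equal(seg$end_bp, 60L * 40000L)
})

test_that("one heterozygous call or one long gap breaks the run", {
    p <- rohParams(windowSnp = 50L, minSnp = 50L)
    g <- rep(0L, 60); g[30] <- 1L
    expect_equal(nrow(detectRoh(singleSampleDataset(g), p)), 0L)
    # 1.2 Mb internal gap: both halves < 50 SNPs
    pos <- c(seq_len(30) * 40000L, 1200000L + 30L * 40000L +
             seq_len(30) * 40000L)
    expect_equal(nrow(detectRoh(singleSampleDataset(rep(0L, 60), pos), p)), 0L)
})

test_that("chromosomes with fewer SNPs than one window are skipped with a warning", {
    ds <- singleSampleDataset(rep(0L, 10))
    expect_warning(seg <- detectRoh(ds, rohParams(windowSnp = 50L)),
                   "skipped")
    expect_equal(nrow(seg), 0L)
})

test_that("detector equals the brute-force oracle on random small instances", {
    set.seed(1234)
    nAgree <- 0L
    for (rep in 1:100) {
        n <- sample(60:300, 1)
        nSam <- sample(1:25, 1)
        spacing <- sample(c(20000L, 40000L, 60000L), 1)
        pos <- cumsum(sample.int(spacing, n, replace = TRUE) +
                      c(0L, rep(1000L, n - 1L)))
        # genotype mixture heavy on homozygotes so runs actually occur
        d <- matrix(sample(c(0L, 0L, 2L, 2L, 1L, NA), n * nSam,
                           replace = TRUE,
                           prob = c(.4, .2, .2, .1, .05, .05)), n, nSam)
        w <- sample(5:20, 1)
        params <- rohParams(windowSnp = w,
                            minSnp = w + sample(0:10, 1),
                            minLengthKb = sample(c(100, 300, 500), 1),
                            densityKbPerSnp = sample(c(50, 80), 1),
                            maxGapKb = sample(c(200, 500, 1000), 1))
        ds <- toyDataset(d, pos = pos)
        got <- detectRoh(ds, params)
        for (i in seq_len(nSam)) {
            want <- rohOracle(d[, i], pos, params)
            gi <- got[got$sample_id == paste0("s", i), , drop = FALSE]
            if (is.null(want)) {
                expect_equal(nrow(gi), 0L)
            } else {
                expect_equal(nrow(gi), nrow(want))
                expect_equal(gi$start_bp, unname(want[, "start"]))
                expect_equal(gi$end_bp, unname(want[, "end"]))
                expect_equal(gi$n_snp, unname(want[, "n"]))
            }
            nAgree <- nAgree + 1L
        }
    }
    expect_gte(nAgree, 100L)
})

test_that("size classes split at 3 and 10 Mb as in the results scheme", {
    expect_equal(rohscan:::.sizeClass(c(2999, 3000, 10000, 10001)),
                 c("short", "medium", "medium", "long"))
    seg <- data.frame(population = "P",
                      length_kb = c(1500, 2999, 3000, 9000, 10000, 10001))
    cls <- classifyRoh(seg)
    pr <- cls$proportions
    expect_equal(pr$n_short, 2L)
    expect_equal(pr$n_medium, 3L)
    expect_equal(pr$n_long, 1L)
    expect_equal(pr$short + pr$medium + pr$long, 1)
})

test_that("F_ROH arithmetic and bounds", {
    g <- genomeInfo(c(`1` = 2262.6e6))
    seg <- data.frame(sample_id = "s1", population = "P", chrom = "1",
                      start_bp = 1, end_bp = 226.26e6)
    expect_equal(froh(seg, g)$f_roh, 0.100)
    # zero segments -> 0
    none <- froh(seg[0, ], g, sampleId = "s1")
    expect_equal(none$f_roh, 0)
    expect_equal(none$n_segments, 0L)
    # one ROH covering each whole chromosome -> exactly 1
    g2 <- genomeInfo(c(`1` = 5e6, `2` = 3e6))
    seg2 <- data.frame(sample_id = "s1", population = "P",
                       chrom = c("1", "2"), start_bp = 1,
                       end_bp = c(5e6, 3e6))
    expect_equal(froh(seg2, g2)$f_roh, 1)
    # segment outside the genome is an error
    seg3 <- seg2; seg3$end_bp[1] <- 6e6
    expect_error(froh(seg3, g2), "outside")
})

test_that("per-individual segments are disjoint; merge-then-measure equals the sum", {
    scan <- smallScanFixture()
    seg <- scan$segments
    skip_if(nrow(seg) == 0, "no segments in the small simulation")
    for (sid in unique(seg$sample_id)) {
        s <- seg[seg$sample_id == sid, , drop = FALSE]
        gr <- GenomicRanges::GRanges(s$chrom,
                                     IRanges::IRanges(s$start_bp, s$end_bp))
        expect_equal(intervalLength(gr),
                     sum(s$end_bp - s$start_bp + 1))
    }
    fr <- froh(seg, smallGenome())
    expect_true(all(fr$f_roh >= 0 & fr$f_roh <= 1))
})

test_that("simulated cohorts reproduce the qualitative ROH structure", {
    scan <- smallScanFixture()
    seg <- scan$segments
    fr <- froh(seg, smallGenome(), sampleId = sampleIds(scan$rohSub),
               population = populations(scan$rohSub))
    m <- sapply(split(fr$f_roh, fr$population), mean)
    expect_gt(m["KNP"], m["DUC"])
    expect_gt(m["DUC"], m["F1"])
    # F1 has no long ROH and the fewest segments
    segF1 <- seg[seg$population == "F1", ]
    expect_equal(sum(segF1$size_class == "long"), 0L)
    counts <- table(factor(seg$population,
                           levels = c("DUC", "KNP", "F1", "F2", "WRH")))
    expect_equal(names(which.min(counts / c(30, 30, 15, 30, 60))), "F1")
})
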