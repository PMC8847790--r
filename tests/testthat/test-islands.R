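# Incidence tracks, island calling rules, concatenated regions and
# parental overlap against per-bp bitmap oracles.

# an incidence track for island tests: mostly low incidence with one
# high-incidence cluster, built from synthetic segments
.clusterTrack <- function(nInd = 10, nSnp = 400, hot = 180:200,
                          hotCount = 9, baseCount = 0) {
    pos <- seq_len(nSnp) * 40000L
    segs <- NULL
    for (i in seq_len(hotCount))
        segs <- rbind(segs, data.frame(
            sample_id = paste0("s", i), population = "P", chrom = "1",
            start_bp = pos[min(hot)], end_bp = pos[max(hot)],
            stringsAsFactors = FALSE))
    if (baseCount > 0)
        for (i in seq_len(baseCount))
            segs <- rbind(segs, data.frame(
                sample_id = paste0("s", i), population = "P", chrom = "1",
                start_bp = pos[1], end_bp = pos[nSnp],
                stringsAsFactors = FALSE))
    ds <- toyDataset(matrix(0L, nSnp, nInd), pos = pos,
                     pops = rep("P", nInd))
    snpIncidence(segs, ds, "P")
}

test_that("incidence is covered individuals over population size", {
    pos <- seq_len(10) * 40000L
    segs <- data.frame(sample_id = paste0("s", 1:3), population = "P",
                       chrom = "1", start_bp = pos[2], end_bp = pos[5],
                       stringsAsFactors = FALSE)
    ds <- toyDataset(matrix(0L, 10, 10), pos = pos, pops = rep("P", 10))
    trk <- snpIncidence(segs, ds, "P")
    expect_equal(trk$incidence[3], 0.3)
    expect_equal(trk$incidence[1], 0)
    expect_equal(attr(trk, "nIndividuals"), 10L)
    # full coverage gives incidence 1 and the maximal z of the track
    segAll <- data.frame(sample_id = paste0("s", 1:10), population = "P",
                         chrom = "1", start_bp = pos[2], end_bp = pos[5],
                         stringsAsFactors = FALSE)
    trk2 <- snpIncidence(segAll, ds, "P")
    expect_equal(max(trk2$incidence), 1)
    expect_equal(which.max(trk2$z), which.max(trk2$incidence))
})

test_that("overlapping segments within one individual are rejected", {
    pos <- seq_len(10) * 40000L
    segs <- data.frame(sample_id = "s1", population = "P", chrom = "1",
                       start_bp = c(pos[1], pos[3]),
                       end_bp = c(pos[5], pos[7]), stringsAsFactors = FALSE)
    ds <- toyDataset(matrix(0L, 10, 2), pos = pos, pops = rep("P", 2))
    expect_error(snpIncidence(segs, ds, "P"), "overlap")
})

test_that("a constructed high-incidence cluster yields its island bins", {
    trk <- .clusterTrack()
    isl <- rohIslands(trk)
    expect_equal(attr(isl, "rule"), "percentile30")
    # qualifying SNPs live at positions 180..200 * 40 kb = 7.2..8.0 Mb,
    # all inside the single 1-Mb bin [7,000,001, 8,000,000]
    expect_equal(nrow(isl), 1L)
    expect_equal(isl$bin_start, 7000001)
    expect_equal(isl$bin_end, 8000000)
    expect_equal(isl$n_snps, 21L)
    expect_equal(isl$peak_incidence, 0.9)
})

test_that("the 30% incidence floor suppresses low-incidence peaks", {
    trk <- .clusterTrack(nInd = 40, hotCount = 10)  # peak incidence 0.25
    expect_gt(max(trk$prob, na.rm = TRUE), 0.999)   # z-rule fires
    isl <- rohIslands(trk)
    expect_equal(nrow(isl), 0L)
    expect_equal(attr(isl, "rule"), "percentile30")
})

test_that("a near-fixated population routes to the fallback-80 rule", {
    # all SNPs covered in 9/10 individuals: sd = 0, z undefined
    trk <- .clusterTrack(hotCount = 0, baseCount = 9, hot = 1:400)
    expect_true(all(is.na(trk$z)))
    isl <- rohIslands(trk)
    expect_equal(attr(isl, "rule"), "fallback80")
    expect_gt(nrow(isl), 0)
    expect_true(all(isl$peak_incidence >= 0.8))
    # every 1-Mb bin over the covered 16 Mb appears exactly once
    expect_equal(nrow(isl), 16L)
})

test_that("concatenated regions merge >=1 bp overlaps but not bookends", {
    seg <- data.frame(sample_id = c("a", "b", "a", "b"), population = "P",
                      chrom = "1",
                      start_bp = c(1, 50, 201, 500),
                      end_bp = c(100, 200, 300, 600),
                      stringsAsFactors = FALSE)
    gr <- concatRegions(seg)
    expect_equal(GenomicRanges::start(gr), c(1, 201, 500))
    expect_equal(GenomicRanges::end(gr), c(200, 300, 600))
    expect_equal(intervalLength(gr), 200 + 100 + 101)
})

test_that("concatenated-region length equals the bitmap oracle on random fixtures", {
    set.seed(77)
    for (rep in 1:5) {
        segs <- randomSegments(1000, 1e7)
        gr <- concatRegions(segs)
        expect_equal(intervalLength(gr),
                     bitmapUnionLength(segs$start_bp, segs$end_bp, 1e7))
    }
})

test_that("parental overlap matches the bitmap oracle on a 10-Mb toy genome", {
    set.seed(99)
    for (rep in 1:5) {
        cross <- randomSegments(40, 1e7)
        pa <- randomSegments(40, 1e7)
        pb <- randomSegments(40, 1e7)
        got <- parentalOverlap(concatRegions(cross), concatRegions(pa),
                               concatRegions(pb))
        cv <- bitmapCoverage(cross$start_bp, cross$end_bp, 1e7)
        shared <- bitmapCoverage(pa$start_bp, pa$end_bp, 1e7) &
                  bitmapCoverage(pb$start_bp, pb$end_bp, 1e7)
        expect_equal(got$overlap_bp, sum(cv & shared))
        expect_equal(got$proportion, sum(cv & shared) / sum(cv))
        expect_equal(got$shared_bp, sum(shared))
    }
})

test_that("parental overlap handles containment, disjointness and emptiness", {
    mk <- function(s, e) GenomicRanges::GRanges("1", IRanges::IRanges(s, e))
    # crossbred inside the shared region -> 1
    expect_equal(parentalOverlap(mk(100, 200), mk(1, 1000),
                                 mk(50, 500))$proportion, 1)
    # crossbred disjoint from both parents -> 0
    expect_equal(parentalOverlap(mk(5000, 6000), mk(1, 100),
                                 mk(50, 150))$proportion, 0)
    # empty crossbred -> NA
    expect_true(is.na(parentalOverlap(GenomicRanges::GRanges(),
                                      mk(1, 100), mk(1, 100))$proportion))
})
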