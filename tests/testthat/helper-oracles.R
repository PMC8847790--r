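# Independent oracles: deliberately naive implementations written as plain
# loops, kept free of the vectorised code paths they check.

# brute-force ROH scan of one genotype vector: enumerates every window and
# every candidate stretch directly against the rules
rohOracle <- function(g, pos, params) {
    n <- length(g)
    w <- params@windowSnp
    if (n < w) return(NULL)
    isHet <- function(i) !is.na(g[i]) && g[i] == 1L
    # window homozygosity by direct counting
    nw <- n - w + 1
    homWin <- logical(nw)
    for (s in seq_len(nw)) {
        het <- 0; mis <- 0
        for (i in s:(s + w - 1)) {
            if (is.na(g[i])) mis <- mis + 1
            else if (g[i] == 1L) het <- het + 1
        }
        homWin[s] <- het <= params@windowHetMax && mis <= params@windowMissingMax
    }
    inrun <- logical(n)
    for (i in seq_len(n)) {
        lo <- max(1, i - w + 1); hi <- min(i, nw)
        hits <- 0; tot <- 0
        for (s in lo:hi) { tot <- tot + 1; if (homWin[s]) hits <- hits + 1 }
        inrun[i] <- tot > 0 && hits / tot >= params@windowHitThreshold
        if (isHet(i)) inrun[i] <- FALSE
    }
    # maximal stretches, split at gaps, trimmed to genotyped endpoints
    segs <- NULL
    i <- 1
    while (i <= n) {
        if (!inrun[i]) { i <- i + 1; next }
        j <- i
        while (j < n && inrun[j + 1] &&
               pos[j + 1] - pos[j] <= params@maxGapKb * 1000) j <- j + 1
        s0 <- i; e0 <- j
        while (s0 <= e0 && is.na(g[s0])) s0 <- s0 + 1
        while (e0 >= s0 && is.na(g[e0])) e0 <- e0 - 1
        if (s0 <= e0) {
            ns <- e0 - s0 + 1
            lenKb <- (pos[e0] - pos[s0] + 1) / 1000
            if (ns >= params@minSnp && lenKb >= params@minLengthKb &&
                lenKb / ns <= params@densityKbPerSnp)
                segs <- rbind(segs, c(start = pos[s0], end = pos[e0], n = ns))
        }
        i <- j + 1
    }
    segs
}

# per-bp bitmap union length of 1-based closed intervals on a toy genome
bitmapUnionLength <- function(starts, ends, genomeLen) {
    covered <- logical(genomeLen)
    for (k in seq_along(starts)) covered[starts[k]:ends[k]] <- TRUE
    sum(covered)
}

bitmapCoverage <- function(starts, ends, genomeLen) {
    covered <- logical(genomeLen)
    for (k in seq_along(starts)) covered[starts[k]:ends[k]] <- TRUE
    covered
}

# quadratic all-pairs interval overlap join
allPairsOverlap <- function(binsDf, featsDf) {
    out <- NULL
    for (i in seq_len(nrow(binsDf))) for (j in seq_len(nrow(featsDf))) {
        if (binsDf$chrom[i] != featsDf$chrom[j]) next
        lo <- max(binsDf$bin_start[i], featsDf$start_bp[j])
        hi <- min(binsDf$bin_end[i], featsDf$end_bp[j])
        if (lo <= hi)
            out <- rbind(out, data.frame(bin = i, feat = j,
                                         overlap = hi - lo + 1))
    }
    out
}

randomSegments <- function(nSeg, genomeLen, maxLen = 2e5,
                           samples = "s1", pop = "P") {
    start <- sample.int(genomeLen - maxLen, nSeg, replace = TRUE)
    len <- sample.int(maxLen, nSeg, replace = TRUE)
    data.frame(sample_id = sample(samples, nSeg, replace = TRUE),
               population = pop, chrom = "1",
               start_bp = start, end_bp = pmin(start + len, genomeLen),
               stringsAsFactors = FALSE)
}
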