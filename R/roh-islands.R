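# ROH incidence tracks, island bins, concatenated regions and parental
# overlap.  Interval algebra is delegated to GenomicRanges; intervals are
# 1-based closed throughout, and "overlap" always means >= 1 bp shared.

.segmentsGRanges <- function(segments) {
    GRanges(as.character(segments$chrom),
            IRanges(segments$start_bp, segments$end_bp))
}

#' Per-SNP ROH incidence within a population
#'
#' For each SNP, the incidence is the fraction of the population's
#' individuals whose ROH cover its position.  A z-score is computed from the
#' population's own incidence distribution across SNPs, and the standard
#' normal CDF of that z-score (\code{prob}, the percentile of the SNP's
#' incidence) is attached: SNPs in the extreme high-incidence tail have
#' \code{prob} near 1.  If the incidence distribution is constant (sd = 0),
#' z and prob are NA, which routes island calling to the fallback rule.
#'
#' Requires each individual's segments to be disjoint (asserted), so that
#' counting covering segments equals counting covered individuals.
#'
#' @param segments data.frame from [detectRoh()].
#' @param ds the [GenotypeData-class] the scan was run on (supplies SNP
#'   positions and the population size).
#' @param population population label (its size is the denominator).
#' @return data.frame (chrom, pos, snp_id, incidence, z, prob) with
#'   attributes \code{population} and \code{nIndividuals}.
#' @export
snpIncidence <- function(segments, ds, population) {
    sel <- populations(ds) == population
    nPop <- sum(sel)
    if (nPop == 0L) stop("population ", population, " has no samples")
    segp <- segments[segments$population == population, , drop = FALSE]
    if (nrow(segp)) {
        bySample <- split(segp, segp$sample_id)
        disjoint <- vapply(bySample, function(s) {
            s <- s[order(s$chrom, s$start_bp), ]
            !any(s$start_bp[-1] <= s$end_bp[-nrow(s)] &
                 s$chrom[-1] == s$chrom[-nrow(s)])
        }, logical(1))
        if (!all(disjoint))
            stop("segments of one individual overlap; incidence undefined")
    }
    info <- snpInfo(ds)
    snps <- GRanges(info$chrom, IRanges(info$pos, width = 1L))
    counts <- if (nrow(segp)) countOverlaps(snps, .segmentsGRanges(segp))
              else integer(nrow(info))
    inc <- counts / nPop
    s <- sd(inc)
    z <- if (is.na(s) || s == 0) rep(NA_real_, length(inc)) else
        (inc - mean(inc)) / s
    out <- data.frame(chrom = info$chrom, pos = info$pos,
                      snp_id = info$snp_id, incidence = inc, z = z,
                      prob = pnorm(z), stringsAsFactors = FALSE)
    attr(out, "population") <- population
    attr(out, "nIndividuals") <- nPop
    out
}

#' Call ROH islands from an incidence track
#'
#' Qualifying SNPs are those in the top 0.1\% of the population's incidence
#' distribution (\code{prob > 0.999}) that are also covered in at least
#' \code{minIncidence} (default 30\%) of individuals.  When the probability
#' rule selects no SNPs -- e.g. in a highly inbred population whose
#' incidence distribution is so uniform that no SNP reaches the 0.999
#' percentile -- the fallback rule qualifies SNPs covered in at least
#' \code{fallbackIncidence} (default 80\%) of individuals.  Qualifying SNPs
#' are grouped into 1-Mb bins ([k*1e6 + 1, (k+1)*1e6]); each non-empty bin
#' is one island.  Adjacent bins are deliberately not merged (islands are
#' counted as 1-Mb bins).
#'
#' @param track data.frame from [snpIncidence()].
#' @param minIncidence joint incidence floor for the percentile rule
#'   (default 0.30).
#' @param fallbackIncidence incidence threshold of the fallback rule
#'   (default 0.80).
#' @param binBp island bin width (default 1e6).
#' @return data.frame (population, chrom, bin_start, bin_end, n_snps,
#'   peak_incidence, rule) with attribute \code{rule}; zero rows when no SNP
#'   qualifies.
#' @export
rohIslands <- function(track, minIncidence = 0.30, fallbackIncidence = 0.80,
                       binBp = 1e6) {
    probHit <- !is.na(track$prob) & track$prob > 0.999
    if (any(probHit)) {
        qual <- probHit & track$incidence >= minIncidence
        rule <- "percentile30"
    } else {
        qual <- track$incidence >= fallbackIncidence
        rule <- "fallback80"
    }
    pop <- attr(track, "population")
    if (!any(qual)) {
        out <- data.frame(population = character(0), chrom = character(0),
                          bin_start = numeric(0), bin_end = numeric(0),
                          n_snps = integer(0), peak_incidence = numeric(0),
                          rule = character(0), stringsAsFactors = FALSE)
        attr(out, "rule") <- rule
        return(out)
    }
    q <- track[qual, , drop = FALSE]
    binStart <- floor((q$pos - 1) / binBp) * binBp + 1
    key <- paste(q$chrom, binStart)
    agg <- split(seq_len(nrow(q)), key)
    out <- do.call(rbind, lapply(agg, function(ii) {
        data.frame(population = if (is.null(pop)) NA_character_ else pop,
                   chrom = q$chrom[ii[1]],
                   bin_start = binStart[ii[1]],
                   bin_end = binStart[ii[1]] + binBp - 1,
                   n_snps = length(ii),
                   peak_incidence = max(q$incidence[ii]),
                   rule = rule, stringsAsFactors = FALSE)
    }))
    out <- out[.orderVariants(out$chrom, out$bin_start), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "rule") <- rule
    out
}

#' Concatenated ROH regions of a population
#'
#' Unions all ROH segments of a population's individuals, merging segments
#' that overlap by at least 1 bp.  Segments that are merely adjacent
#' (bookended, 0 bp overlap) are kept separate.
#'
#' @param segments data.frame from [detectRoh()].
#' @param population optional label to subset on.
#' @return a sorted, pairwise-disjoint \code{GRanges}.
#' @export
concatRegions <- function(segments, population = NULL) {
    if (!is.null(population))
        segments <- segments[segments$population == population, , drop = FALSE]
    if (!nrow(segments)) return(GRanges())
    gr <- .segmentsGRanges(segments)
    sort(reduce(gr, min.gapwidth = 0L))
}

#' Total length of an interval set
#'
#' @param gr a \code{GRanges} (1-based closed intervals).
#' @return total covered bp, counting overlaps once.
#' @export
intervalLength <- function(gr) {
    sum(as.numeric(width(reduce(gr, min.gapwidth = 0L))))
}

.sharedSeqinfo <- function(...) {
    grl <- list(...)
    lev <- unique(unlist(lapply(grl, function(g) unique(as.character(seqnames(g))))))
    lapply(grl, function(g) {
        GenomeInfoDb::seqlevels(g) <- union(GenomeInfoDb::seqlevels(g), lev)
        g
    })
}

#' Parental origin of crossbred ROH regions
#'
#' Computes the fraction of a crossbred population's concatenated ROH
#' regions that falls inside the ROH region shared by the two parental
#' populations (the intersection of their concatenated regions).
#'
#' @param crossbred,parentA,parentB \code{GRanges} interval sets from
#'   [concatRegions()].
#' @return list with \code{proportion} (NA when the crossbred set is empty),
#'   \code{crossbred_bp}, \code{shared_bp}, \code{overlap_bp}.
#' @export
parentalOverlap <- function(crossbred, parentA, parentB) {
    gl <- .sharedSeqinfo(crossbred, parentA, parentB)
    crossbred <- gl[[1]]; parentA <- gl[[2]]; parentB <- gl[[3]]
    shared <- intersect(parentA, parentB, ignore.strand = TRUE)
    crossBp <- intervalLength(crossbred)
    ovl <- intersect(crossbred, shared, ignore.strand = TRUE)
    ovlBp <- intervalLength(ovl)
    list(proportion = if (crossBp == 0) NA_real_ else ovlBp / crossBp,
         crossbred_bp = crossBp,
         shared_bp = intervalLength(shared),
         overlap_bp = ovlBp)
}
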