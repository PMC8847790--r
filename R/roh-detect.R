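# Sliding-window ROH detection (PLINK --homozyg semantics), the L-parameter
# window/segment SNP threshold, size classes, and F_ROH.

#' L-parameter: minimum SNP count for a homozygous run
#'
#' Multiple-testing bound on the number of consecutive homozygous SNPs
#' expected by chance across all SNPs and individuals at false-positive rate
#' \code{alpha}:
#' \deqn{L = \lceil \ln(\alpha / (n_{snps} \cdot n_{ind})) / \ln(1 - het) \rceil}
#' where \code{het} is the mean heterozygosity of the population.  The
#' result is used for both the window size and the minimum SNPs per run.
#'
#' @param nSnps number of SNPs genotyped.
#' @param nIndividuals number of individuals scanned.
#' @param meanHet mean heterozygosity (fraction in (0,1)).
#' @param alpha false-positive rate (default 0.05).
#' @return integer SNP count (>= 1).
#' @examples
#' lParam(50000, 500, 0.35)  # 47
#' @export
lParam <- function(nSnps, nIndividuals, meanHet, alpha = 0.05) {
    if (nSnps < 1 || nIndividuals < 1) stop("nSnps and nIndividuals must be >= 1")
    if (meanHet <= 0) stop("meanHet must be > 0 (threshold undefined at 0)")
    if (meanHet >= 1) stop("meanHet must be < 1")
    max(1L, as.integer(ceiling(log(alpha / (nSnps * nIndividuals)) /
                               log(1 - meanHet))))
}

#' Mean heterozygosity of a dataset
#'
#' Fraction of heterozygous calls among all non-missing genotypes, pooled
#' over SNPs and individuals; the \code{meanHet} input of [lParam()].
#'
#' @param ds a [GenotypeData-class] object.
#' @return fraction in [0,1].
#' @export
meanHeterozygosity <- function(ds) {
    d <- dosages(ds)
    sum(d == 1L, na.rm = TRUE) / sum(!is.na(d))
}

#' Construct ROH detection parameters
#'
#' @param windowSnp SNPs per sliding window (e.g. from [lParam()]).
#' @param minSnp minimum SNPs per segment (defaults to \code{windowSnp}).
#' @param minLengthKb,densityKbPerSnp,maxGapKb,windowHetMax,windowMissingMax,segmentHetMax,windowHitThreshold,lAlpha
#'   see [ROHParams-class].
#' @return A [ROHParams-class] object.  Warns when \code{minSnp <
#'   windowSnp} (legal but unusual).
#' @export
rohParams <- function(windowSnp = 50L, minSnp = windowSnp,
                      minLengthKb = 1000, densityKbPerSnp = 50,
                      maxGapKb = 1000, windowHetMax = 0L,
                      windowMissingMax = 1L, segmentHetMax = 0L,
                      windowHitThreshold = 0.05, lAlpha = 0.05) {
    if (minSnp < windowSnp)
        warning("minSnp < windowSnp: segments may be shorter than one window")
    new("ROHParams", minLengthKb = minLengthKb,
        densityKbPerSnp = densityKbPerSnp, maxGapKb = maxGapKb,
        windowHetMax = as.integer(windowHetMax),
        windowMissingMax = as.integer(windowMissingMax),
        segmentHetMax = as.integer(segmentHetMax),
        windowSnp = as.integer(windowSnp), minSnp = as.integer(minSnp),
        windowHitThreshold = windowHitThreshold, lAlpha = lAlpha)
}

setMethod("show", "ROHParams", function(object) {
    cat("ROHParams: window", object@windowSnp, "SNPs, min", object@minSnp,
        "SNPs,", object@minLengthKb, "kb min length,",
        object@densityKbPerSnp, "kb/SNP max density,",
        object@maxGapKb, "kb max gap\n")
    cat("  window: <=", object@windowHetMax, "het, <=",
        object@windowMissingMax, "missing; hit threshold",
        object@windowHitThreshold, "\n")
})

#' Population-specific ROH parameters via the L-parameter
#'
#' Computes the L-parameter from a population's own SNP count, cohort size
#' and mean heterozygosity, and assigns it to both \code{windowSnp} and
#' \code{minSnp}.
#'
#' @param ds a [GenotypeData-class] object restricted or restrictable to one
#'   population.
#' @param population population label, or NULL for the whole dataset.
#' @param alpha false-positive rate (default 0.05).
#' @param ... passed to [rohParams()].
#' @return A [ROHParams-class] object.
#' @export
rohParamsFor <- function(ds, population = NULL, alpha = 0.05, ...) {
    if (!is.null(population)) ds <- ds[, populations(ds) == population]
    l <- lParam(nVariants(ds), nSamples(ds), meanHeterozygosity(ds), alpha)
    rohParams(windowSnp = l, minSnp = l, lAlpha = alpha, ...)
}

# core scan of one individual x chromosome; returns matrix of
# (startIdx, endIdx) SNP index pairs of accepted segments
.scanChromosome <- function(g, pos, params) {
    n <- length(g)
    w <- params@windowSnp
    if (n < w) return(NULL)
    het <- !is.na(g) & g == 1L
    miss <- is.na(g)
    cumHet <- c(0L, cumsum(het)); cumMiss <- c(0L, cumsum(miss))
    nw <- n - w + 1L
    i <- seq_len(nw)
    homWin <- (cumHet[i + w] - cumHet[i]) <= params@windowHetMax &
              (cumMiss[i + w] - cumMiss[i]) <= params@windowMissingMax
    H <- c(0L, cumsum(homWin))
    s <- seq_len(n)
    hi <- pmin(s, nw); lo <- pmax(s - w + 1L, 1L)
    hits <- H[hi + 1L] - H[lo]
    inrun <- hits / (hi - lo + 1L) >= params@windowHitThreshold
    inrun[het] <- FALSE                       # split at heterozygous calls
    if (!any(inrun)) return(NULL)

    r <- rle(inrun)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keepRun <- r$values
    segs <- NULL
    maxGapBp <- params@maxGapKb * 1000
    for (k in which(keepRun)) {
        a <- starts[k]; b <- ends[k]
        if (b > a) {
            gaps <- which(diff(pos[a:b]) > maxGapBp)
            cut <- c(a - 1L, a - 1L + gaps, b)
        } else cut <- c(a - 1L, b)
        for (t in seq_len(length(cut) - 1L)) {
            s0 <- cut[t] + 1L; e0 <- cut[t + 1L]
            # trim leading/trailing missing so endpoints are genotyped SNPs
            while (s0 <= e0 && miss[s0]) s0 <- s0 + 1L
            while (e0 >= s0 && miss[e0]) e0 <- e0 - 1L
            if (s0 > e0) next
            ns <- e0 - s0 + 1L
            lenKb <- (pos[e0] - pos[s0] + 1) / 1000
            if (ns >= params@minSnp && lenKb >= params@minLengthKb &&
                lenKb / ns <= params@densityKbPerSnp)
                segs <- rbind(segs, c(s0, e0))
        }
    }
    segs
}

#' Detect runs of homozygosity
#'
#' Sliding-window ROH scan of every individual and autosome, following the
#' PLINK \code{--homozyg} semantics described in [ROHParams-class]: windows
#' of \code{windowSnp} consecutive SNPs are scored homozygous, each SNP's
#' hit rate is the fraction of windows covering it that are homozygous
#' (edge SNPs are covered by fewer windows), in-run SNPs are grouped into
#' maximal stretches split at heterozygous calls and at gaps larger than
#' \code{maxGapKb}, and stretches are kept when they satisfy the SNP-count,
#' length and density rules.  Segment coordinates are 1-based and bounded by
#' genotyped SNPs.
#'
#' @param ds a [GenotypeData-class] object (the call-rate-only ROH subset;
#'   MAF/LD filtering biases ROH discovery and should not be applied).
#' @param params a [ROHParams-class] object, e.g. from [rohParamsFor()].
#' @param population restrict the scan to one population (default: all
#'   samples).
#' @return data.frame (sample_id, population, chrom, start_bp, end_bp,
#'   n_snp, length_kb, size_class).  Chromosomes with fewer SNPs than one
#'   window are skipped with a warning.
#' @export
detectRoh <- function(ds, params, population = NULL) {
    if (!is.null(population)) ds <- ds[, populations(ds) == population]
    info <- snpInfo(ds)
    d <- dosages(ds)
    pops <- populations(ds); ids <- sampleIds(ds)
    chroms <- unique(info$chrom)
    rows <- list(); nr <- 0L
    skipped <- character(0)
    for (chr in chroms) {
        cidx <- which(info$chrom == chr)
        if (length(cidx) < params@windowSnp) {
            skipped <- c(skipped, chr)
            next
        }
        pos <- info$pos[cidx]
        dc <- d[cidx, , drop = FALSE]
        for (i in seq_len(ncol(dc))) {
            segs <- .scanChromosome(dc[, i], pos, params)
            if (is.null(segs)) next
            nr <- nr + 1L
            rows[[nr]] <- data.frame(
                sample_id = ids[i], population = pops[i], chrom = chr,
                start_bp = pos[segs[, 1L]], end_bp = pos[segs[, 2L]],
                n_snp = segs[, 2L] - segs[, 1L] + 1L,
                stringsAsFactors = FALSE)
        }
    }
    if (length(skipped))
        warning("chromosomes with fewer SNPs than one window skipped: ",
                paste(skipped, collapse = ", "))
    out <- if (nr) do.call(rbind, c(rows, make.row.names = FALSE)) else
        data.frame(sample_id = character(0), population = character(0),
                   chrom = character(0), start_bp = integer(0),
                   end_bp = integer(0), n_snp = integer(0),
                   stringsAsFactors = FALSE)
    out$length_kb <- (out$end_bp - out$start_bp + 1) / 1000
    out$size_class <- .sizeClass(out$length_kb)
    out
}

.sizeClass <- function(lengthKb) {
    cls <- rep(NA_character_, length(lengthKb))
    cls[lengthKb < 3000] <- "short"
    cls[lengthKb >= 3000 & lengthKb <= 10000] <- "medium"
    cls[lengthKb > 10000] <- "long"
    cls
}

#' Classify ROH segments by physical length
#'
#' Size classes follow the usual scheme: short = [1, 3) Mb, medium =
#' [3, 10] Mb, long = (10, Inf) Mb.
#'
#' @param segments data.frame from [detectRoh()].
#' @return list with \code{segments} (input plus/with \code{size_class})
#'   and \code{proportions}: per-population class counts and proportions
#'   (proportions sum to 1 where segments exist).
#' @export
classifyRoh <- function(segments) {
    segments$size_class <- .sizeClass(segments$length_kb)
    lv <- c("short", "medium", "long")
    tab <- table(factor(segments$population),
                 factor(segments$size_class, levels = lv))
    props <- as.data.frame.matrix(tab / pmax(rowSums(tab), 1L))
    counts <- as.data.frame.matrix(tab)
    names(counts) <- paste0("n_", lv)
    props <- cbind(population = rownames(props), counts, props,
                   row.names = NULL)
    list(segments = segments, proportions = props)
}

#' ROH-based inbreeding coefficient F_ROH
#'
#' \deqn{F_{ROH} = L_{ROH} / L_{autosomes}} where \eqn{L_{ROH}} is the summed
#' length of an individual's ROH segments and \eqn{L_{autosomes}} the total
#' SNP-covered autosomal genome length.  Individuals without segments get 0.
#'
#' @param segments data.frame from [detectRoh()].
#' @param genome a [GenomeInfo-class] object.
#' @param sampleId optional character vector of individuals to report
#'   (e.g. all samples of a dataset so ROH-free individuals appear);
#'   defaults to the individuals present in \code{segments}.
#' @param population optional labels aligned with \code{sampleId}.
#' @return data.frame (sample_id, population, n_segments, sum_length_kb,
#'   f_roh).
#' @export
froh <- function(segments, genome, sampleId = NULL, population = NULL) {
    stopifnot(is(genome, "GenomeInfo"))
    len <- chromLengths(genome)
    if (nrow(segments)) {
        bad <- !(as.character(segments$chrom) %in% names(len)) |
            segments$end_bp > len[as.character(segments$chrom)] |
            segments$start_bp < 1
        if (any(bad))
            stop(sum(bad), " segment(s) fall outside the genome chromosomes")
    }
    if (is.null(sampleId)) {
        sampleId <- unique(segments$sample_id)
        population <- segments$population[match(sampleId, segments$sample_id)]
    }
    if (is.null(population)) population <- rep(NA_character_, length(sampleId))
    total <- totalAutosomeLength(genome)
    bp <- setNames(numeric(length(sampleId)), sampleId)
    nseg <- setNames(integer(length(sampleId)), sampleId)
    if (nrow(segments)) {
        agg <- tapply(segments$end_bp - segments$start_bp + 1,
                      segments$sample_id, sum)
        cnt <- tapply(segments$sample_id, segments$sample_id, length)
        bp[names(agg)] <- agg
        nseg[names(cnt)] <- as.integer(cnt)
    }
    data.frame(sample_id = sampleId, population = population,
               n_segments = as.integer(nseg), sum_length_kb = bp / 1000,
               f_roh = bp / total, row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-population summary of ROH burden
#'
#' @param segments data.frame from [detectRoh()].
#' @param frohTable data.frame from [froh()].
#' @return data.frame with mean/sd segment length, mean/sd per-individual
#'   segment count, and mean/sd F_ROH per population.
#' @export
rohSummary <- function(segments, frohTable) {
    pops <- sort(unique(c(segments$population, frohTable$population)))
    do.call(rbind, lapply(pops, function(pp) {
        segp <- segments[segments$population == pp, , drop = FALSE]
        fp <- frohTable[frohTable$population == pp, , drop = FALSE]
        data.frame(population = pp,
                   n_segments = nrow(segp),
                   length_kb_mean = if (nrow(segp)) mean(segp$length_kb) else NA_real_,
                   length_kb_sd = if (nrow(segp) > 1) sd(segp$length_kb) else NA_real_,
                   n_per_ind_mean = mean(fp$n_segments),
                   n_per_ind_sd = sd(fp$n_segments),
                   froh_mean = mean(fp$f_roh), froh_sd = sd(fp$f_roh),
                   stringsAsFactors = FALSE)
    }))
}
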