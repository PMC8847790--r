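# Staged quality control: call rate -> MAF -> LD pruning.
# The three stages produce the three analysis subsets used downstream:
# ROH (call rate only), diversity (+ MAF), structure (+ LD pruning).

#' Construct QC thresholds
#'
#' @param snpCallRateMin,sampleCallRateMin,mafMin,ldWindowSnps,ldStepSnps,ldR2Max,dropNonautosomal
#'   see [QCParams-class] for meanings and defaults.
#' @return A [QCParams-class] object.
#' @export
qcParams <- function(snpCallRateMin = 0.90, sampleCallRateMin = 0.90,
                     mafMin = 0.05, ldWindowSnps = 50L, ldStepSnps = 5L,
                     ldR2Max = 0.5, dropNonautosomal = TRUE) {
    new("QCParams", snpCallRateMin = snpCallRateMin,
        sampleCallRateMin = sampleCallRateMin, mafMin = mafMin,
        ldWindowSnps = as.integer(ldWindowSnps),
        ldStepSnps = as.integer(ldStepSnps), ldR2Max = ldR2Max,
        dropNonautosomal = dropNonautosomal)
}

.qcReport <- function(ds0, ds1, removed) {
    list(removed = removed,
         initial = c(snps = nVariants(ds0), samples = nSamples(ds0)),
         final = c(snps = nVariants(ds1), samples = nSamples(ds1)))
}

#' Per-SNP minor allele frequencies
#'
#' Allele frequencies are pooled over all samples (all populations together),
#' computed on non-missing genotypes.
#'
#' @param ds a [GenotypeData-class] object.
#' @return numeric vector of MAF per SNP (NA where no calls).
#' @export
snpMaf <- function(ds) {
    d <- dosages(ds)
    p <- rowMeans(d, na.rm = TRUE) / 2
    pmin(p, 1 - p)
}

#' Call-rate filtering
#'
#' First removes flagged (non-autosomal/unmapped) SNPs when
#' \code{dropNonautosomal} is set, then SNPs whose call rate is below
#' \code{snpCallRateMin}, then samples whose call rate -- computed on the
#' surviving SNPs -- is below \code{sampleCallRateMin}.  A call rate exactly
#' at the threshold is retained (the rule is "less than").
#'
#' @param ds a [GenotypeData-class] object.
#' @param params a [QCParams-class] object.
#' @return list(\code{data}, \code{report}).
#' @export
filterCallRate <- function(ds, params = qcParams()) {
    ds0 <- ds
    flagged <- snpInfo(ds)$flagged
    nFlag <- 0L
    if (params@dropNonautosomal && any(flagged)) {
        nFlag <- sum(flagged)
        ds <- ds[!flagged, ]
    }
    d <- dosages(ds)
    snpCR <- rowMeans(!is.na(d))
    keepSnp <- snpCR >= params@snpCallRateMin
    ds <- ds[keepSnp, ]
    if (nVariants(ds) == 0L) stop("call-rate filter removed all SNPs")
    d <- dosages(ds)
    samCR <- colMeans(!is.na(d))
    keepSam <- samCR >= params@sampleCallRateMin
    if (!any(keepSam)) stop("call-rate filter removed all samples")
    ds <- ds[, keepSam]
    report <- .qcReport(ds0, ds, c(nonautosomal = nFlag,
                                   snp_call_rate = sum(!keepSnp),
                                   sample_call_rate = sum(!keepSam)))
    list(data = ds, report = report)
}

#' Minor-allele-frequency filtering
#'
#' Removes SNPs with pooled MAF below \code{mafMin}; monomorphic SNPs
#' (MAF = 0) are always removed.  A MAF exactly at the threshold is retained.
#'
#' @inheritParams filterCallRate
#' @return list(\code{data}, \code{report}).
#' @export
filterMaf <- function(ds, params = qcParams()) {
    maf <- snpMaf(ds)
    keep <- !is.na(maf) & maf >= params@mafMin & maf > 0
    if (!any(keep)) stop("MAF filter removed all SNPs")
    out <- ds[keep, ]
    list(data = out, report = .qcReport(ds, out, c(maf = sum(!keep))))
}

# pairwise r^2 over samples non-missing for both SNPs, via crossproducts
# (X: samples x snps, NA allowed)
.pairwiseR2 <- function(X) {
    M <- !is.na(X); storage.mode(M) <- "double"
    X0 <- X; X0[is.na(X0)] <- 0
    n <- crossprod(M)
    Sx <- crossprod(X0, M)
    Sxy <- crossprod(X0)
    Sxx <- crossprod(X0^2, M)
    num <- n * Sxy - Sx * t(Sx)
    den <- (n * Sxx - Sx^2) * t(n * Sxx - Sx^2)
    r2 <- num^2 / den
    r2[!is.finite(r2)] <- 0
    r2
}

# prune one window: indices into the dosage matrix, returns indices to drop
.pruneWindow <- function(d, idx, maf, pos, r2max) {
    alive <- rep(TRUE, length(idx))
    r2 <- .pairwiseR2(d[, idx, drop = FALSE])
    diag(r2) <- 0
    repeat {
        r2a <- r2
        r2a[!alive, ] <- 0; r2a[, !alive] <- 0
        mx <- max(r2a)
        if (mx <= r2max) break
        w <- which(r2a == mx, arr.ind = TRUE)[1L, ]
        i <- idx[w[1L]]; j <- idx[w[2L]]
        # remove smaller MAF; tie -> later map position
        drop_i <- if (maf[i] != maf[j]) maf[i] < maf[j] else pos[i] > pos[j]
        k <- if (drop_i) w[1L] else w[2L]
        alive[k] <- FALSE
    }
    idx[!alive]
}

#' Linkage-disequilibrium pruning
#'
#' PLINK-style \code{indep-pairwise} pruning: per chromosome, a window of
#' \code{ldWindowSnps} SNPs advances \code{ldStepSnps} SNPs at a time;
#' within each window pairwise r^2 is the squared Pearson correlation of
#' dosage vectors over samples non-missing for both SNPs.  While any pair
#' exceeds \code{ldR2Max} the member with the smaller MAF is removed (tie:
#' the later map position).  The retained set keeps map order.
#'
#' @inheritParams filterCallRate
#' @return list(\code{data}, \code{report}).
#' @export
ldPrune <- function(ds, params = qcParams()) {
    info <- snpInfo(ds)
    d <- t(dosages(ds))            # samples x snps
    maf <- snpMaf(ds)
    pos <- info$pos
    w <- params@ldWindowSnps; step <- params@ldStepSnps
    alive <- rep(TRUE, nVariants(ds))
    chromIdx <- split(seq_len(nVariants(ds)), info$chrom)
    # windows are re-laid over the surviving SNPs and passes repeat until a
    # fixpoint, so the pruned set carries no violating pair in any final
    # window -- a stronger, re-scannable guarantee than a single sweep
    repeat {
        changed <- FALSE
        for (cidx in chromIdx) {
            cur <- cidx[alive[cidx]]
            n <- length(cur)
            if (n < 2L) next
            for (s in seq(1L, n, by = step)) {
                win <- cur[s:min(s + w - 1L, n)]
                win <- win[alive[win]]
                if (length(win) < 2L) next
                drop <- .pruneWindow(d, win, maf, pos, params@ldR2Max)
                if (length(drop)) { alive[drop] <- FALSE; changed <- TRUE }
            }
        }
        if (!changed) break
    }
    out <- ds[alive, ]
    list(data = out,
         report = .qcReport(ds, out, c(ld_pruned = sum(!alive))))
}

#' Produce the three staged QC subsets
#'
#' Reproduces the three-subset design of array studies of this kind: the ROH
#' subset receives call-rate filtering only (MAF/LD filtering distorts ROH
#' discovery), the diversity subset adds the MAF filter, and the structure
#' subset adds LD pruning.  By construction
#' \code{roh} \eqn{\supseteq} \code{diversity} \eqn{\supseteq}
#' \code{structure} as SNP sets.
#'
#' @inheritParams filterCallRate
#' @return list with [GenotypeData-class] elements \code{roh},
#'   \code{diversity}, \code{structure} and a combined \code{report}.
#' @export
qcSubsets <- function(ds, params = qcParams()) {
    cr <- filterCallRate(ds, params)
    mf <- filterMaf(cr$data, params)
    ld <- ldPrune(mf$data, params)
    list(roh = cr$data, diversity = mf$data, structure = ld$data,
         report = list(call_rate = cr$report, maf = mf$report,
                       ld = ld$report))
}
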