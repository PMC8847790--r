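#' GenotypeData: SNP-array genotypes with map and population labels
#'
#' The central container of the package.  Extends
#' \linkS4class{RangedSummarizedExperiment}: variants are rows (a
#' \code{GRanges} of single-bp positions carrying \code{snp_id},
#' \code{allele_a}, \code{allele_b} and a \code{flagged} marker for
#' non-autosomal or unmapped SNPs), samples are columns (with a
#' \code{population} label), and the single assay \code{"dosage"} holds the
#' count of \code{allele_b} copies per genotype: 0, 1, 2 or \code{NA} for
#' missing.  Coordinates are 1-based inclusive bp (PLINK convention); all
#' interval arithmetic downstream uses 1-based closed intervals.
#'
#' Variants are kept sorted by (chromosome, position) with autosomes 1-18
#' first in numeric order, and duplicate (chromosome, position) pairs among
#' non-flagged variants are rejected.  Use [genotypeData()] to construct
#' objects; it sorts and validates.
#'
#' @seealso [genotypeData()], [readPlink()], [dosages()]
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

#' GenomeInfo: autosome lengths
#'
#' Chromosome lengths (bp) of the autosomal genome covered by the SNP array.
#' The total autosomal length is the denominator of F_ROH.
#'
#' @slot lengths named numeric vector of per-chromosome lengths in bp; names
#'   are chromosome identifiers ("1", "2", ...).
#' @seealso [genomeInfo()], [sscrofaGenome()], [froh()]
#' @export
setClass("GenomeInfo", representation(lengths = "numeric"))

setValidity("GenomeInfo", function(object) {
    msg <- NULL
    if (length(object@lengths) == 0L)
        msg <- c(msg, "at least one chromosome length required")
    if (any(object@lengths <= 0))
        msg <- c(msg, "all chromosome lengths must be > 0")
    if (is.null(names(object@lengths)) || anyDuplicated(names(object@lengths)))
        msg <- c(msg, "lengths must have unique chromosome names")
    if (is.null(msg)) TRUE else msg
})

#' ROHParams: parameterization of sliding-window ROH detection
#'
#' Mirrors the PLINK \code{--homozyg} parameter set.  A window of
#' \code{windowSnp} consecutive SNPs is scored homozygous when it contains at
#' most \code{windowHetMax} heterozygous and \code{windowMissingMax} missing
#' calls; a SNP is "in run" when the fraction of windows covering it that are
#' homozygous reaches \code{windowHitThreshold}.  Maximal in-run stretches
#' are split at heterozygous calls and at gaps larger than \code{maxGapKb},
#' then filtered on \code{minSnp} SNPs, \code{minLengthKb} kb, and an average
#' SNP spacing of at most \code{densityKbPerSnp} kb per SNP.
#'
#' \code{windowSnp} and \code{minSnp} are typically both set to the
#' L-parameter (see [lParam()]), a multiple-testing bound on the minimum run
#' length expected by chance across all SNPs and individuals.
#'
#' @slot minLengthKb minimum run length in kb (default 1000, i.e. 1 Mb).
#' @slot densityKbPerSnp maximum average kb per SNP inside a run (default 50).
#' @slot maxGapKb maximum gap between consecutive run SNPs in kb (default 1000).
#' @slot windowHetMax maximum heterozygous calls per window (default 0).
#' @slot windowMissingMax maximum missing calls per window (default 1).
#' @slot segmentHetMax maximum heterozygous calls per final segment (only 0
#'   is supported; runs are split at heterozygous calls).
#' @slot windowSnp SNPs per sliding window.
#' @slot minSnp minimum SNPs per reported segment.
#' @slot windowHitThreshold minimum homozygous-window fraction for a SNP to
#'   be in run (default 0.05).
#' @slot lAlpha false-positive rate used when the window size was derived
#'   with [lParam()] (informational; default 0.05).
#' @seealso [rohParams()], [lParam()], [detectRoh()]
#' @export
setClass("ROHParams", representation(
    minLengthKb = "numeric",
    densityKbPerSnp = "numeric",
    maxGapKb = "numeric",
    windowHetMax = "integer",
    windowMissingMax = "integer",
    segmentHetMax = "integer",
    windowSnp = "integer",
    minSnp = "integer",
    windowHitThreshold = "numeric",
    lAlpha = "numeric"
))

setValidity("ROHParams", function(object) {
    msg <- NULL
    if (object@minLengthKb <= 0) msg <- c(msg, "minLengthKb must be > 0")
    if (object@windowSnp < 2L) msg <- c(msg, "windowSnp must be >= 2")
    if (object@minSnp < 1L) msg <- c(msg, "minSnp must be >= 1")
    if (object@windowHitThreshold < 0 || object@windowHitThreshold > 1)
        msg <- c(msg, "windowHitThreshold must be in [0,1]")
    if (object@segmentHetMax != 0L)
        msg <- c(msg, "only segmentHetMax = 0 is supported (runs split at heterozygous calls)")
    if (object@densityKbPerSnp <= 0) msg <- c(msg, "densityKbPerSnp must be > 0")
    if (object@maxGapKb <= 0) msg <- c(msg, "maxGapKb must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' QCParams: thresholds for the staged quality-control workflow
#'
#' Defaults reproduce a standard SNP-array QC: SNP call rate >= 0.90, sample
#' call rate >= 0.90, MAF >= 0.05, LD pruning with 50-SNP windows advancing
#' 5 SNPs at r^2 > 0.5 (PLINK \code{indep-pairwise 50 5 0.5}).
#'
#' @slot snpCallRateMin minimum SNP call rate (fraction, default 0.90).
#' @slot sampleCallRateMin minimum sample call rate (default 0.90).
#' @slot mafMin minimum minor allele frequency (default 0.05).
#' @slot ldWindowSnps LD-pruning window size in SNPs (default 50).
#' @slot ldStepSnps LD-pruning window step in SNPs (default 5).
#' @slot ldR2Max maximum tolerated pairwise r^2 (default 0.5).
#' @slot dropNonautosomal drop flagged / non-autosomal SNPs first (default TRUE).
#' @seealso [qcParams()], [qcSubsets()]
#' @export
setClass("QCParams", representation(
    snpCallRateMin = "numeric",
    sampleCallRateMin = "numeric",
    mafMin = "numeric",
    ldWindowSnps = "integer",
    ldStepSnps = "integer",
    ldR2Max = "numeric",
    dropNonautosomal = "logical"
))

setValidity("QCParams", function(object) {
    msg <- NULL
    fr <- c(object@snpCallRateMin, object@sampleCallRateMin, object@mafMin,
            object@ldR2Max)
    if (any(fr < 0 | fr > 1))
        msg <- c(msg, "all rate/frequency thresholds must be in [0,1]")
    if (object@ldStepSnps < 1L || object@ldWindowSnps < object@ldStepSnps)
        msg <- c(msg, "need ldWindowSnps >= ldStepSnps >= 1")
    if (is.null(msg)) TRUE else msg
})
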