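# Construction, validation and accessors for GenotypeData.

.chromOrderKey <- function(chrom) {
    k <- suppressWarnings(as.integer(chrom))
    autosome <- !is.na(k) & k >= 1L & k <= 18L
    list(primary = ifelse(autosome, 0L, 1L),
         numeric = ifelse(autosome, k, NA_integer_))
}

.orderVariants <- function(chrom, pos) {
    key <- .chromOrderKey(chrom)
    order(key$primary, key$numeric, as.character(chrom), pos)
}

.checkDosage <- function(d) {
    v <- d[!is.na(d)]
    if (length(v) && !all(v == 0L | v == 1L | v == 2L))
        stop("dosage entries must be 0, 1, 2 or NA")
}

#' Construct a GenotypeData object
#'
#' Builds the package's central container from an allele-dosage matrix and a
#' variant map.  Variants are sorted by (chromosome, position); duplicate
#' positions among non-flagged variants are an error.  Dosages count copies
#' of \code{allele_b} (0/1/2, \code{NA} = missing).
#'
#' @param dosage integer matrix, variants x samples.
#' @param variants data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos}, \code{allele_a}, \code{allele_b} and optionally
#'   \code{flagged} (logical; non-autosomal or unmapped SNPs destined for QC
#'   removal).
#' @param sampleId character vector of unique sample identifiers.
#' @param population character vector of per-sample population labels.
#' @return A [GenotypeData-class] object.
#' @examples
#' ds <- genotypeData(
#'   dosage = matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'                   dimnames = list(NULL, c("s1", "s2"))),
#'   variants = data.frame(snp_id = c("rs1", "rs2"), chrom = "1",
#'                         pos = c(100L, 200L),
#'                         allele_a = "A", allele_b = "G"),
#'   sampleId = c("s1", "s2"), population = c("DUC", "KNP"))
#' dosages(ds)
#' @export
genotypeData <- function(dosage, variants, sampleId, population) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    required <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
    if (!all(required %in% names(variants)))
        stop("variants must have columns: ", paste(required, collapse = ", "))
    if (nrow(dosage) != nrow(variants))
        stop("dosage rows (", nrow(dosage), ") != variants (", nrow(variants), ")")
    if (ncol(dosage) != length(sampleId) || length(sampleId) != length(population))
        stop("sample dimensions inconsistent")
    if (anyDuplicated(sampleId))
        stop("sample identifiers must be unique")
    if (anyDuplicated(variants$snp_id))
        stop("snp identifiers must be unique")
    .checkDosage(dosage)
    if (is.null(variants$flagged))
        variants$flagged <- rep(FALSE, nrow(variants))
    key <- .chromOrderKey(variants$chrom)
    variants$flagged <- variants$flagged | key$primary == 1L

    ord <- .orderVariants(variants$chrom, variants$pos)
    variants <- variants[ord, , drop = FALSE]
    dosage <- dosage[ord, , drop = FALSE]

    ok <- !variants$flagged
    dup <- duplicated(paste(variants$chrom, variants$pos)[ok])
    if (any(dup)) {
        bad <- paste(variants$chrom, variants$pos)[ok][dup]
        stop("duplicate (chrom, pos): ", paste(unique(bad), collapse = ", "))
    }

    chr <- as.character(variants$chrom)
    lev <- unique(chr)  # already in sorted variant order
    gr <- GRanges(factor(chr, levels = lev),
                  IRanges(start = as.integer(variants$pos), width = 1L),
                  snp_id = as.character(variants$snp_id),
                  allele_a = as.character(variants$allele_a),
                  allele_b = as.character(variants$allele_b),
                  flagged = variants$flagged)
    names(gr) <- variants$snp_id
    dimnames(dosage) <- list(variants$snp_id, sampleId)
    se <- SummarizedExperiment(
        assays = list(dosage = dosage),
        rowRanges = gr,
        colData = DataFrame(population = as.character(population),
                            row.names = sampleId))
    new("GenotypeData", se)
}

#' @describeIn genotypeData Allele-dosage matrix (variants x samples).
#' @param x a [GenotypeData-class] object.
#' @export
dosages <- function(x) assay(x, "dosage")

#' @describeIn genotypeData Per-sample population labels.
#' @export
populations <- function(x) as.character(colData(x)$population)

#' @describeIn genotypeData Sample identifiers.
#' @export
sampleIds <- function(x) colnames(x)

#' @describeIn genotypeData Variant map as a data.frame (snp_id, chrom, pos,
#'   allele_a, allele_b, flagged).
#' @export
snpInfo <- function(x) {
    gr <- rowRanges(x)
    data.frame(snp_id = mcols(gr)$snp_id,
               chrom = as.character(seqnames(gr)),
               pos = start(gr),
               allele_a = mcols(gr)$allele_a,
               allele_b = mcols(gr)$allele_b,
               flagged = mcols(gr)$flagged,
               row.names = NULL,
               stringsAsFactors = FALSE)
}

#' @describeIn genotypeData Number of variants.
#' @export
nVariants <- function(x) nrow(x)

#' @describeIn genotypeData Number of samples.
#' @export
nSamples <- function(x) ncol(x)

setMethod("show", "GenotypeData", function(object) {
    pops <- table(populations(object))
    cat("GenotypeData:", nrow(object), "variants x", ncol(object), "samples\n")
    cat("  populations:",
        paste(sprintf("%s (%d)", names(pops), as.integer(pops)), collapse = ", "),
        "\n")
    nflag <- sum(mcols(rowRanges(object))$flagged)
    if (nflag)
        cat("  flagged (non-autosomal/unmapped) variants:", nflag, "\n")
    chr <- unique(as.character(seqnames(rowRanges(object))))
    cat("  chromosomes:", paste(head(chr, 10), collapse = ", "),
        if (length(chr) > 10) "..." else "", "\n")
})

# Rebuild a GenotypeData after any row/column subset expressed as indices.
.subsetGenotypeData <- function(x, snps = NULL, samples = NULL) {
    if (!is.null(snps)) x <- x[snps, ]
    if (!is.null(samples)) x <- x[, samples]
    x
}
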