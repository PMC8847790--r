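#' Construct a GenomeInfo object
#'
#' @param lengths named numeric vector of chromosome lengths in bp.
#' @return A [GenomeInfo-class] object.
#' @examples
#' g <- genomeInfo(c(`1` = 5e6, `2` = 5e6))
#' totalAutosomeLength(g)
#' @export
genomeInfo <- function(lengths) {
    new("GenomeInfo", lengths = setNames(as.numeric(lengths), names(lengths)))
}

#' Per-chromosome lengths of a GenomeInfo
#' @param x a [GenomeInfo-class] object.
#' @return named numeric vector of lengths in bp.
#' @export
chromLengths <- function(x) {
    stopifnot(is(x, "GenomeInfo"))
    x@lengths
}

#' Total autosomal length of a GenomeInfo
#' @param x a [GenomeInfo-class] object.
#' @return total length in bp (the F_ROH denominator).
#' @export
totalAutosomeLength <- function(x) sum(chromLengths(x))

#' Default 18-autosome pig genome
#'
#' Chromosome lengths proportioned like the Sus scrofa 11.1 autosomes and
#' scaled so the total SNP-covered autosomal genome is exactly 2,262.6 Mb,
#' the denominator used for F_ROH on the PorcineSNP60 array.
#'
#' @return A [GenomeInfo-class] with autosomes "1".."18".
#' @examples
#' totalAutosomeLength(sscrofaGenome())  # 2,262,600,000
#' @export
sscrofaGenome <- function() {
    raw <- c(274.3, 151.9, 132.8, 130.9, 104.5, 170.8, 121.8, 138.9, 139.5,
             69.4, 79.2, 61.6, 208.3, 141.8, 140.4, 79.9, 63.5, 55.9) * 1e6
    total <- 2262.6e6
    len <- round(raw * total / sum(raw))
    len[18] <- total - sum(len[-18])
    genomeInfo(setNames(len, as.character(1:18)))
}

setMethod("show", "GenomeInfo", function(object) {
    cat("GenomeInfo with", length(object@lengths), "chromosomes;",
        "total", format(sum(object@lengths), big.mark = ","), "bp\n")
})
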