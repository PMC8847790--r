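# Coordinate remapping between genome assemblies (manifest-style table).

#' Update SNP coordinates from a remap table
#'
#' Applies an assembly remap (e.g. Sscrofa10.2 to Sscrofa11.1) given as a
#' manifest-style table \code{snp_id -> (chrom, pos)}.  SNPs absent from the
#' table, or mapped to chromosome 0 / position 0, are classified unmapped:
#' they keep their old coordinates but are flagged so the QC stage removes
#' them.  The returned dataset is re-sorted by the new coordinates; dosage
#' columns follow their SNP identifiers.
#'
#' @param ds a [GenotypeData-class] object.
#' @param remap data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (or the first three columns are taken as such).
#' @return list with elements \code{data} (remapped [GenotypeData-class]) and
#'   \code{report} (counts: \code{remapped}, \code{unmapped},
#'   \code{unchanged}).
#' @examples
#' \dontrun{
#' res <- updateCoordinates(ds, read.table("manifest.tsv", header = TRUE))
#' res$report
#' }
#' @export
updateCoordinates <- function(ds, remap) {
    remap <- as.data.frame(remap)
    if (!all(c("snp_id", "chrom", "pos") %in% names(remap))) {
        if (ncol(remap) < 3L)
            stop("remap table needs columns snp_id, chrom, pos")
        names(remap)[1:3] <- c("snp_id", "chrom", "pos")
    }
    if (anyDuplicated(remap$snp_id))
        stop("remap table has duplicate snp_id entries")
    info <- snpInfo(ds)
    idx <- match(info$snp_id, remap$snp_id)
    found <- !is.na(idx)
    newChrom <- as.character(remap$chrom[idx])
    newPos <- suppressWarnings(as.integer(remap$pos[idx]))
    badTarget <- found & (is.na(newPos) | newPos == 0L |
                          is.na(newChrom) | newChrom == "0")
    unmapped <- !found | badTarget

    chrom <- info$chrom; pos <- info$pos
    chrom[found & !unmapped] <- newChrom[found & !unmapped]
    pos[found & !unmapped] <- newPos[found & !unmapped]

    moved <- found & !unmapped & (chrom != info$chrom | pos != info$pos)
    report <- c(remapped = sum(moved),
                unmapped = sum(unmapped),
                unchanged = sum(found & !unmapped & !moved))

    key <- .chromOrderKey(chrom)
    ok <- !unmapped & key$primary == 0L
    dup <- paste(chrom, pos)[ok][duplicated(paste(chrom, pos)[ok])]
    if (length(dup))
        stop("remap creates duplicate (chrom, pos): ",
             paste(unique(dup), collapse = ", "))

    variants <- data.frame(snp_id = info$snp_id, chrom = chrom, pos = pos,
                           allele_a = info$allele_a, allele_b = info$allele_b,
                           flagged = info$flagged | unmapped,
                           stringsAsFactors = FALSE)
    list(data = genotypeData(dosages(ds), variants,
                             sampleId = sampleIds(ds),
                             population = populations(ds)),
         report = report)
}
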