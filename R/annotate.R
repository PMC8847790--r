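# Gene (GFF3) and QTL (BED-like TSV) annotation of ROH island bins by
# interval overlap.  GFF3 parsing is delegated to rtracklayer after a
# tolerant pre-scan that drops malformed lines with a counted warning.

#' Read gene features from a GFF3 file
#'
#' Imports features of the requested types and resolves a display name per
#' feature by attribute priority (first non-empty among
#' \code{nameAttributePriority}).  GFF3 1-based coordinates are preserved;
#' strand is ignored (ROH islands are unstranded).  Malformed lines (not 9
#' tab-separated fields) are skipped with one counted warning.  Chromosome
#' names can be translated through \code{chromAliases} (named vector,
#' alias -> chromosome); features on chromosomes that are neither known
#' aliases nor plain dataset names are excluded and counted.
#'
#' @param path GFF3 file path (may be gzip-compressed).
#' @param featureTypes GFF3 types to keep (default \code{"gene"}).
#' @param nameAttributePriority attribute names tried in order to resolve
#'   the feature name (default \code{c("Name", "gene", "ID")}).
#' @param chromAliases optional named character vector mapping
#'   accession-style names to chromosome names ("1".."18").
#' @param knownChroms chromosomes accepted without an alias (default
#'   \code{as.character(1:18)}; NULL accepts everything).
#' @return data.frame (chrom, start_bp, end_bp, kind, name, type), with
#'   attributes \code{nSkipped} (malformed lines) and \code{nExcluded}
#'   (unknown chromosomes).
#' @export
readGff3 <- function(path, featureTypes = "gene",
                     nameAttributePriority = c("Name", "gene", "ID"),
                     chromAliases = NULL,
                     knownChroms = as.character(1:18)) {
    lines <- readLines(path)
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    nf <- lengths(regmatches(body, gregexpr("\t", body))) + 1L
    bad <- nf != 9L
    nSkipped <- sum(bad)
    if (nSkipped)
        warning(nSkipped, " malformed GFF3 line(s) skipped")
    tmp <- tempfile(fileext = ".gff3")
    on.exit(unlink(tmp))
    writeLines(c("##gff-version 3", body[!bad]), tmp)
    gr <- rtracklayer::import(tmp, format = "gff3")
    gr <- gr[as.character(gr$type) %in% featureTypes]
    chrom <- as.character(seqnames(gr))
    if (!is.null(chromAliases)) {
        hit <- chrom %in% names(chromAliases)
        chrom[hit] <- chromAliases[chrom[hit]]
    }
    keep <- if (is.null(knownChroms)) rep(TRUE, length(chrom))
            else chrom %in% knownChroms
    nExcluded <- sum(!keep)
    if (nExcluded)
        warning(nExcluded, " feature(s) on unknown chromosomes excluded")
    gr <- gr[keep]; chrom <- chrom[keep]
    md <- mcols(gr)
    name <- rep(NA_character_, length(gr))
    for (attrName in rev(nameAttributePriority)) {
        if (attrName %in% names(md)) {
            v <- as.character(md[[attrName]])
            ok <- !is.na(v) & nzchar(v)
            name[ok] <- v[ok]
        }
    }
    out <- data.frame(chrom = chrom, start_bp = start(gr), end_bp = end(gr),
                      kind = "gene", name = name,
                      type = as.character(gr$type),
                      stringsAsFactors = FALSE)
    attr(out, "nSkipped") <- nSkipped
    attr(out, "nExcluded") <- nExcluded
    out
}

#' Read a QTL table
#'
#' Reads a BED-like, 1-based TSV with columns chrom, start, end, trait name
#' (header optional, detected from a non-numeric second field).
#'
#' @param path TSV file path.
#' @return data.frame (chrom, start_bp, end_bp, kind = "QTL", name).
#' @export
readQtlTable <- function(path) {
    first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
    hasHeader <- length(first) >= 2L &&
        is.na(suppressWarnings(as.numeric(first[2])))
    tb <- read.table(path, sep = "\t", header = hasHeader,
                     stringsAsFactors = FALSE, quote = "")
    if (ncol(tb) < 4L) stop("QTL table needs >= 4 columns (chrom, start, end, name)")
    data.frame(chrom = as.character(tb[[1]]), start_bp = as.integer(tb[[2]]),
               end_bp = as.integer(tb[[3]]), kind = "QTL",
               name = as.character(tb[[4]]), stringsAsFactors = FALSE)
}

#' Annotate island bins with overlapping features
#'
#' Emits one row per (bin, feature) pair sharing at least 1 bp, with the
#' overlap width.  A feature straddling two bins yields two rows; unique
#' feature counts should be taken from [uniqueFeatureSummary()].
#'
#' @param bins data.frame from [rohIslands()] (needs chrom, bin_start,
#'   bin_end and optionally population).
#' @param features data.frame from [readGff3()] and/or [readQtlTable()]
#'   (rbind them to annotate both kinds at once).
#' @return data.frame (population, chrom, bin_start, bin_end, kind, name,
#'   feature_start, feature_end, overlap_bp).
#' @export
annotateBins <- function(bins, features) {
    empty <- data.frame(population = character(0), chrom = character(0),
                        bin_start = numeric(0), bin_end = numeric(0),
                        kind = character(0), name = character(0),
                        feature_start = integer(0), feature_end = integer(0),
                        overlap_bp = numeric(0), stringsAsFactors = FALSE)
    if (!nrow(bins) || !nrow(features)) return(empty)
    grB <- GRanges(as.character(bins$chrom),
                   IRanges(bins$bin_start, bins$bin_end))
    grF <- GRanges(as.character(features$chrom),
                   IRanges(features$start_bp, features$end_bp))
    gl <- .sharedSeqinfo(grB, grF)
    hits <- suppressWarnings(findOverlaps(gl[[1]], gl[[2]]))
    if (!length(hits)) return(empty)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ovl <- width(pintersect(gl[[1]][qi], gl[[2]][si]))
    data.frame(
        population = if ("population" %in% names(bins))
            bins$population[qi] else NA_character_,
        chrom = as.character(bins$chrom)[qi],
        bin_start = bins$bin_start[qi], bin_end = bins$bin_end[qi],
        kind = features$kind[si], name = features$name[si],
        feature_start = features$start_bp[si],
        feature_end = features$end_bp[si],
        overlap_bp = as.numeric(ovl), stringsAsFactors = FALSE)
}

#' Unique annotated features per population
#'
#' Deduplicates the (bin, feature) pair table by resolved feature name
#' within population and kind.
#'
#' @param annotation data.frame from [annotateBins()].
#' @return data.frame (population, kind, n_unique).
#' @export
uniqueFeatureSummary <- function(annotation) {
    if (!nrow(annotation))
        return(data.frame(population = character(0), kind = character(0),
                          n_unique = integer(0)))
    key <- unique(annotation[, c("population", "kind", "name")])
    agg <- table(key$population, key$kind)
    out <- as.data.frame(agg, stringsAsFactors = FALSE)
    names(out) <- c("population", "kind", "n_unique")
    out[out$n_unique > 0, , drop = FALSE]
}
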