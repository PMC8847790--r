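# PLINK text (.ped/.map) and binary (.bed/.bim/.fam) input/output.
# No PLINK reader is available in the R stack used here, so the two layouts
# are parsed directly; both follow PLINK 1.x conventions ("0" = missing
# allele; .bed SNP-major with magic bytes 0x6c 0x1b 0x01).

# dosage value for the 2-bit .bed codes 00,01,10,11 (hom A1, missing, het,
# hom A2), counting copies of A2 (= allele_b)
.bedDecodeLUT <- local({
    lut <- matrix(NA_integer_, nrow = 256L, ncol = 4L)
    map <- c(0L, NA_integer_, 1L, 2L)
    for (v in 0:255)
        for (k in 0:3)
            lut[v + 1L, k + 1L] <- map[bitwAnd(bitwShiftR(v, 2L * k), 3L) + 1L]
    lut
})

.readTable <- function(path, ncolEmpty = 4L, ...) {
    if (file.size(path) == 0L)
        return(as.data.frame(matrix(character(0), 0L, ncolEmpty),
                             stringsAsFactors = FALSE))
    read.table(path, header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character", ...)
}

#' Read genotypes from PLINK files
#'
#' Reads a dataset from PLINK text (\code{.ped}/\code{.map}) or binary
#' (\code{.bed}/\code{.bim}/\code{.fam}) files.  Population labels are taken
#' from the family-ID column.  Non-autosomal chromosomes (outside 1-18) are
#' retained but flagged for later QC removal.
#'
#' For the text layout the counted allele (\code{allele_b}) is the
#' alphabetically later of the two observed alleles; a SNP with only one
#' observed allele gets \code{allele_b = "0"} (the unobserved allele cannot
#' be recovered from a .ped file).  The binary layout stores both alleles in
#' the .bim file, so orientation round-trips exactly.
#'
#' @param prefix path prefix (without extension).
#' @param format \code{"binary"}, \code{"text"} or \code{"auto"} (detect by
#'   which files exist, preferring binary).
#' @return A [GenotypeData-class] object.
#' @seealso [writePlink()]
#' @export
readPlink <- function(prefix, format = c("auto", "binary", "text")) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (file.exists(paste0(prefix, ".bed"))) "binary"
                  else if (file.exists(paste0(prefix, ".ped"))) "text"
                  else stop("no .bed or .ped file found for prefix ", prefix)
    }
    if (format == "binary") .readPlinkBinary(prefix) else .readPlinkText(prefix)
}

.readPlinkText <- function(prefix) {
    mapf <- paste0(prefix, ".map"); pedf <- paste0(prefix, ".ped")
    if (!file.exists(mapf) || !file.exists(pedf))
        stop("missing .ped/.map files for prefix ", prefix)
    map <- .readTable(mapf)
    if (!ncol(map) %in% c(3L, 4L))
        stop("format error: .map must have 3 or 4 columns")
    poscol <- ncol(map)
    m <- nrow(map)

    lines <- readLines(pedf)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[ \t]+")
    nfield <- lengths(toks)
    if (length(unique(nfield)) > 1L || (m > 0L && nfield[1] != 6L + 2L * m))
        stop("format error: .ped field count does not match .map variant count")
    ped <- do.call(rbind, toks)
    fam <- ped[, 1L]; iid <- ped[, 2L]
    n <- nrow(ped)
    if (m == 0L) {
        return(genotypeData(matrix(integer(0), 0L, n),
                            data.frame(snp_id = character(0), chrom = character(0),
                                       pos = integer(0), allele_a = character(0),
                                       allele_b = character(0)),
                            sampleId = iid, population = fam))
    }
    a1 <- t(ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])  # m x n
    a2 <- t(ped[, 6L + 2L * seq_len(m), drop = FALSE])
    missing <- a1 == "0" | a2 == "0"
    a1[missing] <- NA; a2[missing] <- NA

    allele_a <- character(m); allele_b <- character(m)
    dosage <- matrix(NA_integer_, m, n)
    for (j in seq_len(m)) {
        obs <- sort(unique(c(a1[j, ], a2[j, ])))
        obs <- obs[!is.na(obs)]
        if (length(obs) > 2L)
            stop("format error: more than two alleles at SNP ", map[j, 2L])
        aa <- if (length(obs) >= 1L) obs[1L] else "0"
        bb <- if (length(obs) == 2L) obs[2L] else "0"
        allele_a[j] <- aa; allele_b[j] <- bb
        dosage[j, ] <- (a1[j, ] == bb) + (a2[j, ] == bb)
    }
    variants <- data.frame(snp_id = map[, 2L], chrom = map[, 1L],
                           pos = as.integer(map[, poscol]),
                           allele_a = allele_a, allele_b = allele_b,
                           stringsAsFactors = FALSE)
    genotypeData(dosage, variants, sampleId = iid, population = fam)
}

.readPlinkBinary <- function(prefix) {
    bimf <- paste0(prefix, ".bim"); famf <- paste0(prefix, ".fam")
    bedf <- paste0(prefix, ".bed")
    if (!all(file.exists(c(bimf, famf, bedf))))
        stop("missing .bed/.bim/.fam files for prefix ", prefix)
    bim <- .readTable(bimf, ncolEmpty = 6L)
    if (ncol(bim) != 6L) stop("format error: .bim must have 6 columns")
    fam <- .readTable(famf)
    m <- nrow(bim); n <- nrow(fam)
    raw <- readBin(bedf, what = "raw", n = file.size(bedf))
    if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
        stop("format error: bad .bed magic bytes")
    if (raw[3] != as.raw(0x01))
        stop("format error: only SNP-major .bed files are supported")
    bpf <- ceiling(n / 4)
    body <- raw[-(1:3)]
    if (length(body) != bpf * m)
        stop("format error: .bed size does not match .bim/.fam dimensions")
    codes <- .bedDecodeLUT[as.integer(body) + 1L, , drop = FALSE]  # (bpf*m) x 4
    arr <- array(t(codes), dim = c(4L * bpf, m))
    dosage <- t(arr[seq_len(n), , drop = FALSE])                   # m x n
    variants <- data.frame(snp_id = bim[, 2L], chrom = bim[, 1L],
                           pos = as.integer(bim[, 4L]),
                           allele_a = bim[, 5L], allele_b = bim[, 6L],
                           stringsAsFactors = FALSE)
    genotypeData(dosage, variants, sampleId = fam[, 2L], population = fam[, 1L])
}

#' Write genotypes to PLINK files
#'
#' Writes the dataset in PLINK text or binary layout.  Binary output
#' round-trips exactly through [readPlink()]; text output round-trips
#' exactly whenever both alleles of every SNP are observed and
#' \code{allele_a < allele_b} alphabetically (the .ped format does not store
#' allele identities).
#'
#' @param ds a [GenotypeData-class] object.
#' @param prefix output path prefix.
#' @param format \code{"binary"} or \code{"text"}.
#' @return \code{prefix}, invisibly.
#' @export
writePlink <- function(ds, prefix, format = c("binary", "text")) {
    format <- match.arg(format)
    info <- snpInfo(ds)
    d <- dosages(ds)
    fam <- data.frame(populations(ds), sampleIds(ds), 0L, 0L, 0L, -9L)
    if (format == "binary") {
        write.table(data.frame(info$chrom, info$snp_id,
                               rep(0L, nrow(info)), info$pos,
                               info$allele_a, info$allele_b),
                    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                    row.names = FALSE, col.names = FALSE)
        write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                    row.names = FALSE, col.names = FALSE)
        n <- ncol(d); m <- nrow(d); bpf <- ceiling(n / 4)
        code <- matrix(0L, 4L * bpf, m)
        enc <- d; enc[is.na(enc)] <- -1L
        # dosage -> 2-bit code: 0->0 (hom A1), 1->2 (het), 2->3 (hom A2), NA->1
        codemap <- c(`-1` = 1L, `0` = 0L, `1` = 2L, `2` = 3L)
        code[seq_len(n), ] <- codemap[as.character(t(enc))]
        dim(code) <- c(4L, bpf * m)
        bytes <- as.raw(code[1L, ] + 4L * code[2L, ] + 16L * code[3L, ] +
                        64L * code[4L, ])
        con <- file(paste0(prefix, ".bed"), "wb")
        on.exit(close(con))
        writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
        writeBin(bytes, con)
    } else {
        write.table(data.frame(info$chrom, info$snp_id,
                               rep(0L, nrow(info)), info$pos),
                    paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                    row.names = FALSE, col.names = FALSE)
        m <- nrow(d)
        geno <- matrix("0 0", nrow = ncol(d), ncol = m)
        if (m > 0L) {
            gs <- cbind(paste(info$allele_a, info$allele_a),
                        paste(info$allele_a, info$allele_b),
                        paste(info$allele_b, info$allele_b))
            dt <- t(d)  # samples x m
            for (j in seq_len(m)) {
                g <- dt[, j]
                ok <- !is.na(g)
                geno[ok, j] <- gs[j, ][g[ok] + 1L]
            }
        }
        out <- cbind(as.matrix(format(fam, trim = TRUE)), geno)
        writeLines(apply(out, 1L, paste, collapse = " "), paste0(prefix, ".ped"))
    }
    invisible(prefix)
}
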