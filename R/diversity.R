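# Observed/expected heterozygosity and homozygosity-based inbreeding (F_HOM).

#' Per-SNP and per-population heterozygosity statistics
#'
#' For every SNP (within each population, or pooled) computes the allele-b
#' frequency p over non-missing genotypes, the observed heterozygote
#' fraction H_O, and the Hardy-Weinberg expected heterozygosity
#' H_E = 2p(1-p).  Population summaries are means and SDs across SNPs;
#' SNPs with zero non-missing calls in a population are excluded from that
#' population's summary and counted.
#'
#' @param ds a [GenotypeData-class] object (typically the diversity QC
#'   subset).
#' @param byPopulation compute within each population (default) or pooled.
#' @return list with \code{perSnp} (population, snp_id, n, p, h_obs, h_exp)
#'   and \code{summary} (population, n_snps, n_excluded, ho_mean, ho_sd,
#'   he_mean, he_sd).
#' @export
hetStats <- function(ds, byPopulation = TRUE) {
    d <- dosages(ds)
    info <- snpInfo(ds)
    pops <- if (byPopulation) populations(ds) else rep("ALL", nSamples(ds))
    perSnp <- list(); summ <- list()
    for (pp in unique(pops)) {
        dp <- d[, pops == pp, drop = FALSE]
        n <- rowSums(!is.na(dp))
        het <- rowSums(dp == 1L, na.rm = TRUE)
        p <- rowSums(dp, na.rm = TRUE) / (2 * pmax(n, 1L))
        hObs <- ifelse(n > 0L, het / n, NA_real_)
        hExp <- ifelse(n > 0L, 2 * p * (1 - p), NA_real_)
        ok <- n > 0L
        perSnp[[pp]] <- data.frame(population = pp, snp_id = info$snp_id,
                                   n = n, p = ifelse(ok, p, NA_real_),
                                   h_obs = hObs, h_exp = hExp,
                                   stringsAsFactors = FALSE)
        summ[[pp]] <- data.frame(population = pp, n_snps = sum(ok),
                                 n_excluded = sum(!ok),
                                 ho_mean = mean(hObs[ok]), ho_sd = sd(hObs[ok]),
                                 he_mean = mean(hExp[ok]), he_sd = sd(hExp[ok]),
                                 stringsAsFactors = FALSE)
    }
    list(perSnp = do.call(rbind, c(perSnp, make.row.names = FALSE)),
         summary = do.call(rbind, c(summ, make.row.names = FALSE)))
}

#' Homozygosity-based inbreeding coefficient F_HOM
#'
#' For individual i over its non-missing loci J_i:
#' \deqn{F_{HOM} = (O - E) / (|J_i| - E)}
#' where O is the observed number of homozygous loci and
#' \eqn{E = \sum_{j \in J_i} (1 - 2 p_j (1 - p_j))} the expected number
#' under Hardy-Weinberg.  With \code{correction = "sample_size"} the
#' heterozygosity term is multiplied by \eqn{N_j/(N_j - 1)} per locus
#' (the small-sample correction PLINK's \code{--het} applies; the default
#' \code{"none"} matches the plain formula).  Frequencies default to
#' within-population, since per-population tables are the usual report;
#' set \code{byPopulation = FALSE} for pooled frequencies.
#'
#' @param ds a [GenotypeData-class] object.
#' @param byPopulation frequency grouping (default within population).
#' @param correction \code{"none"} (default) or \code{"sample_size"}.
#' @param freqs optional externally supplied allele-b frequencies (numeric
#'   vector aligned with \code{snpInfo(ds)}); overrides the internally
#'   estimated frequencies for every population.
#' @return data.frame (sample_id, population, n_loci, o_hom, e_hom, f_hom);
#'   \code{f_hom} is NA when the denominator is degenerate.
#' @export
inbreedingFhom <- function(ds, byPopulation = TRUE,
                           correction = c("none", "sample_size"),
                           freqs = NULL) {
    correction <- match.arg(correction)
    d <- dosages(ds)
    if (!is.null(freqs) && length(freqs) != nrow(d))
        stop("freqs must align with the dataset variants")
    pops <- if (byPopulation) populations(ds) else rep("ALL", nSamples(ds))
    out <- vector("list", length(unique(pops)))
    names(out) <- unique(pops)
    for (pp in unique(pops)) {
        sel <- pops == pp
        dp <- d[, sel, drop = FALSE]
        nObs <- rowSums(!is.na(dp))
        p <- if (is.null(freqs)) rowSums(dp, na.rm = TRUE) / (2 * pmax(nObs, 1L))
             else as.numeric(freqs)
        hetExp <- 2 * p * (1 - p)
        if (correction == "sample_size")
            hetExp <- hetExp * ifelse(nObs > 1L, nObs / (nObs - 1L), NA_real_)
        eHomPerLocus <- 1 - hetExp
        nonmiss <- !is.na(dp)
        J <- colSums(nonmiss)
        O <- colSums(dp == 0L | dp == 2L, na.rm = TRUE)
        E <- colSums(eHomPerLocus * nonmiss, na.rm = TRUE)
        denom <- J - E
        f <- ifelse(abs(denom) < 1e-12, NA_real_, (O - E) / denom)
        out[[pp]] <- data.frame(sample_id = sampleIds(ds)[sel],
                                population = populations(ds)[sel],
                                n_loci = J, o_hom = O, e_hom = E, f_hom = f,
                                stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, c(out, make.row.names = FALSE))
    res[match(sampleIds(ds), res$sample_id), , drop = FALSE]
}

#' Population summary of F_HOM
#'
#' @param fhom output of [inbreedingFhom()].
#' @return data.frame (population, n, fhom_mean, fhom_sd); SD across
#'   individuals.
#' @export
fhomSummary <- function(fhom) {
    sp <- split(fhom$f_hom, fhom$population)
    data.frame(population = names(sp),
               n = vapply(sp, function(x) sum(!is.na(x)), integer(1)),
               fhom_mean = vapply(sp, mean, numeric(1), na.rm = TRUE),
               fhom_sd = vapply(sp, sd, numeric(1), na.rm = TRUE),
               row.names = NULL, stringsAsFactors = FALSE)
}
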