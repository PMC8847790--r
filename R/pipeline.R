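# End-to-end orchestration: simulate or load genotypes, staged QC,
# diversity, structure, ROH, islands, optional annotation; TSV outputs with
# a checksummed manifest so a rerun with the same config and seed is
# verifiably identical.

.writeTsv <- function(df, dir, name) {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full analysis pipeline
#'
#' Executes the staged workflow on either PLINK input or a fresh simulation:
#' QC into the three analysis subsets, heterozygosity and F_HOM on the
#' diversity subset, PCA and (when both founder cohorts are present)
#' supervised ancestry on the structure subset, per-population ROH detection
#' with L-parameter thresholds on the ROH subset, F_ROH, incidence tracks
#' and island bins, concatenated regions with parental overlap, and -- when
#' annotation files are configured -- gene/QTL annotation of the islands.
#' Every output TSV is listed in a manifest with its MD5 checksum.
#'
#' @param config a list, or path to a JSON file, with elements:
#'   \describe{
#'     \item{input}{list(prefix, format) for PLINK input, OR}
#'     \item{simulate}{list of [simConfig()] arguments (exactly one of
#'       input/simulate must be present),}
#'     \item{qc}{optional list of [qcParams()] arguments,}
#'     \item{roh}{optional list: alpha and [rohParams()] overrides,}
#'     \item{islands}{optional list: minIncidence, fallbackIncidence,}
#'     \item{founders}{optional c(panelA, panelB) population labels for the
#'       ancestry panels (default c("DUC", "KNP")),}
#'     \item{gff3, qtl}{optional annotation file paths,}
#'     \item{outDir}{output directory (created),}
#'     \item{seed}{seed for a simulate block.}
#'   }
#' @return data.frame manifest (file, md5), invisibly; also written to
#'   \code{manifest.tsv} in \code{outDir}.
#' @export
runPipeline <- function(config) {
    if (is.character(config))
        config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (is.null(config$outDir)) stop("config$outDir is required")
    hasInput <- !is.null(config$input); hasSim <- !is.null(config$simulate)
    if (hasInput == hasSim)
        stop("exactly one of config$input and config$simulate must be given")
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    logline <- function(...) message("[rohscan] ", ...)

    genome <- sscrofaGenome()
    tracts <- NULL
    if (hasSim) {
        simArgs <- config$simulate
        if (is.null(simArgs$seed)) simArgs$seed <- config$seed
        cfg <- do.call(simConfig, simArgs)
        genome <- cfg$genome
        logline("simulating: seed ", cfg$seed, ", ", cfg$nSnps, " SNPs")
        sim <- simulateStudy(cfg)
        ds <- sim$genotypes; tracts <- sim$tracts
        truth <- ancestryTruth(tracts, genome)
        files <- c(files, .writeTsv(truth$perCohort, config$outDir,
                                    "ancestry_truth.tsv"))
    } else {
        logline("reading PLINK input: ", config$input$prefix)
        ds <- readPlink(config$input$prefix,
                        format = if (is.null(config$input$format)) "auto"
                                 else config$input$format)
    }

    qp <- do.call(qcParams, if (is.null(config$qc)) list() else config$qc)
    logline("QC: call rate >= ", qp@snpCallRateMin, ", MAF >= ", qp@mafMin,
            ", LD prune ", qp@ldWindowSnps, " ", qp@ldStepSnps, " ",
            qp@ldR2Max)
    subsets <- qcSubsets(ds, qp)
    qcTab <- data.frame(
        subset = c("roh", "diversity", "structure"),
        n_snps = c(nVariants(subsets$roh), nVariants(subsets$diversity),
                   nVariants(subsets$structure)),
        n_samples = c(nSamples(subsets$roh), nSamples(subsets$diversity),
                      nSamples(subsets$structure)))
    files <- c(files, .writeTsv(qcTab, config$outDir, "qc_subsets.tsv"))

    het <- hetStats(subsets$diversity)
    fhom <- inbreedingFhom(subsets$diversity)
    files <- c(files,
               .writeTsv(het$summary, config$outDir, "diversity_summary.tsv"),
               .writeTsv(fhom, config$outDir, "fhom.tsv"))

    pops <- unique(populations(ds))
    panels <- if (is.null(config$founders)) c("DUC", "KNP") else config$founders
    pca <- runPCA(subsets$structure, k = min(10L, nSamples(ds) - 1L),
                  orientPopulation = panels[1])
    scores <- data.frame(sample_id = rownames(pca$scores),
                         population = pca$populations, pca$scores)
    files <- c(files, .writeTsv(scores, config$outDir, "pca_scores.tsv"))
    if (all(panels %in% pops)) {
        adm <- supervisedAdmixture(subsets$structure,
                                   panelFreqs(subsets$structure, panels[1]),
                                   panelFreqs(subsets$structure, panels[2]))
        files <- c(files, .writeTsv(adm, config$outDir, "admixture_q.tsv"))
    }

    rohArgs <- if (is.null(config$roh)) list() else config$roh
    alpha <- if (is.null(rohArgs$alpha)) 0.05 else rohArgs$alpha
    rohArgs$alpha <- NULL
    segList <- list(); trackList <- list(); islList <- list()
    for (pp in pops) {
        params <- do.call(rohParamsFor,
                          c(list(ds = subsets$roh, population = pp,
                                 alpha = alpha), rohArgs))
        logline("ROH scan ", pp, ": window/min SNPs = ", params@windowSnp)
        seg <- suppressWarnings(detectRoh(subsets$roh, params,
                                          population = pp))
        segList[[pp]] <- seg
        track <- snpIncidence(seg, subsets$roh, pp)
        trackList[[pp]] <- cbind(population = pp, track)
        islArgs <- if (is.null(config$islands)) list() else config$islands
        islList[[pp]] <- do.call(rohIslands, c(list(track = track), islArgs))
    }
    segments <- do.call(rbind, c(segList, make.row.names = FALSE))
    frTab <- froh(segments, genome, sampleId = sampleIds(subsets$roh),
                  population = populations(subsets$roh))
    cls <- classifyRoh(segments)
    islands <- do.call(rbind, c(islList, make.row.names = FALSE))
    files <- c(files,
               .writeTsv(segments, config$outDir, "roh_segments.tsv"),
               .writeTsv(frTab, config$outDir, "froh.tsv"),
               .writeTsv(rohSummary(segments, frTab), config$outDir,
                         "roh_summary.tsv"),
               .writeTsv(cls$proportions, config$outDir,
                         "roh_size_classes.tsv"),
               .writeTsv(do.call(rbind, c(trackList, make.row.names = FALSE)),
                         config$outDir, "roh_incidence.tsv"),
               .writeTsv(islands, config$outDir, "roh_islands.tsv"))

    if (all(panels %in% pops)) {
        regA <- concatRegions(segments, panels[1])
        regB <- concatRegions(segments, panels[2])
        ovlRows <- list()
        for (pp in setdiff(pops, panels)) {
            ov <- parentalOverlap(concatRegions(segments, pp), regA, regB)
            ovlRows[[pp]] <- data.frame(population = pp,
                                        proportion = ov$proportion,
                                        crossbred_mb = ov$crossbred_bp / 1e6,
                                        shared_mb = ov$shared_bp / 1e6,
                                        stringsAsFactors = FALSE)
        }
        if (length(ovlRows))
            files <- c(files, .writeTsv(
                do.call(rbind, c(ovlRows, make.row.names = FALSE)),
                config$outDir, "parental_overlap.tsv"))
    }

    core <- c("chrom", "start_bp", "end_bp", "kind", "name")
    feats <- NULL
    if (!is.null(config$gff3)) feats <- readGff3(config$gff3)[, core]
    if (!is.null(config$qtl))
        feats <- rbind(feats, readQtlTable(config$qtl)[, core])
    if (!is.null(feats) && nrow(islands)) {
        ann <- annotateBins(islands, feats)
        files <- c(files,
                   .writeTsv(ann, config$outDir, "island_annotation.tsv"),
                   .writeTsv(uniqueFeatureSummary(ann), config$outDir,
                             "island_annotation_summary.tsv"))
    }

    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    .writeTsv(manifest, config$outDir, "manifest.tsv")
    logline("wrote ", nrow(manifest), " outputs to ", config$outDir)
    invisible(manifest)
}
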