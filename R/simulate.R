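# Crossbreeding simulator: two divergent founder breeds (one bottlenecked),
# random-mating burn-in, and a pedigree gene drop with recombination and
# ancestry-tract truth.  Breed divergence follows the Balding-Nichols model;
# crossovers follow Haldane (no interference, Poisson counts, uniform
# positions on a linear genetic map).

#' Simulation configuration
#'
#' Defaults state the emulated study design: 18 autosomes totalling
#' 2,262.6 Mb ([sscrofaGenome()]), 56,498 array SNPs (about one per 40 kb,
#' so the 50 kb/SNP ROH density rule is satisfiable), Balding-Nichols
#' divergence Fst = 0.25 between a diverse "DUC-like" founder breed
#' (Ne = 200) and a bottlenecked high-inbreeding "KNP-like" breed (Ne = 10,
#' echoing a nine-animal founder restoration), 20 burn-in generations of
#' random mating, cohorts DUC 100, KNP 100, F1 50, F2 100, WRH 500, a
#' uniform 1 cM/Mb genetic map, and 1\% genotype missingness.
#'
#' @param nSnps number of array SNPs.
#' @param genome a [GenomeInfo-class] object, or a named list/vector of
#'   chromosome lengths (handy for JSON configurations).
#' @param ancestralMafRange range of the uniform ancestral allele frequency.
#' @param fst Balding-Nichols divergence between the two breeds, in (0,1).
#' @param neDuc,neKnp effective sizes of the burn-in populations (>= 2).
#' @param burninGenerations generations of within-breed random mating.
#' @param cohortSizes named vector with entries DUC, KNP, F1, F2, WRH.
#' @param recombRate genetic map density in cM/Mb (0 disables crossover).
#' @param missingRate per-genotype missingness of the emitted array data.
#' @param seed mandatory integer seed; every stochastic draw flows from it.
#' @return classed list of settings (\code{"simConfig"}).
#' @export
simConfig <- function(nSnps = 56498L,
                      genome = sscrofaGenome(),
                      ancestralMafRange = c(0.05, 0.95),
                      fst = 0.25,
                      neDuc = 200L, neKnp = 10L,
                      burninGenerations = 20L,
                      cohortSizes = c(DUC = 100L, KNP = 100L, F1 = 50L,
                                      F2 = 100L, WRH = 500L),
                      recombRate = 1.0,
                      missingRate = 0.01,
                      seed) {
    if (missing(seed)) stop("seed is mandatory for reproducibility")
    if (fst <= 0 || fst >= 1) stop("fst must be in (0,1)")
    if (neDuc < 2L || neKnp < 2L) stop("effective sizes must be >= 2")
    if (any(cohortSizes < 1L)) stop("cohort sizes must be >= 1")
    cohortSizes <- unlist(cohortSizes)
    if (!is(genome, "GenomeInfo")) genome <- genomeInfo(unlist(genome))
    structure(list(nSnps = as.integer(nSnps), genome = genome,
                   ancestralMafRange = ancestralMafRange, fst = fst,
                   neDuc = as.integer(neDuc), neKnp = as.integer(neKnp),
                   burninGenerations = as.integer(burninGenerations),
                   cohortSizes = cohortSizes, recombRate = recombRate,
                   missingRate = missingRate, seed = as.integer(seed)),
              class = "simConfig")
}

# allocate SNP counts to chromosomes proportionally to length
.allocateSnps <- function(nSnps, lengths) {
    frac <- lengths / sum(lengths)
    base <- floor(nSnps * frac)
    rem <- nSnps - sum(base)
    if (rem > 0) {
        extra <- order(nSnps * frac - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
    }
    as.integer(base)
}

# one gamete from individual k of an allele-matrix pool (columns 2k-1, 2k)
.gameteFromPool <- function(M, k, pos, chromLen, morgans) {
    h1 <- M[, 2L * k - 1L]; h2 <- M[, 2L * k]
    cx <- if (morgans > 0) rpois(1L, morgans) else 0L
    phase <- sample.int(2L, 1L) - 1L
    if (cx == 0L) return(if (phase == 0L) h1 else h2)
    bp <- sort(runif(cx, 0, chromLen))
    seg <- findInterval(pos, bp)
    use2 <- (seg + phase) %% 2L == 1L
    out <- h1
    out[use2] <- h2[use2]
    out
}

# one generation of random mating inside an allele-matrix pool
.matePool <- function(pool, nOffspring, posList, lens, morgansPerChrom) {
    ne <- ncol(pool[[1]]) %/% 2L
    newPool <- lapply(seq_along(pool), function(c)
        matrix(0L, nrow(pool[[c]]), 2L * nOffspring))
    for (i in seq_len(nOffspring)) {
        par <- sample.int(ne, 2L, replace = FALSE)   # no selfing
        for (c in seq_along(pool)) {
            newPool[[c]][, 2L * i - 1L] <-
                .gameteFromPool(pool[[c]], par[1L], posList[[c]], lens[c],
                                morgansPerChrom[c])
            newPool[[c]][, 2L * i] <-
                .gameteFromPool(pool[[c]], par[2L], posList[[c]], lens[c],
                                morgansPerChrom[c])
        }
    }
    newPool
}

#' Simulate founder breed haplotype pools
#'
#' Draws an ancestral allele frequency per SNP from
#' \code{ancestralMafRange}, diverges the two breeds with the
#' Balding-Nichols beta distribution at the configured Fst, samples initial
#' haplotypes independently per SNP, and then runs
#' \code{burninGenerations} of within-breed random mating (with Haldane
#' recombination) at each breed's effective size.  The burn-in is what
#' builds up linkage disequilibrium and -- in the small-Ne breed --
#' autozygosity and long ROH.
#'
#' Seeds the RNG from \code{cfg$seed}; [geneDrop()] continues the same
#' stream, so a full run is reproduced by rerunning both with the same
#' configuration.
#'
#' @param cfg a [simConfig()] object.
#' @return list with \code{map} (variant table), \code{posList} (per-chrom
#'   positions), \code{pools} (per-breed, per-chrom haplotype matrices),
#'   \code{freqs} (ancestral and per-breed allele frequencies) and
#'   \code{cfg}.
#' @export
simulateFounders <- function(cfg) {
    stopifnot(inherits(cfg, "simConfig"))
    set.seed(cfg$seed)
    lens <- chromLengths(cfg$genome)
    chroms <- names(lens)
    counts <- .allocateSnps(cfg$nSnps, lens)
    posList <- lapply(seq_along(lens), function(c)
        sort(sample.int(lens[c], counts[c])))
    names(posList) <- chroms

    nucs <- c("A", "C", "G", "T")
    m <- sum(counts)
    pair <- t(vapply(seq_len(m), function(i) sort(sample(nucs, 2L)),
                     character(2)))
    map <- data.frame(
        snp_id = sprintf("snp_%s_%d", rep(chroms, counts), unlist(posList)),
        chrom = rep(chroms, counts),
        pos = unlist(posList),
        allele_a = pair[, 1L], allele_b = pair[, 2L],
        stringsAsFactors = FALSE)

    pAnc <- runif(m, cfg$ancestralMafRange[1], cfg$ancestralMafRange[2])
    shape <- (1 - cfg$fst) / cfg$fst
    pDuc <- rbeta(m, pAnc * shape, (1 - pAnc) * shape)
    pKnp <- rbeta(m, pAnc * shape, (1 - pAnc) * shape)

    morgans <- lens * cfg$recombRate / 1e8
    offs <- c(0L, cumsum(counts))
    makePool <- function(p, ne) {
        lapply(seq_along(lens), function(c) {
            idx <- (offs[c] + 1L):offs[c + 1L]
            matrix(rbinom(counts[c] * 2L * ne, 1L, p[idx]),
                   nrow = counts[c], ncol = 2L * ne)
        })
    }
    poolDuc <- makePool(pDuc, cfg$neDuc)
    poolKnp <- makePool(pKnp, cfg$neKnp)
    for (g in seq_len(cfg$burninGenerations)) {
        poolDuc <- .matePool(poolDuc, cfg$neDuc, posList, lens, morgans)
        poolKnp <- .matePool(poolKnp, cfg$neKnp, posList, lens, morgans)
    }
    list(map = map, posList = posList,
         pools = list(DUC = poolDuc, KNP = poolKnp),
         freqs = data.frame(snp_id = map$snp_id, p_anc = pAnc,
                            p_duc = pDuc, p_knp = pKnp,
                            stringsAsFactors = FALSE),
         cfg = cfg)
}

#' Default crossing scheme
#'
#' F1 = DUC x KNP; F2 = F1 x DUC; WRH = F1 x F2.  Founder cohorts have NA
#' parents.  Every non-founder cohort's parents appear earlier in the
#' table.
#'
#' @return data.frame (cohort, parent1, parent2).
#' @export
defaultPedigree <- function() {
    data.frame(cohort = c("DUC", "KNP", "F1", "F2", "WRH"),
               parent1 = c(NA, NA, "DUC", "F1", "F1"),
               parent2 = c(NA, NA, "KNP", "DUC", "F2"),
               stringsAsFactors = FALSE)
}

# individual representation: list(al = list of 2 x (per-chrom allele vector),
# tr = list of 2 x (per-chrom tract matrix [start, end, breedCode]))
.founderIndividual <- function(pool, k, nChrom, lens, breedCode) {
    al <- lapply(1:2, function(h)
        lapply(seq_len(nChrom), function(c) pool[[c]][, 2L * k - 2L + h]))
    tr <- lapply(1:2, function(h)
        lapply(seq_len(nChrom), function(c)
            matrix(c(1, lens[c], breedCode), nrow = 1)))
    list(al = al, tr = tr)
}

.mergeTracts <- function(tr) {
    if (nrow(tr) <= 1L) return(tr)
    keep <- c(TRUE, tr[-1L, 3L] != tr[-nrow(tr), 3L])
    grp <- cumsum(keep)
    starts <- tr[keep, 1L]
    ends <- tapply(tr[, 2L], grp, max)
    breeds <- tr[keep, 3L]
    cbind(starts, as.numeric(ends), breeds, deparse.level = 0)
}

# meiosis of one parent: returns list(al = per-chrom alleles, tr = tracts)
.meiosis <- function(parent, posList, lens, morgans) {
    nChrom <- length(posList)
    alOut <- vector("list", nChrom); trOut <- vector("list", nChrom)
    for (c in seq_len(nChrom)) {
        cx <- if (morgans[c] > 0) rpois(1L, morgans[c]) else 0L
        phase <- sample.int(2L, 1L) - 1L
        if (cx == 0L) {
            h <- phase + 1L
            alOut[[c]] <- parent$al[[h]][[c]]
            trOut[[c]] <- parent$tr[[h]][[c]]
            next
        }
        bp <- sort(runif(cx, 0, lens[c]))
        pos <- posList[[c]]
        seg <- findInterval(pos, bp)
        use2 <- (seg + phase) %% 2L == 1L
        al <- parent$al[[1L]][[c]]
        al[use2] <- parent$al[[2L]][[c]][use2]
        alOut[[c]] <- al
        bounds <- c(0, bp, lens[c])
        pieces <- vector("list", cx + 1L)
        for (s in seq_len(cx + 1L)) {
            h <- ((s - 1L + phase) %% 2L) + 1L
            lo <- floor(bounds[s]) + 1
            hi <- floor(bounds[s + 1L])
            if (s == cx + 1L) hi <- lens[c]
            if (lo > hi) { pieces[[s]] <- NULL; next }
            tr <- parent$tr[[h]][[c]]
            sel <- tr[, 2L] >= lo & tr[, 1L] <= hi
            tr <- tr[sel, , drop = FALSE]
            if (nrow(tr)) {
                tr[1L, 1L] <- max(tr[1L, 1L], lo)
                tr[nrow(tr), 2L] <- min(tr[nrow(tr), 2L], hi)
                tr[, 1L] <- pmax(tr[, 1L], lo)
                tr[, 2L] <- pmin(tr[, 2L], hi)
            }
            pieces[[s]] <- tr
        }
        trOut[[c]] <- .mergeTracts(do.call(rbind, pieces))
    }
    list(al = alOut, tr = trOut)
}

#' Gene-drop the crossing scheme
#'
#' Builds every cohort of the pedigree: founder cohorts are bred from their
#' burn-in pools (one more round of random mating, no selfing), non-founder
#' cohorts draw one parent from each parental cohort, and each offspring
#' haplotype is a recombinant of its parent's two haplotypes (Poisson
#' crossover counts on the genetic map, uniform positions).  Founder-breed
#' ancestry tracts are propagated segment-by-segment and tile every
#' haplotype exactly.
#'
#' Continues the RNG stream started by [simulateFounders()]; do not reseed
#' between the two calls.
#'
#' @param founders output of [simulateFounders()].
#' @param pedigree crossing scheme (default [defaultPedigree()]); a rule
#'   naming an unknown cohort is an error.
#' @return list with \code{genotypes} (a [GenotypeData-class] with
#'   population labels, missingness applied) and \code{tracts}
#'   (data.frame: sample_id, population, haplotype, chrom, start_bp,
#'   end_bp, breed).
#' @export
geneDrop <- function(founders, pedigree = defaultPedigree()) {
    cfg <- founders$cfg
    lens <- chromLengths(cfg$genome)
    chroms <- names(lens)
    nChrom <- length(lens)
    posList <- founders$posList
    morgans <- lens * cfg$recombRate / 1e8
    breedCode <- c(DUC = 1, KNP = 2)

    cohorts <- list()
    for (r in seq_len(nrow(pedigree))) {
        cname <- pedigree$cohort[r]
        size <- cfg$cohortSizes[[cname]]
        if (is.null(size))
            stop("no cohort size configured for ", cname)
        p1 <- pedigree$parent1[r]; p2 <- pedigree$parent2[r]
        if (is.na(p1) && is.na(p2)) {
            if (!cname %in% names(founders$pools))
                stop("no founder pool for cohort ", cname)
            pool <- founders$pools[[cname]]
            ne <- ncol(pool[[1]]) %/% 2L
            bred <- .matePool(pool, size, posList, lens, morgans)
            cohorts[[cname]] <- lapply(seq_len(size), function(k)
                .founderIndividual(bred, k, nChrom, lens, breedCode[[cname]]))
        } else {
            for (p in c(p1, p2))
                if (!p %in% names(cohorts))
                    stop("crossing rule references unknown cohort ", p)
            cohorts[[cname]] <- lapply(seq_len(size), function(k) {
                if (p1 == p2) {
                    ij <- sample.int(length(cohorts[[p1]]), 2L)
                    momdad <- list(cohorts[[p1]][[ij[1]]],
                                   cohorts[[p1]][[ij[2]]])
                } else {
                    momdad <- list(
                        cohorts[[p1]][[sample.int(length(cohorts[[p1]]), 1L)]],
                        cohorts[[p2]][[sample.int(length(cohorts[[p2]]), 1L)]])
                }
                g1 <- .meiosis(momdad[[1]], posList, lens, morgans)
                g2 <- .meiosis(momdad[[2]], posList, lens, morgans)
                list(al = list(g1$al, g2$al), tr = list(g1$tr, g2$tr))
            })
        }
    }

    # assemble genotype matrix and tract table (flat vectors, no rbind)
    allIds <- character(0); allPops <- character(0)
    m <- nrow(founders$map)
    nTot <- sum(vapply(cohorts, length, integer(1)))
    dosage <- matrix(NA_integer_, m, nTot)
    tId <- list(); tPop <- list(); tHap <- list(); tChr <- list()
    tStart <- list(); tEnd <- list(); tBreed <- list()
    ti <- 0L; col <- 0L
    breedName <- c("DUC", "KNP")
    for (cname in names(cohorts)) {
        for (k in seq_along(cohorts[[cname]])) {
            col <- col + 1L
            id <- sprintf("%s_%03d", cname, k)
            allIds <- c(allIds, id); allPops <- c(allPops, cname)
            ind <- cohorts[[cname]][[k]]
            dosage[, col] <- unlist(lapply(seq_len(nChrom), function(c)
                ind$al[[1L]][[c]] + ind$al[[2L]][[c]]), use.names = FALSE)
            for (h in 1:2) for (c in seq_len(nChrom)) {
                tr <- ind$tr[[h]][[c]]
                ti <- ti + 1L
                nr <- nrow(tr)
                tId[[ti]] <- rep(id, nr); tPop[[ti]] <- rep(cname, nr)
                tHap[[ti]] <- rep(h, nr); tChr[[ti]] <- rep(chroms[c], nr)
                tStart[[ti]] <- tr[, 1L]; tEnd[[ti]] <- tr[, 2L]
                tBreed[[ti]] <- breedName[tr[, 3L]]
            }
        }
    }
    tracts <- data.frame(
        sample_id = unlist(tId), population = unlist(tPop),
        haplotype = unlist(tHap), chrom = unlist(tChr),
        start_bp = unlist(tStart), end_bp = unlist(tEnd),
        breed = unlist(tBreed), stringsAsFactors = FALSE)
    if (cfg$missingRate > 0) {
        nm <- rbinom(1L, length(dosage), cfg$missingRate)
        if (nm > 0)
            dosage[sample.int(length(dosage), nm)] <- NA_integer_
    }
    ds <- genotypeData(dosage, founders$map, sampleId = allIds,
                       population = allPops)
    list(genotypes = ds, tracts = tracts)
}

#' Expected cohort-level breed ancestry from the pedigree
#'
#' Pedigree-expectation recursion: a founder cohort contributes 1 to its own
#' breed and 0 to the other; every non-founder cohort's expectation is the
#' mean of its parents'.  For the default scheme the composite (WRH)
#' expectation is 0.625 DUC and 0.375 KNP.
#'
#' @param pedigree crossing scheme (default [defaultPedigree()]).
#' @param breed founder breed name (a founder cohort label).
#' @param cohort cohort to evaluate (default: last row of the pedigree).
#' @return expected ancestry fraction in [0,1].
#' @examples
#' expectedAncestry(breed = "DUC")  # 0.625
#' expectedAncestry(breed = "KNP")  # 0.375
#' @export
expectedAncestry <- function(pedigree = defaultPedigree(), breed,
                             cohort = pedigree$cohort[nrow(pedigree)]) {
    memo <- new.env(parent = emptyenv())
    visiting <- character(0)
    rec <- function(cn) {
        if (cn %in% visiting) stop("pedigree contains a cycle at ", cn)
        if (!is.null(memo[[cn]])) return(memo[[cn]])
        r <- match(cn, pedigree$cohort)
        if (is.na(r)) stop("unknown cohort ", cn)
        p1 <- pedigree$parent1[r]; p2 <- pedigree$parent2[r]
        val <- if (is.na(p1) && is.na(p2)) {
            as.numeric(cn == breed)
        } else {
            visiting <<- c(visiting, cn)
            v <- (rec(p1) + rec(p2)) / 2
            visiting <<- setdiff(visiting, cn)
            v
        }
        memo[[cn]] <- val
        val
    }
    rec(cohort)
}

#' Realized ancestry fractions from tract truth
#'
#' @param tracts tract table from [geneDrop()].
#' @param genome the [GenomeInfo-class] used in the simulation.
#' @return list with \code{perSample} (sample_id, population, frac_DUC,
#'   frac_KNP) and \code{perCohort} (population, n, mean_frac_DUC,
#'   mean_frac_KNP).  Fractions are tract length over the diploid genome
#'   length and sum to 1 per sample.
#' @export
ancestryTruth <- function(tracts, genome) {
    total <- 2 * totalAutosomeLength(genome)
    len <- tracts$end_bp - tracts$start_bp + 1
    ag <- tapply(len, list(tracts$sample_id, tracts$breed), sum, default = 0)
    frac <- ag / total
    perSample <- data.frame(
        sample_id = rownames(frac),
        population = tracts$population[match(rownames(frac),
                                             tracts$sample_id)],
        frac_DUC = if ("DUC" %in% colnames(frac)) frac[, "DUC"] else 0,
        frac_KNP = if ("KNP" %in% colnames(frac)) frac[, "KNP"] else 0,
        row.names = NULL, stringsAsFactors = FALSE)
    sp <- split(perSample, perSample$population)
    perCohort <- do.call(rbind, lapply(sp, function(x)
        data.frame(population = x$population[1], n = nrow(x),
                   mean_frac_DUC = mean(x$frac_DUC),
                   mean_frac_KNP = mean(x$frac_KNP),
                   stringsAsFactors = FALSE)))
    rownames(perCohort) <- NULL
    list(perSample = perSample, perCohort = perCohort)
}

#' Audit ancestry-tract tiling
#'
#' Checks that the tracts of every haplotype tile its chromosome exactly:
#' start at 1, end at the chromosome length, no gaps, no overlaps.
#'
#' @param tracts tract table from [geneDrop()].
#' @param genome the [GenomeInfo-class] used in the simulation.
#' @return TRUE invisibly, or an error describing the first violation.
#' @export
validateTracts <- function(tracts, genome) {
    lens <- chromLengths(genome)
    sp <- split(tracts, list(tracts$sample_id, tracts$haplotype,
                             tracts$chrom), drop = TRUE)
    for (tr in sp) {
        tr <- tr[order(tr$start_bp), , drop = FALSE]
        L <- lens[[as.character(tr$chrom[1])]]
        if (tr$start_bp[1] != 1 || tr$end_bp[nrow(tr)] != L ||
            (nrow(tr) > 1 && any(tr$start_bp[-1] != tr$end_bp[-nrow(tr)] + 1)))
            stop("tract tiling violated for ", tr$sample_id[1], " hap ",
                 tr$haplotype[1], " chrom ", tr$chrom[1])
    }
    invisible(TRUE)
}

#' Run the full simulation
#'
#' Convenience wrapper: seeds once, simulates founder pools, gene-drops the
#' pedigree, and returns genotypes plus tract truth.
#'
#' @param cfg a [simConfig()] object.
#' @param pedigree crossing scheme (default [defaultPedigree()]).
#' @return list(\code{genotypes}, \code{tracts}, \code{founders},
#'   \code{cfg}).
#' @export
simulateStudy <- function(cfg, pedigree = defaultPedigree()) {
    founders <- simulateFounders(cfg)
    gd <- geneDrop(founders, pedigree)
    list(genotypes = gd$genotypes, tracts = gd$tracts,
         founders = founders[c("map", "freqs")], cfg = cfg)
}
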