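# rohscan

Genome-wide assessment of composite (synthetic) livestock breeds from
SNP-array genotypes, in R.

Composite breeds are formed by planned crossing of founder breeds — for
example a composite pig line bred as `WRH = F1 × F2` with `F1 = DUC × KNP`
and `F2 = F1 × DUC`, where one founder (DUC-like) is a diverse commercial
line and the other (KNP-like) a small conserved native breed restored from
a handful of animals.  Breeders and conservation geneticists working with
such populations need to know how much genome each founder actually
contributed, how much diversity the cross recovered, and where the genome
is still locked in long homozygous stretches.  `rohscan` covers that
workflow end to end:

* **I/O and QC** — PLINK text (`.ped/.map`) and binary (`.bed/.bim/.fam`)
  reading/writing, manifest-style coordinate remaps, and the standard
  staged QC that produces three analysis subsets: call-rate-only (for
  ROH), + MAF (for diversity), + LD pruning (for structure).
* **Diversity and inbreeding** — per-SNP and per-population H<sub>O</sub>
  and H<sub>E</sub> = 2p(1−p); the homozygosity-excess coefficient
  F<sub>HOM</sub> = (O − E)/(J − E) with
  E = Σ<sub>j</sub>(1 − 2p<sub>j</sub>(1−p<sub>j</sub>)); and the
  ROH-based coefficient
  F<sub>ROH</sub> = L<sub>ROH</sub>/L<sub>autosomes</sub>.
* **Structure** — genotype PCA (Patterson standardization) and a
  supervised two-way ancestry estimator: per sample, the fraction *q* of
  genome from founder panel A maximizing
  Σ<sub>j</sub> log Binom(g<sub>j</sub> | 2, q·p<sub>Aj</sub> + (1−q)·p<sub>Bj</sub>)
  by EM.
* **ROH** — PLINK-`--homozyg`-style sliding-window detection with the
  L-parameter threshold
  L = ⌈ln(α/(n<sub>SNPs</sub>·n<sub>ind</sub>))/ln(1 − het)⌉ applied per
  population; size classes (1–3, 3–10, >10 Mb); per-SNP incidence
  z-scores; 1-Mb ROH-island bins (percentile > 0.999 ∧ incidence ≥ 30%,
  with an 80%-incidence fallback for highly inbred populations);
  concatenated ROH regions (≥ 1 bp overlap merges) and the parental origin
  of crossbred ROH.
* **Annotation** — gene (GFF3) and QTL (BED-like TSV) overlap with island
  bins.
* **Simulation** — a Balding–Nichols + gene-drop generator with Haldane
  recombination and per-haplotype ancestry-tract truth, emulating the
  two-founder crossing scheme, so every stage is testable without
  external data.

## Worked example

A miniature world (4 chromosomes × 20 Mb, 2,000 SNPs) with the default
crossing scheme:

```r
library(rohscan)
genome <- genomeInfo(setNames(rep(20e6, 4), as.character(1:4)))
cfg <- simConfig(nSnps = 2000, genome = genome,
                 cohortSizes = c(DUC = 30, KNP = 30, F1 = 15, F2 = 30, WRH = 60),
                 neDuc = 50, neKnp = 6, burninGenerations = 10, seed = 42)
sim <- simulateStudy(cfg)
sim$genotypes
#> GenotypeData: 2000 variants x 165 samples
#>   populations: DUC (30), F1 (15), F2 (30), KNP (30), WRH (60)
#>   chromosomes: 1, 2, 3, 4
```

The tract truth shows the pedigree arithmetic at work — every F1 genome is
exactly half-and-half, and the composite cohort scatters around the
expected 62.5% DUC / 37.5% KNP:

```r
ancestryTruth(sim$tracts, genome)$perCohort
#>   population  n mean_frac_DUC mean_frac_KNP
#> 1        DUC 30     1.0000000     0.0000000
#> 2         F1 15     0.5000000     0.5000000
#> 3         F2 30     0.7475104     0.2524896
#> 4        KNP 30     0.0000000     1.0000000
#> 5        WRH 60     0.6499677     0.3500323
expectedAncestry(breed = "DUC")   # 0.625
```

Diversity on the MAF-filtered subset reproduces the expected pattern: the
bottlenecked KNP-like founder has by far the lowest heterozygosity, the
crossbreds the highest:

```r
sub <- qcSubsets(sim$genotypes)
hetStats(sub$diversity)$summary
#>   population n_snps n_excluded   ho_mean     ho_sd   he_mean     he_sd
#> 1        DUC   1511          0 0.3320126 0.1851647 0.3169304 0.1658624
#> 2        KNP   1511          0 0.1625789 0.2044560 0.1568103 0.1981786
#> 3         F1   1511          0 0.4773449 0.2549804 0.3517974 0.1370637
#> 4         F2   1511          0 0.3936538 0.1562084 0.3618499 0.1231576
#> 5        WRH   1511          0 0.3700016 0.1386701 0.3644497 0.1264237
```

ROH detection runs on the call-rate-only subset with the population's own
L-parameter; the small-Ne founder is heavily autozygous:

```r
params <- rohParamsFor(sub$roh, population = "KNP")
params
#> ROHParams: window 106 SNPs, min 106 SNPs, 1000 kb min length, 50 kb/SNP max density, 1000 kb max gap
#>   window: <= 0 het, <= 1 missing; hit threshold 0.05
seg <- detectRoh(sub$roh, params, population = "KNP")
fr <- froh(seg, genome,
           sampleId = sampleIds(sub$roh)[populations(sub$roh) == "KNP"])
round(mean(fr$f_roh), 3)
#> [1] 0.428
```

`runPipeline(config)` chains all stages (simulate-or-load → QC →
diversity → PCA/ancestry → ROH → islands → regions → annotation) and
writes TSV outputs with an MD5-checksummed manifest; rerunning the same
JSON config and seed reproduces identical checksums.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the expected
founder-genome composition of the composite cohort: the
pedigree-expectation recursion over the crossing scheme, cross-checked
against the mean realized ancestry-tract fraction of a seeded default
gene-drop simulation (500 composite animals), and writes both breed
percentages as JSON.

## Package layout

| area | entry points |
|------|--------------|
| I/O | `readPlink`, `writePlink`, `updateCoordinates` |
| QC | `qcParams`, `filterCallRate`, `filterMaf`, `ldPrune`, `qcSubsets` |
| diversity | `hetStats`, `inbreedingFhom`, `fhomSummary` |
| structure | `runPCA`, `panelFreqs`, `supervisedAdmixture` |
| ROH | `lParam`, `rohParams`, `rohParamsFor`, `detectRoh`, `classifyRoh`, `froh`, `rohSummary` |
| islands/intervals | `snpIncidence`, `rohIslands`, `concatRegions`, `parentalOverlap`, `intervalLength` |
| annotation | `readGff3`, `readQtlTable`, `annotateBins`, `uniqueFeatureSummary` |
| simulation | `simConfig`, `simulateFounders`, `geneDrop`, `simulateStudy`, `defaultPedigree`, `expectedAncestry`, `ancestryTruth`, `validateTracts` |
| orchestration | `runPipeline` |

The methods vignette (`vignettes/rohscan-methods.Rmd`) documents the
models, parameter defaults, the simulator's stated world and its
limitations, and the numerical choices.
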