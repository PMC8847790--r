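---
title: "Methods: ROH, inbreeding and ancestry in composite breeds with rohscan"
author: "rohscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH, inbreeding and ancestry in composite breeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`rohscan` implements the desk workflow for the genome-wide assessment of a
composite (synthetic) livestock breed genotyped on a medium-density SNP
array: a composite pig line
formed as WRH = F1 x F2 with F1 = DUC x KNP and F2 = F1 x DUC, where one
founder breed (DUC-like) is a diverse commercial line and the other
(KNP-like) a small, bottlenecked conserved population.  The package
answers three families of questions:

1. **Diversity and inbreeding.** Observed/expected heterozygosity per SNP
   and population; the homozygosity-excess inbreeding coefficient
   $F_{HOM} = (O - E)/(J - E)$ with $O$ the observed homozygous loci, $J$
   the non-missing loci and $E = \sum_j (1 - 2p_j(1-p_j))$; and the
   ROH-based coefficient $F_{ROH} = L_{ROH}/L_{autosomes}$.
2. **Structure.** PCA of standardized genotypes and a supervised two-way
   ancestry estimator (the K = 2 admixture question posed against two
   known founder panels).
3. **ROH.** Sliding-window detection, size-class spectra, incidence
   z-scores, 1-Mb island bins, concatenated regions, and the parental
   origin of crossbred ROH.

A gene-drop simulator provides ancestry-truth synthetic data so every
stage can be verified without external downloads.

# The data container

`GenotypeData` extends `RangedSummarizedExperiment`: variants are rows
(single-bp `GRanges`), samples are columns, and the `dosage` assay counts
copies of `allele_b` (0/1/2, `NA` missing).  Coordinates are 1-based
inclusive bp throughout — PLINK convention — and all interval algebra
downstream (islands, concatenated regions, overlap) uses 1-based closed
intervals.  `allele_b` is the counted allele and is orientation-stable
through round-trips; the package never re-polarizes by frequency.

The PLINK binary layout stores both alleles and round-trips exactly.  The
text `.ped` layout does not store allele identities, so a SNP with only one
observed allele cannot recover the other: the text reader orients alleles
alphabetically and leaves `allele_b = "0"` for monomorphic SNPs.  The
simulator emits alphabetically ordered allele pairs, so simulator datasets
round-trip exactly through both layouts once monomorphic SNPs are removed.

# Staged quality control

Three subsets reproduce the usual array-study design:

| subset     | filters                                   | consumer        |
|------------|-------------------------------------------|-----------------|
| roh        | non-autosomal/unmapped, call rate >= 90%  | ROH detection   |
| diversity  | + MAF >= 0.05                              | H_O, H_E, F_HOM |
| structure  | + LD pruning (50-SNP window, step 5, r² <= 0.5) | PCA, ancestry |

Decisions a practitioner should know:

* Call-rate and MAF rules are strict "less than": a SNP at exactly the
  threshold is retained.  Samples are filtered after SNPs, on the
  surviving SNPs.
* MAF is computed pooled over all populations (the study design QCs once,
  then splits); monomorphic SNPs are always removed at the MAF step.
* LD r² is the squared Pearson correlation of dosage vectors over samples
  non-missing for both SNPs (composite LD — the standard choice for
  unphased array data).  When a pair violates the threshold the member
  with the smaller MAF is removed, ties broken toward the later map
  position.  PLINK's internal pair decision is undocumented; a
  deterministic rule matters more here than bug-compatibility.
* Pruning windows are re-laid over the *surviving* SNPs and passes repeat
  until a fixpoint.  A single sweep (PLINK's behaviour) can leave
  violating pairs that only become window-mates after their neighbours
  are removed; the fixpoint guarantees the pruned set re-scans clean,
  which is also what makes the operation idempotent.

# F_HOM details

The default follows the plain formula (no small-sample correction);
`correction = "sample_size"` multiplies the per-locus heterozygosity by
$N_j/(N_j-1)$, which is what PLINK `--het` does.  Frequencies default to
within-population (per-population tables are the usual report) and can be
overridden (`byPopulation = FALSE`, or an explicit `freqs` vector).  Note
that within-population frequencies absorb population structure: on a mixed
cohort the correlation between $F_{HOM}$ and $F_{ROH}$ is high only when
$F_{HOM}$ is computed against pooled frequencies, and that is how the
package's acceptance checks compute it.  A degenerate denominator
($J = E$, e.g. all supplied frequencies 0 or 1) yields `NA`.

# PCA and supervised ancestry

PCA standardizes each SNP at $2\hat p$ and $\sqrt{2\hat p(1-\hat p)}$,
imputes missing genotypes to the SNP mean (zero after centering), drops
monomorphic SNPs with a warning, and reports eigenvalue/trace as the
explained fraction.  Sign is arbitrary in any eigendecomposition; each PC
is optionally oriented so a chosen reference cohort has negative mean
score, making plots reproducible.

The ancestry estimator deliberately departs from unsupervised ADMIXTURE:
the biological question is "how much of each genome comes from the two
known founder breeds", so the founder allele-frequency panels are held
fixed and only the per-sample proportion $q$ is estimated, by EM on
$\sum_j \log \mathrm{Binom}(g_j \mid 2,\, q p_{Aj} + (1-q) p_{Bj})$.  This
keeps the estimator convex in $q$, exactly testable (EM log-likelihood is
non-decreasing; swapping panels maps $q \mapsto 1-q$ exactly), and free of
label-switching.  Numeric parity with unsupervised ADMIXTURE's $q$ values
is explicitly not a goal.  Panel frequencies are clamped to
$[10^{-6}, 1-10^{-6}]$ so fixed loci cannot produce infinite
log-likelihoods.

# ROH detection

Detection mirrors PLINK `--homozyg`: windows of `windowSnp` consecutive
SNPs are scored homozygous when they contain at most `windowHetMax` (0)
heterozygous and `windowMissingMax` (1) missing calls; each SNP's hit rate
is the fraction of windows covering it that are homozygous, with the
denominator at chromosome edges being the windows that actually cover the
SNP (PLINK 1.9 behaviour); SNPs at hit rate >= 0.05 are "in run".  Maximal
in-run stretches are split at heterozygous calls and at gaps > 1,000 kb,
trimmed so both endpoints are genotyped SNPs, and kept when they have at
least `minSnp` SNPs, at least 1 Mb length, and an average spacing of at
most 50 kb/SNP.  Segment length is `end - start + 1` on 1-based closed
coordinates; PLINK's kb rounding is not replicated.  Only
`segmentHetMax = 0` is supported (a heterozygous call always splits); the
slot exists so the parameterization is explicit.

`windowSnp` and `minSnp` both default to the **L-parameter**
$L = \lceil \ln(\alpha/(n_{snps} n_{ind})) / \ln(1 - het) \rceil$,
computed per population from its own SNP count, cohort size and mean
heterozygosity (`rohParamsFor()`).  The ROH scan runs on the
call-rate-only subset: MAF and LD filters distort ROH discovery.

Size classes follow the results convention: short [1, 3) Mb, medium
[3, 10] Mb, long (10, ∞) Mb.  (A methods-section variant "3 to <5 Mb"
exists in the source literature of this analysis style; the results/figure
scheme is the one used, and the choice is deliberate, not silent.)

# Incidence, islands, parental overlap

For a population of size $n$, a SNP's incidence is the fraction of
individuals whose ROH cover it (per-individual segments are asserted
disjoint, so counting segments equals counting individuals).  A z-score
over the population's own incidence distribution is converted to its
normal percentile `prob = pnorm(z)`; island-qualifying SNPs are those with
`prob > 0.999` **and** incidence >= 30%.  When no SNP passes the
percentile rule — typical for a highly inbred population whose incidence
track is high and flat (sd ≈ 0 makes z undefined) — the fallback rule
qualifies SNPs with incidence >= 80%.  Qualifying SNPs are grouped into
1-Mb bins $[k \cdot 10^6 + 1, (k+1) \cdot 10^6]$; each non-empty bin is
one island, and adjacent bins are *not* merged (islands are counted as
1-Mb bins; a merged view is available via `concatRegions()` on the bins if
wanted).

Concatenated ROH regions are the union of a population's segments merging
only genuine overlaps (>= 1 bp); bookended segments stay separate.  The
parental-overlap report intersects the two founder populations'
concatenated regions and measures what fraction of a crossbred
population's concatenated ROH falls inside that shared region.
GenomicRanges provides the interval engine (`reduce(min.gapwidth = 0)`,
`intersect`); tests check it against per-bp bitmap oracles.

# The simulator: a stated world

The generator emulates the study design rather than tuning toward any
published number:

* 18 autosomes proportioned like the pig autosomes and scaled to a total
  of 2,262.6 Mb — the SNP-covered autosomal length that also serves as the
  $F_{ROH}$ denominator;
* 56,498 SNPs placed uniformly (≈ one per 40 kb, the density of a 60K
  array after call-rate QC, and comfortably inside the 50 kb/SNP ROH
  density rule);
* ancestral allele frequencies U(0.05, 0.95), Balding–Nichols divergence
  with Fst = 0.25 between the founder breeds — a strong but realistic
  divergence for a commercial line versus an isolated native breed;
* burn-in: 20 generations of random mating at Ne = 200 (DUC-like) and
  Ne = 10 (KNP-like; the conserved breed was restored from nine founders,
  and a two-digit Ne is what produces its observed F_ROH ≈ 0.4);
* cohorts DUC 100, KNP 100, F1 50, F2 100, WRH 500.  WRH = 500 gives the
  ancestry-recovery check a small enough standard error (≈ 0.3
  percentage points); the other cohorts are desk-scaled versions of the
  real 1,029/208/11/144/632 design — F1 in particular is enlarged from 11
  so that crossbred ROH statistics are not dominated by sampling noise;
* Haldane crossovers (Poisson counts on a uniform 1 cM/Mb map, uniform
  positions, no interference) — the standard neutral choice;
* 1% genotype missingness, uniformly at random.

Parent pairs are drawn without selfing; monogamy is not enforced.  A
single mandatory seed drives every draw: `simulateFounders()` seeds the
stream and `geneDrop()` continues it.

What the generator does *not* emulate: real LD and recombination-map
heterogeneity, genotyping error and batch effects, selection, mutation,
sex chromosomes, overlapping generations, and the actual multi-year
breeding timeline.  A green qualitative test therefore establishes that
the *methods* behave as the theory predicts on data with the stated
demographic structure — not that the simulator reproduces the real
populations' numeric values.  Quantities tied to real-data specifics
(absolute segment counts per animal, the exact number of islands) are out
of reach by construction and are not asserted.

# Numerical and degenerate-input choices

* Incidence sd = 0 → z undefined → percentile rule selects nothing →
  fallback-80 path (never a division-by-zero).
* `snpIncidence` on an empty population errors; an empty crossbred
  interval set gives a `NA` overlap proportion rather than 0/0.
* A chromosome with fewer SNPs than one window is skipped with a warning.
* LD windows with fewer than two surviving SNPs are no-ops.
* `lParam` requires heterozygosity strictly inside (0, 1); the result is
  floored at 1.
* EM convergence is |Δq| < 1e-6, capped at 1000 iterations; the final
  log-likelihood is recomputed at the accepted q.
* Unmapped SNPs after a coordinate remap keep their old coordinates but
  are flagged, and the QC stage removes them — they are never silently
  dropped at read time.

# Known limitations

* The text `.ped` round-trip limitation for monomorphic SNPs described
  above.
* `segmentHetMax > 0` is not implemented.
* The LD pruner is deterministic but not bit-compatible with PLINK's
  undocumented pair choice; pruned-set sizes are comparable, memberships
  can differ.
* Islands at the very start of a chromosome can sit in a bin whose last
  megabase extends past the chromosome end; bins are genomic grid units,
  not clipped intervals.
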