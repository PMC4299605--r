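---
title: "segqtl: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{segqtl: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`segqtl` analyses a haploid two-parent cross in which the segregants are
genotyped from their own RNA-seq reads and every transcript (sense and
antisense) and growth parameter is a mappable quantitative trait. This
vignette explains the models behind each stage, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was open.

## 1. Genotyping from expressed variants

Parental origin is inferred per polymorphic site per strain by matching
the called allele to the parent carrying it. Three rules guard the calls:

* heterozygous calls are impossible in haploids and are set to unknown;
* calls with genotype quality below `min_quality = 20` are unknown (the
  usual working threshold for genotype-quality scores);
* a site is discarded when it *both* fails the parental consistency check
  *and* has minor allele frequency below 10%. The rule is a conjunction
  by default; `filter_sites(rule = "or")` gives the stricter disjunctive
  reading, since either interpretation is defensible.

Because variants are observable only where their host gene is expressed,
roughly half of the site-by-strain entries are missing. Two repair steps
exploit the large haplotype blocks left by meiosis:

* **Isolated-discordance correction** — a called site that disagrees with
  both flanking called sites, which agree with each other and lie less
  than `max_flank_distance = 50000` bp apart, is overwritten with the
  flank label. Decisions are taken against the original matrix in a
  single left-to-right pass; cascading re-evaluation is deliberately
  disabled so one correction can never license another.
* **Imputation** — an unknown entry is filled with the shared label of
  its nearest called flanks when they agree and are < 50 kb apart
  (assuming no double recombination inside the window). Entire unknown
  runs are filled per-entry under the same rule; `single_only = TRUE`
  restricts filling to isolated unknowns. The flank distance is measured
  *between the two flanking sites*, not focal-to-flank.

Sites called in fewer than half of the strains are then dropped and
maximal runs of adjacent sites with identical segregation vectors —
including the positions of their unknowns — collapse into one marker, so
each marker is a genomic interval in full linkage disequilibrium in the
cross. Unknown patterns must match exactly for two sites to collapse:
"same segregation pattern across all segregants" is taken literally over
the three-symbol alphabet {P1, P2, unknown}.

Replicate RNA-seq runs of one strain are compared by pairwise concordance
over co-called sites; below `concordance_min = 0.9` (no threshold is
standard, so a value far above the ~0.96 expected from a 2% call-error
rate but far below chance was chosen) all replicates of the strain are
flagged as a probable sample swap.

## 2. Strain-specific coordinates and quantification

Indels shift all downstream coordinates, so per-strain annotation is
produced by accumulating indel length deltas into an offset map
(`personalize_genome()`). The liftover is monotone within a chromosome
and round-trips exactly for every position not inside a deleted run;
annotation boundaries inside deletions clamp to the deletion edge with a
warning.

Reads are assigned by their midpoint to the CDS containing it: same
strand increments the gene's sense count, opposite strand its antisense
count. Midpoint assignment resolves reads spanning CDS boundaries without
double counting, and in a convergent overlapping pair one read can be
sense for one gene and antisense for the other — which is exactly the
configuration antisense analysis cares about. Only CDS intervals are
used, avoiding variable UTR lengths.

Normalization: genes with zero counts in more than half the samples are
dropped; remaining zeros become 0.1 (sense) so the log is defined, or
missing (antisense, where coverage is sparse and a zero is better treated
as unobserved); samples are scaled by `mean(t)/t_i` with `t_i` the total
mapped reads, preserving count magnitude; data are log2-transformed; and
batch effects are removed by per-gene per-batch mean-centering (one-way
ANOVA adjustment). Centering is done on the log2 scale: centering raw
scaled counts can produce negative values that break the subsequent log,
so the literal order (available as `center_before_log = TRUE`, with a
small positive floor) is not the default. Batch means can exclude
designated samples (e.g. a deletion strain of a different background)
while the subtraction still applies to them.

## 3. Random-forest QTL mapping

Traits are continuous, so regression forests are grown with markers plus
population-structure covariates as predictors (`mtry` defaults to one
third of the predictor count, the regression default). The linkage score
of a marker is its **selection frequency**: the number of split nodes
using the marker divided by the total number of split nodes over all
combined trees. Selection frequencies over all predictors of a combined
forest sum to one. An alternative definition (fraction of trees containing
the marker) was considered and rejected because it saturates for strong
effects.

**Missing genotypes.** Forests cannot split on missing predictors, and
treating "missing" as a third genotype biases splits toward markers with
informative missingness. Instead the total tree budget
(`n_forests × trees_per_forest`) is divided into `n_missing_assignments`
chunks; before each chunk every missing entry is filled with a fresh
Bernoulli(0.5) allele (allele-frequency weighted fills behind
`freq_weighted = TRUE`), and split counts are pooled over all chunks.
With no missing entries a single forest of the full budget is grown, so
the result is independent of the assignment count.

**Population structure.** The kinship between two strains is the fraction
of co-called markers with identical alleles. Its top eigenvectors — a
fixed `fixed_k = 8`, or the smallest k explaining strictly more than 80%
of the (non-negative) eigenvalue mass — enter the forests as additional
predictors and are excluded from the returned marker scores.

**Significance.** One set of `n_perm` strain-index permutations is drawn
once and applied to *every* trait, preserving inter-trait correlation in
the null so that downstream hotspot counts are not inflated by correlated
traits discovering the same spurious marker. Marker and covariate rows
stay fixed to strains while trait values shuffle, maintaining the
trait-covariate correspondence. Pooling the permuted scores over traits
gives a per-marker null distribution; p-values use the plus-one estimator
`(1 + #null ≥ obs) / (1 + #null)`, which cannot be zero. The same
permuted scores are converted to null p-values, and the FDR at threshold
p₀ is the mean permuted discovery count at p₀ over the observed discovery
count, clipped to [0, 1] and monotonized. Benjamini–Hochberg on the
empirical p-values is *not* used by default because the permutation
estimator respects the dependence among markers.

**Grouping.** Consecutive linked markers form one region; two regions on
one chromosome merge — absorbing the intermediate non-linked markers —
when every cross-region pair of linked markers has |r| > 0.8 and at most
10 non-linked markers separate them. Regions that cannot merge remain one
multi-region *QTL group* counted as a single linkage, because it is a
priori unknown which region holds the causal variant. Reported intervals
span between the first non-linked flanking polymorphisms; terminal linked
markers extend to the chromosome end.

## 4. Downstream statistics

* **Hotspots** — each QTL is assigned to a 50-kb bin by its peak (highest
  scoring) marker; multi-bin membership for wide QTLs is a flag, not the
  default. The expected count per bin is the genome-wide mean λ =
  total/bins (a chromosome-specific λ is a flag), the tail probability is
  the exact Poisson upper tail, bins with p < 8e-4 are kept, and
  consecutive significant bins sharing ≥ 1 target merge (`share =
  "identical"` for the stricter reading).
* **cis/trans** — a QTL is cis when any member marker reaches |r| > 0.8
  with a marker flanking the target gene's CDS. Absolute correlation
  makes the call invariant to allele relabeling; using the two nearest
  flanking markers (one at chromosome ends) makes it invariant to marker
  reordering.
* **Directionality** — the sign of the P2-group mean minus the P1-group
  mean; no new test, since the linkage is already significant.
* **Candidate regulators** — the annotated gene inside the QTL interval
  maximizing squared Pearson correlation with the target; the target is
  excluded from its own QTL and ties break to the smaller coordinate.
  Hotspot regulators are chosen by majority vote over per-target
  candidates.
* **Gene-pair orientation** — coding genes are ordered by TSS per
  chromosome; successive pairs are convergent (+,−), divergent (−,+) or
  tandem, crossed with CDS overlap (UTR-only overlap does not count).
  Enrichment of a target set counts, per category, the adjacencies of the
  target genes (an interior gene contributes both its flanking pairs) and
  compares against random target sets of the same size; both enrichment
  and depletion p-values are reported. On a universe of disjoint pairs
  this statistic is exactly hypergeometric, which the tests exploit as an
  oracle.

## 5. Growth parameters

From an OD time series: efficiency = OD(end) − OD(start); AUC = trapezoid
integral above the initial-OD baseline (so a constant shift changes
nothing); μ_max = maximum first derivative of a smoothing-spline fit to
ln OD (GCV-selected smoothness; a sliding-window OLS slope is the
alternative and agrees within 10% on clean exponentials); lag time = the
tangent construction `t* − (ln OD(t*) − ln OD(0)) / μ_max`; and doubling
time T_d = ln 2 / μ_max identically. The spline estimator is the default
because it uses all points near the exponential phase rather than a fixed
window. Flat or declining curves report missing rate parameters rather
than nonsense values. Light-scattering readings convert to OD through an
ordinary least-squares line fitted on anchor measurements.

## 6. The synthetic cross: what it emulates, and what it does not

The generator's defaults (`sim_config()`) are the desk-scale study
conditions used throughout the tests:

| parameter | default | why |
|---|---|---|
| chromosomes | 3 (1.4/1.2/1.0 Mb) | a three-chromosome yeast-like genome at ~1/4 linear scale |
| genes / variants | 300 / 1000 | keeps marker spacing (~3.6 kb) in the regime where 50-kb imputation is meaningful |
| variant mix | 85% SNP, 15% indel (≤3 bp), 80% in CDS | indels drive both liftover and mapping bias; most observable variants are exonic |
| inversion | chr1:200–500 kb, suppression 0.1 | a large rearranged region where crossovers in heterozygotes mostly abort |
| segregants | 44 F2 | two successive meioses accumulate more breakpoints than F1 |
| crossover rate | 6 / Mb / meiosis, interference 50 kb | tuned once so F2 segregants average ≈17 observable breakpoints genome-wide; the interference distance reflects the near-absence of double crossovers within tens of kb and keeps the discordance-correction heuristic from rewriting genuine double recombinants |
| counts | NB, dispersion 0.05; baselines log2 ~ N(5, 1.5); library-size lognormal(0, 0.15); per-gene batch offsets N(0, 0.3) | moderate overdispersion typical of bulk RNA-seq replicates |
| antisense shift | −4 log2 | antisense coverage is orders of magnitude sparser than sense |
| call observability | P(called) = 1 − exp(−count/θ), θ = 32 | monotone in coverage; θ set once so ≈48% of site×strain entries are directly called, the regime the imputation stage is designed for |
| call error / quality | 0.002; quality ~ N(60, 15) truncated at 0 | a small allele-flip rate with most calls above the quality threshold |
| reads | 48 bp, 48-nt poly-A tail, positional error 0.01/base, mismatch budget 3 | the read count per gene is `max(1, ceiling(10 · 2^expression))` — the natural-scale transform is 2^x because expression is log2 everywhere else |

Planted effects are expressed in units of the per-gene residual SD of
normalized log2 expression implied by the count model (delta method:
`sd ≈ sqrt(1/m + φ)/ln 2`), so "a 1.5 SD effect" means the same thing for
weakly and strongly expressed genes.

**Mapping bias** is modeled analytically rather than by running an
aligner: in reference mode every covered alt-allele SNP base costs one
mismatch against the budget, and a read covering an alt-allele indel
cannot be placed at all (ungapped alignment breaks on indels). This
isolates the mechanism — reference mapping under-counts polymorphic genes
in alt-carrying strains, deterministically given the read table — at desk
scale.

Not emulated: base-level sequence evolution, diploid genetics,
fragment-length/mate-pair structure, FASTQ quality strings, UTRs and
isoforms, and spike-ins. Passing tests therefore demonstrate the
pipeline's statistical behaviour under its own assumptions, not
performance on any real library; in particular real antisense signal,
real error profiles and real batch structure are all richer than the
generator's.

## 7. Numerical choices and problem sizes

* All randomness flows from one master seed through named substreams
  (`substream_seed()`), so each stage is independently reproducible and
  results are bit-identical for a fixed seed.
* Forest fits use the `randomForest` engine; split counts come from
  `varUsed()`. Scaled-down profiles are used throughout the tests: the
  planted-QTL analysis runs 44 strains × ~200 markers × 15 traits with
  500 trees, 50 missing re-assignments and 200 shared permutations; the
  null-calibration analysis runs 200 pure-noise traits × 50 markers with
  50 trees and 100 permutations. These sizes keep the full ensemble +
  permutation machinery exercised end-to-end on a single CPU.
* Poisson tails use `ppois(k − 1, λ, lower.tail = FALSE)`; tests compare
  against a direct brute-force series sum at 1e-12.
* Empirical p-values are plus-one estimators; q-values are monotonized by
  a reverse cumulative minimum. Degenerate cases (no discoveries at a
  threshold) report q = 1.
* Ties in regulator selection and hotspot votes break to the smaller
  genomic coordinate, making every result deterministic.
* Coordinates are 1-based inclusive everywhere (VCF/GFF convention); BED
  export converts to 0-based half-open.

## 8. Known limitations

* The kinship is a plain allele-sharing matrix; no variance-component or
  mixed-model correction beyond eigenvector covariates.
* Forest-based scores have no closed-form null, so everything downstream
  rests on the permutation machinery; with few permutations the FDR tail
  is unstable (a warning fires below 20).
* The cis/trans rule depends on local marker density: in marker deserts
  the flanking-marker correlation under-calls cis.
* Interval mapping between markers, epistasis and multi-trait joint
  models are out of scope.
* The growth lag-time estimator assumes the curve actually leaves the
  baseline; for near-flat curves the tangent construction is numerically
  fragile and parameters are reported missing instead.
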