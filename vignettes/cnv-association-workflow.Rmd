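---
title: "CNV association mapping from SNP-array intensities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV association mapping from SNP-array intensities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvgwas)
library(dplyr)
```

## The problem

Genome-wide association in dairy cattle has historically scanned SNP
genotypes against breeding values for milk production traits. Copy-number
variants (CNVs) — deletions and duplications spanning kilobases to
megabases — carry additional genetic variation that biallelic SNPs capture
only indirectly, through linkage disequilibrium (LD) with nearby markers.
`cnvgwas` implements a complete pipeline for (i) calling common CNVs from
SNP-array intensity data, (ii) testing them for association with
de-regressed breeding values, (iii) partitioning the surrounding markers
into haplotype blocks, and (iv) classifying, for every significant
(CNV, trait) pair, whether the CNV's signal is captured by a neighbouring
"tag" SNP — either by direct overlap or through LD — or stands as an
independent signal a SNP panel would miss.

The package also ships a synthetic-cohort generator with a known truth set,
because the class of proprietary national-evaluation datasets this pipeline
targets cannot be redistributed. Every stage is therefore testable end to
end without any download.

## Phenotypes: de-regressed transmitting abilities

Predicted transmitting abilities (PTA) are shrunken towards the population
mean in proportion to the information available on each animal; the
squared-accuracy of a PTA is its *reliability* $r \in (0, 1]$. Using raw
PTAs as a regression response would give heavily-recorded bulls undue
leverage, so the response is the de-regressed PTA,

$$\mathrm{dPTA} = \mathrm{PTA} / r^2,$$

implemented in `deregress()`. Reliability exactly 0 is rejected rather than
silently producing infinities. `trait_correlation_matrix()` provides the
usual pairwise-complete Pearson correlations among traits (on dPTA by
default, on PTA on request, since either convention appears in practice).

## Intensity preprocessing and CNV discovery

The copy-number signal is the Log R Ratio (LRR): the log-scaled, normalised
total probe intensity, near 0 at diploid copy number, shifted down for a
loss and up for a gain. Raw LRR tracks drift with local GC content
("waviness"); `gc_correct()` removes, per sample, the least-squares fit of
LRR on (gc, gc²), leaving residuals exactly uncorrelated with GC.

`segment_multivariate()` segments a window of markers jointly across all
samples ("multivariate" in the sense of pooling every sample's intensity in
one objective):

1. **Recursive binary splitting.** Among current segments, the split that
   most reduces the within-segment sum of squares pooled over samples is
   applied, subject to a minimum of 3 markers per segment, until a maximum
   of 20 segments per window is reached or no split reduces the pooled sum
   of squares. The gain of a split is computed from per-sample segment sums
   and counts only, so missing cells are simply excluded (a design choice:
   missing intensities are never imputed, and a segment is callable for a
   sample only with at least two observed markers).
2. **Pairwise permutation pruning.** Each boundary between adjacent
   segments is tested at significance level 0.01 with 1,000 marker-order
   permutations of the two segments' union: the observed boundary gain is
   compared with the best admissible split gain of the permuted union
   (add-one convention). The least significant boundary is merged and
   testing repeats until all remaining boundaries are significant.

Two details of this design were genuinely open and deserve their rationale.
First, split-then-prune rather than test-as-you-split: an interior CNV
occupying a modest fraction of a window often admits *no* significant
single binary split of the whole window (the best first split lands
off-target and its permutation p hovers above the threshold), so a
first-failure stopping rule can miss a CNV that is trivially recoverable
once the window is over-segmented and pruned back. Second,
least-significant-first merging with re-testing: boundaries inside a
homogeneous run coalesce first, so a genuine edge is eventually tested on a
union large enough for the permutation null to resolve p-values below the
threshold (a union of a 4-marker and a 3-marker segment has only
$\binom{7}{4} = 35$ distinguishable arrangements, so no such boundary could
ever reach p < 0.01 on its own union). The permutation loop exits early
once the exceedance count makes p ≥ α inevitable; the decision is
unchanged, only the spent effort.

Window choice: the whole chromosome by default; `max_segments` applies per
window. Per-segment, per-sample means are then called into three states by
`call_state()` with the strict rule loss < −0.5 < neutral < +0.5 < gain
(values exactly at ±0.5 call neutral), non-neutral segments are
union-merged across samples into nonredundant regions (`merge_regions()`),
and regions are kept when the non-neutral fraction among callable samples
exceeds 4% (`frequency_filter()`; the 0.4% reading of the protocol is
selectable via `min_freq = 0.004`). All internal coordinates are 1-based
fully closed — the convention under which a region printed as
chr14:11,250,157–11,307,423 has length 57,267 bp — and BED output is the
only 0-based half-open surface.

## Association testing

`assoc_scan()` fits, per variant and trait, ordinary least squares of dPTA
on \[intercept, dose, covariates\] — the additive genetic model — with a
two-sided t-test on the dose coefficient. Dose is the 0/1/2 allele count
for SNPs and the −1/0/+1 state code for CNVs (equivalent up to an affine
map to 1/2/3 copy counts; the coding only rescales β). Stratification and
batch structure are absorbed by the top 10 principal components of the
variant-centred dosage matrix (`pca_covariates()`; k is configurable — the
choice of 10 is conventional, not data-driven). A constant dose is flagged
`untestable` rather than returning NaN.

`permutation_pvalue()` offers a residual-permutation (Freedman–Lane-style)
alternative: dPTA is residualised on the covariates, residuals are
permuted, and the dose t-statistic is recomputed, so the covariates stay
honoured under the null; `p = (1 + \#\{|t^*| \ge |t|\})/(B + 1)`. Analytic
and permutation p-values agree in rank almost perfectly in the package's
own simulations, and both are exposed.

Multiple testing uses Benjamini–Hochberg step-up adjustment
(`fdr_adjust()`, a validating wrapper over the standard implementation),
applied per trait within each variant class, because the two classes carry
very different significance conventions: CNVs are declared significant at
FDR-adjusted p < 0.05 and SNPs at the far stricter FDR-adjusted p < 1e-8.

## Linkage disequilibrium and haplotype blocks

Pairwise LD between unphased biallelic markers is computed by the two-locus
EM algorithm (`em_haplotype_freqs()`): only the double heterozygote is
phase-ambiguous, and the EM iterates its expected phase split to
convergence (tolerance 1e-10, 1,000-iteration cap). From haplotype
frequencies, `ld_from_freqs()` returns
$D = p_{AB} - p_A p_B$, $D' = |D|/D_{\max}$ and
$r^2 = D^2/(p_A p_a p_B p_b)$.

`dprime_ci()` provides the confidence interval the Gabriel-criteria block
definition needs: the genotype-table likelihood is profiled over $D'$ on a
0.001 grid with allele frequencies at their sample MLEs, the normalised
likelihood mass is treated as a density, and the 5th/95th percentiles bound
the interval. `gabriel_blocks()` then labels a marker pair "strong LD" when
ci_low ≥ 0.70 and ci_high ≥ 0.98, "strong recombination" when
ci_high < 0.90, and accepts a contiguous run as a block when strong-LD
pairs make at least 95% of its classified pairs (with at least one strong
pair). Markers below 5% minor-allele frequency are ignored as
non-informative, block spans are capped at 1.26 Mb — the longest block
reported for this array in Holsteins, which is also why CNV windows extend
25 markers (≈ 1.26 Mb at ~50 kb spacing) each side in `flank_window()` —
and overlapping candidates are resolved greedily, longest run first,
leftmost on ties. The published pair-count relaxations for 2–3-marker
blocks are deliberately *not* implemented: the cited criteria were given
without parameters, and a single auditable rule was preferred.

## Tag-SNP capture classification

For each significant (CNV, trait) pair — restricted to CNVs under 400 kb,
larger ones being excluded with an explicit status — `classify_relation()`
assigns exactly one of eight categories, in strict precedence order:

| category | meaning |
|---|---|
| `IN` | a significant SNP lies inside the CNV |
| `IN*` | the nearest flanking SNP on either side is significant |
| `IN**` | the second-nearest flanking SNP is significant |
| `LD` | the CNV lies in a haplotype block containing a significant SNP |
| `LD*` | the block immediately adjacent to the CNV contains one |
| `LD NS` / `LD* NS` | same geometry, block holds no significant SNP |
| `NN` | none of the above |

Overlap beats linkage: a pair that is both `IN` and `LD` is reported `IN`
(compound printed labels such as `"IN + LD"` resolve the same way).
"Adjacent to a CNV" is read positionally — the nearest (respectively
second-nearest) called flanking marker on each side. "In a block" means a
block member lies inside the CNV or the block span contains it; "adjacent
to a block" means the block's boundary marker is one of the CNV's two
nearest flanking markers. `summarize_tagging()` aggregates labels to
per-trait and overall counts with `Tagged` (= IN + IN\* + IN\*\* + LD +
LD\*) and `Not tagged` roll-ups, lumping `LD* NS` into `LD NS` by default
to mirror the conventional printed layout (the raw view is one argument
away). The packaged classification table (`load_table1_fixture()`)
aggregates to 82 combinations, 75.61% tagged — the headline estimate that
roughly a quarter of trait-associated CNVs are *not* captured by
neighbouring tag SNPs.

## The synthetic cohort: what it emulates, and what it does not

`sim_config()` fixes the standing test-bed conditions; the three generators
are each bit-reproducible from the master seed.

* **Genotypes** (`simulate_haplotypes()`): a block-copy founder model.
  Markers are partitioned into contiguous blocks (8–12 markers by default);
  each block has a founder pool of 8 haplotypes derived from two
  complementary ancestors with a 3% per-marker flip rate, and each
  individual haplotype picks a founder per block. This yields strong
  within-block LD (complete at pool size 2), no between-block LD, and
  near-0.5 allele frequencies. It is *not* a coalescent: the pipeline needs
  block structure, not a realistic frequency spectrum, and the founder
  model is dependency-free and fast. `block_length_range = c(1, 1)` with a
  large pool gives the independent-marker null.
* **Intensities** (`simulate_lrr()`): baseline 0, plus −0.7 for loss
  carriers and +0.5 for gain carriers over the CNV's markers, plus a GC
  wave `amplitude × (gc − mean gc)` (amplitude 0.1 by default), plus
  Gaussian noise of sd 0.2. The shifts straddle the ±0.5 call threshold
  under realistic noise; real arrays do not publish their shift magnitudes,
  so these are explicit, configurable stand-ins.
* **Phenotypes** (`simulate_phenotypes()`): the true additive value is
  Σ effect × dose (CNV dose −1/0/+1); PTA adds Gaussian noise of variance
  (1 − r)/r with reliability r drawn uniformly from \[0.5, 0.99\]; dPTA is
  then PTA/r². Effects are in trait-SD units (the latent genetic + noise
  scale is unit-normalised). Reliability 1 means zero noise, so effect
  recovery at full reliability is exact. No pedigree or BLUP machinery is
  emulated.

Default study conditions: 2,000 samples, one 100-marker chromosome at
50 kb spacing, a single deletion at 20% carrier frequency spanning 10
markers, with a 0.5 trait-SD effect on one trait. Passing tests under these
conditions demonstrates internal correctness and statistical calibration of
every stage; it does not certify performance on real arrays with
batch-specific noise, allele-frequency-dependent intensity clusters, or
pedigree confounding, none of which the generator emulates.

## Numerical and edge-case decisions

* Segment means require ≥ 2 observed markers; otherwise the call is
  missing, and regions with no callable sample are dropped with a warning.
* State thresholds are strict inequalities; a mean of exactly ±0.5 is
  neutral.
* The permutation add-one convention bounds p away from zero
  (min 1/(B + 1)).
* EM convergence: max frequency change < 1e-10 or 1,000 iterations;
  haplotype frequencies are clamped to ≥ 1e-12 inside the D' likelihood
  grid to keep logs finite.
* Monomorphic loci, and pairs with fewer than 10 complete genotypes, are
  flagged non-informative rather than given fabricated LD values.
* Block candidates are scored on informative pairs only and require at
  least one strong-LD pair, so a window of unclassifiable pairs can never
  form a block by vacuous ratio.
* Greedy block selection breaks length ties leftmost, making output
  deterministic.
* `merge_regions()` is order-independent (sorted union-merge), and
  classification is invariant to the input ordering of SNPs and blocks.

## Problem sizes used in the test-bed

The shipped tests and the reproduction script run, by the package's own
choice of problem size: segmentation recovery at 150 markers × 200 samples;
null calibration at 500 samples × 1,000 variants; full-pipeline detection
at 2,000 samples across replicate seeds; block recovery at 200 samples × 40
markers across replicate seeds; and the packaged classification table for
the tagging summary. These sizes keep each property estimable with
comfortable margins while the complete suite runs in minutes.

## Known limitations

* Breakpoints are resolved to marker resolution only; no sub-marker
  refinement is attempted, and region bounds are the outermost member
  marker positions.
* No B-allele-frequency modelling: state calls use total intensity alone,
  so balanced events invisible in LRR are out of reach.
* Only autosomes are in scope; X/Y intensity conventions are not handled.
* The association model is fixed-effect OLS with PCA correction, not a
  mixed model with a genomic relationship matrix; in strongly pedigreed
  cohorts residual relatedness can inflate test statistics.
* Gabriel-criteria parameters are the conventional defaults; no attempt is
  made to mimic any particular software's undocumented tweaks.
```{r session}
sessionInfo()
```
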