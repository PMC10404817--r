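---
title: "Methods: cross-species brain-biased gene discovery with brainReg"
author: "brainReg maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species brain-biased gene discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainReg)
```

# Overview

`brainReg` identifies genes whose brain/nonbrain expression bias is
specific to the primate lineage, and links them to candidate regulatory
elements whose epigenetic activity is likewise lineage-specific. This
vignette is the package's own account of the models, thresholds and design
choices; the README shows the corresponding worked example.

The pipeline has four statistical layers:

1. per-species brain-versus-nonbrain differential expression on the
   one-to-one ortholog universe;
2. a decision tree over the per-species results selecting
   primate-specific brain-biased genes (PSBEGs), plus a fetal-zone
   expression filter;
3. cross-species presence/absence classification of epigenetic peaks via
   block coordinate maps, with loop-based assignment of distal elements
   to gene promoters;
4. hypergeometric overlap statistics between the resulting gene sets.

# Differential expression model

## Normalization

Size factors use the median-of-ratios estimator: for sample $j$,
$s_j = \mathrm{median}_g\, c_{gj} / (\prod_k c_{gk})^{1/n}$, over genes
with strictly positive counts in every sample. Factors are defined up to a
common rescaling; all downstream quantities depend only on normalized
counts $c_{gj}/s_j$, so this indeterminacy is harmless. The estimator is
cross-checked against the DESeq2 implementation in the unit tests.

## Inference engine

The canonical engine for this design is a negative-binomial GLM with
dispersion shrinkage (DESeq2). `brainReg` deliberately substitutes a
simpler, fully self-contained engine: per gene it models
$y_{gj} = \log_2(c_{gj}/s_j + 1)$ with a linear model
`y ~ group (+ flagged covariates)`. With no covariates this is exactly a
Welch two-sample t-test; with covariates it is an ordinary linear model
with a two-sided t-test on the group coefficient. The decision rule is
unchanged from the NB workflow: BH-adjusted FDR < 0.05 **and**
$|\log_2 \mathrm{FC}| \ge 1.5$, where the reported fold change is always
the difference of group means of $y$ (pseudocount 1 bounds it at zero
counts). The substitution trades per-gene dispersion modelling for a
deterministic, dependency-free engine whose null behaviour we can verify
by simulation (the test suite checks empirical FDR control over 200
label-exchangeable studies); it is *not* a reimplementation of the NB
model, and users who need shrinkage should run DESeq2 externally and feed
its calls into `runPsbegPipeline()` — the decision tree only consumes
per-gene calls.

## Covariate screen

Known covariates (age, RIN: numeric; sex: categorical) are compared
between brain and nonbrain groups with a two-sided Mann-Whitney U test
(numeric) or Fisher exact test (categorical); a covariate enters the DE
design only when its screen p-value is below 0.05. Constant covariates get
p = 1. The test choice per covariate type is this package's decision; the
convention upstream tools follow for categorical covariates is not
standardized. Covariates collinear with the group indicator (perfect
confounding) cannot be estimated alongside the group effect and are
dropped with a warning.

## QC and filtering thresholds

All thresholds are strict as documented: samples need **more than** 12
million uniquely mapped reads **and** a unique-mapping rate **above**
0.70; genes must be nonzero in **strictly more than** 20% of samples. A
sample at exactly 12 million reads, or a gene nonzero in exactly 20% of
samples, is removed. The log-fold-change gate is inclusive
($\ge 1.5$). The acceptance tests exercise each boundary at, just below
and just above the cut.

# The PSBEG decision tree

With $H$, $M$, $T$ the brain-highly-expressed (up-in-brain) sets of the
reference primate, comparator primate and nonprimate, projected onto the
reference ids through the one-to-one ortholog table, the candidate set is

$$((H \cap M) \setminus T) \;\cup\; (H \setminus (M \cup T)).$$

The second term admits genes whose brain bias is specific to the reference
primate alone. Candidates then pass three organ-top filters: the highest
expressed organ must be a brain organ in the reference primate, and a
nonbrain organ in both the nonprimate and the mouse-like outgroup.

Design choices that the tree's verbal description leaves open:

* **Organ summary statistic.** "Highest expression among organs" is
  computed on median-of-ratios-normalized counts, summarizing each organ
  by its **median** across samples (robust to outlier samples); the mean
  is available via `organSummary(stat = "mean")`. TPM-based summaries can
  be supplied by building the summary matrix externally.
* **Ties.** A gene whose maximum is attained by more than one organ fails
  the filter. "The highest" is read as a unique maximum; ties are
  ambiguous evidence and the conservative choice is deterministic.
* **Brain/nonbrain organ labels** come from the sample metadata `group`
  column, never from name matching.
* The **alternative branch** (candidates intersected with the
  nonprimate's brain-lowly-expressed set, then the outgroup filter) is
  reported as `experimentalSubset`. Its containment in the final set is
  an empirical regularity, not a logical consequence of the tree — a
  brain-lowly-expressed gene need not have a nonbrain argmax organ — so
  the package asserts it in tests on simulated data rather than enforcing
  it as a class invariant.

The audit trail assigns every universe gene exactly one terminal
disposition (`not_candidate`, eliminated at a named filter, or `psbeg`),
so the funnel from candidates to the final set is fully reconstructable.

## Fetal-zone filter

A gene survives when strictly more than 80% of fetal human samples (zones
SVZ, VZ, aRG, bRG) have $\log_2(\mathrm{FPKM}+1) > 1$ and strictly more
than 80% of fetal mouse samples have $\log_2(\mathrm{FPKM}+1) < 1$. A
sample exactly at the threshold counts against both criteria.

# Cross-species peak classification

## Coordinate maps

Cross-assembly conversion uses a minimal block-map contract rather than
UCSC chain files: equal-width source/target block pairs with explicit
gaps; the on-disk dialect is a 7-column TSV. An interval converts when at
least `minMappedFraction = 0.95` of its bases fall in blocks (mirroring
common liftOver practice), all pieces land on one target chromosome, and
orientations are consistent; otherwise the conversion fails. Orientation
`-` reverses coordinates within the block. Internally all intervals are
`GRanges` (1-based closed); BED and block-map files (0-based half-open)
are converted at the I/O boundary, which keeps a single coordinate
convention inside the package.

## Presence rule and classes

A peak is *present* in a species when it overlaps (>= 1 bp) at least one
peak in **every** sample of that species — the strictest reading of
replicate consensus, chosen as default because the consensus rule used
upstream of peak lists is typically unstated; `any` and `fraction(f)`
rules are selectable, as is a minimum-overlap fraction. Failed conversion
counts as absence, applied symmetrically in the genome-wide classifier:

| comparator | outgroup | class |
|---|---|---|
| absent/unmappable | absent/unmappable | human_specific |
| present | absent/unmappable | primate_specific |
| any | present | human_all_shared |

The three classes partition the reference-present peaks; the test suite
checks all nine evidence combinations against an enumeration oracle and a
10,000-peak synthetic genome against planted truth. Mapping is
single-direction (reference to other species); reciprocal-best mapping is
not implemented.

The focal-gene scan applies the same logic to peaks within 2 Mb of a gene
of interest against the outgroup only, so primate-specific peaks are
reported as specifically activated there as well.

## Loops and element-gene links

Promoter windows span 2 kb upstream to 1 kb downstream of the TSS,
strand-aware and clipped at the chromosome start. A loop with one anchor
in a gene's promoter window assigns elements overlapping the other anchor
to that gene (`loop_distal`); elements in a promoter window directly are
`promoter_overlap`; both anchors are treated symmetrically. Conserved
noncoding elements are linked to genes within 500 kb by edge-to-edge
distance to the gene **body** (the common annotator default; TSS distance
is an option), nearest gene by default with lexicographic tie-breaking,
or all genes within the window — both readings of "proximal within 500 kb"
occur in practice, so both are provided and the intent is not guessed.

# Overlap statistics

Gene-set overlaps are tested one-sided (enrichment) via the
hypergeometric upper tail, computed with `phyper` (a stable log-space tail
evaluation); this equals the one-sided Fisher exact test, which the suite
cross-checks by brute-force pmf summation for every margin configuration
up to a universe of 60. The universe is always explicit — by default the
one-to-one ortholog universe — and never inferred from set unions. Odds
ratios are sample estimates with a 0.5 continuity correction when a cell
is zero. Across a matrix of tests, BH adjustment spans all cells. For
region-versus-region comparisons the package reports counts and ratios
(intersection over total queries) rather than a test, matching how such
overlaps are conventionally summarized.

# Single-cell comparisons

Cluster assignments and cross-species integration are consumed as input;
the package does not reimplement anchor integration. Cluster labels
transfer by the largest percentage among the reference species' cells
(ties to the lexicographically smaller label, flagged; clusters without
reference cells are `unassigned`). Per-cluster cross-species DEGs use
two-sided Wilcoxon rank-sum tests, adjusted across genes within each
(cluster, species pair) stratum — Bonferroni by default, the convention of
the integration toolkit this workflow typically follows, with BH
selectable, since "adjusted P" alone does not pin down the method.
Constant genes get p = 1. Clusters with fewer than 3 cells in either
species are skipped with a warning.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not any real dataset:

* **Counts** are negative binomial, `mu` from a log-normal baseline
  (meanlog log 100, sdlog 1) shared across species, dispersion 0.1 by
  default. Planted genes multiply their brain-tissue mean by the fold
  effect (default 8) in the two primates and divide it in the nonprimate
  and outgroup; all other genes have identical means across tissues, so
  label permutations are exchangeable and null calibration is meaningful.
* **Design**: four species (reference primate, comparator primate,
  nonprimate, mouse-like outgroup), one brain and three nonbrain organs,
  10 samples per organ; covariates age, sex and RIN are balanced unless
  `confoundedCovariates = TRUE`, which shifts brain-sample ages to
  exercise the screen. QC fields are drawn above the retention thresholds
  so the QC filter is a pass-through unless a test constructs failures.
* **Genomes**: one chromosome per species, genes every 50 kb with
  alternating strand; peaks on a non-overlapping grid, roughly 50%
  shared / 30% primate-specific / 20% human-specific. Maps are
  identity-coordinate with gaps: gaps always cover the peaks planted as
  unmappable, never the peaks that must convert, and random 5 kb gap
  chunks bring the unmappable share up to `unmappableFraction` (default
  0.1). Comparator samples carry peaks at shared + primate-specific
  positions, outgroup samples at shared positions only. Loops wire
  human-specific enhancer peaks to planted genes' promoters.
* **Fetal zones**: planted genes are log-normal around FPKM 8 in the
  human-like and 0.2 in the mouse-like tables; other genes share a
  moderate level in both species (failing the mouse criterion) and a
  trailing 5% are zero everywhere (failing the human criterion).
* **Single cell**: negative-binomial expression per cluster with planted
  fold-effect DEGs in one designated cluster; comparator-primate cells
  carry reference labels with a 10% admixture.
* **Seeds**: one master seed; each generator derives its own stream from
  a fixed label, so adding a generator never perturbs the others, and
  identical config + seed reproduce every output byte for byte.

What the generator does **not** emulate: library-size variation beyond
NB sampling, batch structure, GC/length biases, isoform complexity,
sequence evolution, peak-width variability, or doublets/ambient RNA in
the single-cell layer. Passing the recovery tests therefore demonstrates
that the selection logic is implemented correctly, not that it is robust
to the full noise structure of real data.

# Numerical choices and degenerate inputs

* Welch p-values for zero-variance genes: p = 1 when the group means are
  equal, 0 otherwise (perfect separation at zero variance).
* `bhAdjust` rejects values outside [0, 1] or missing, rather than
  propagating NA silently.
* Interval intersection ignores strand everywhere except promoter
  windows; peaks and conserved elements are unstranded signals, gene
  annotations must be stranded.
* Mapped intervals spanning several blocks return the spanning range on
  the target; round-trips through the inverse map are exact for intervals
  inside consistent-orientation block runs (property-tested).
* All set outputs are sorted or order-stable, and the decision tree is a
  pure function of its inputs — permuting gene order does not change any
  result.

# Problem sizes in the shipped tests

The test and acceptance runs use 2,000-gene studies (20 planted, fold 8,
dispersion 0.1, 10 samples per tissue, 20 seeds) for recovery, 200
x 400-gene studies for null calibration, a 10,000-peak genome for
classification, exhaustive hypergeometric checks to universe 60, and full
Wilcoxon enumeration to group size 8 — sizes chosen so the whole suite
runs in a few minutes on a laptop while keeping every check exact or
well-powered.

# Known limitations

* The DE engine is a deliberate simplification of the NB workflow (see
  above); very low counts with few replicates will be less powerful than
  dispersion-shrinkage methods.
* Ortholog projection silently restricts every cross-species statement to
  the one-to-one universe; genes outside it are invisible to the tree.
* Peak classification depends on the replicate-consensus rule; with the
  strict `all` default a single failed replicate flips a peak to absent.
* Block maps model colinear mappings only; inversions within a block and
  many-to-many mappings are out of scope.
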