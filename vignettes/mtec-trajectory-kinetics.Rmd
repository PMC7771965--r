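---
title: "Models and methods: mTEC trajectory and TSA kinetics"
author: "tecdyn"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Models and methods: mTEC trajectory and TSA kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(message = FALSE, warning = FALSE)
library(tecdyn)
library(SummarizedExperiment)
```

# The analysis this package implements

Medullary thymic epithelial cells (mTECs) delete autoreactive T cells by
collectively displaying tissue-specific antigens (TSAs): genes whose
peripheral expression is restricted to five or fewer tissues, expressed
promiscuously in the thymus under the control of the transcriptional
regulators Aire and Fezf2. Droplet single-cell RNA-seq of the thymic
epithelium resolves this compartment into cortical TECs, a `Ccl21a`-high
mTEC subset, a cycling transit-amplifying population ("TAC-TEC") at a
developmental branch point, `Aire`-positive mTECs, a post-Aire ("Late-Aire")
state and tuft-like cells. The package provides, as reusable and tested
functions, the quantitative procedures needed to dissect this system:

* **Preprocessing** — QC filtering, library-size log-normalisation
  (natural log of `1 + s·x/total` with scale `s = 1000`),
  mean/dispersion variable-gene selection, PCA with a fixed sign
  convention, seeded k-means as a pluggable clustering.
* **Cell-cycle phase calls** from marker gene *pairs*: for each phase the
  score is the fraction of its pairs whose first gene is the more highly
  expressed within the cell, so calls depend only on within-cell expression
  order.
* **Gene sets** — TSA curation from a gene-by-tissue detection table
  (detected in at most 5 tissues, protein-coding), knockout-dependent sets
  from strict differential-expression thresholds, Wilcoxon rank-sum marker
  detection with Benjamini–Hochberg adjustment, cluster-unique signatures,
  and hypergeometric overlap enrichment identical to a one-sided Fisher
  exact test.
* **Detection kinetics** — per-cell percent-of-set and mean-expression
  statistics, per-sample cumulative detection fractions after equalising
  sequencing depth by exact multivariate-hypergeometric UMI down-sampling,
  and a cell-subsampling null distribution scored with a z-statistic.
* **Trajectory** — start-anchored branching pseudotime from a minimum
  spanning tree over cluster centroids, smoothed expression profiles over
  pseudotime, and per-sample pseudotime densities.
* **Annotation** — majority-vote label transfer from reference cells,
  two-marker quadrant frequencies at strict cutoffs, per-sample population
  proportions.

Every stage is exercised end-to-end on a synthetic branching-trajectory
generator with full ground truth, described next.

# The synthetic generator

`simConfig()` + `simulateDataset()` draw a control thymus;
`ablationPreset()` + `simulateTimecourse()` draw an ablation/recovery time
course. The model, in the order the truth is planted:

**Populations and pseudotime.** Cells are allocated to the six populations
by configurable weights (default 10% cTEC, 25% `Ccl21a`-high, 15% TAC-TEC,
25% Aire-positive, 18% Late-Aire, 7% tuft). Developmental pseudotime `t`
lies in [0, 1] with the branch point at 0.3: TAC-TECs occupy `t` in
(0.05, 0.3) and are primed toward one of the two fates (default 70%
Aire-primed); Aire-positive cells occupy (0.3, 0.7), Late-Aire (0.7, 1.0)
and `Ccl21a`-high (0.3, 1.0) on their own branch. cTEC and tuft cells sit
outside the trajectory.

**Cycling** is confined to the branch point: 60% of TAC-TECs are in S or
G2/M versus 1% elsewhere, so planted G2/M cells concentrate (>80%) in the
TAC-TEC population. Each phase owns 30 marker genes expressed at rate 2.5
in-phase and 0.15 out of phase; `simulateCyclePairs()` emits (a, b) pairs
whose inequality holds in-phase, reverses in b's phase, and vanishes in the
third phase — which makes the documented 0.5-tie convention of
`scorePhases()` exact on noise-free rates.

**Programs.** The `Fezf2` transcript follows a broad bump peaking at
`t = 0.30`; `Aire` follows a bump peaking at `t = 0.55` that switches on at
a per-cell onset drawn from (0.12, 0.28) and off at an offset drawn from
(0.75, 0.95), so a fraction of Late-Aire cells have already lost `Aire`.
TSA activation probabilities are logistic in `t`: the Fezf2-dependent
sub-pool rises early (midpoint 0.28) and stays on; the Aire-dependent and
unassigned sub-pools rise late (midpoint 0.55), placing the TSA peak after
the `Aire` peak. Each cell's expressed-TSA set is an independent Bernoulli
draw from these probabilities — a mosaic — and the activation ceilings are
rescaled at configuration time so the *expected fraction of the TSA pool
expressed per mature Aire-branch cell* equals the midpoint of
`tsaFractionPerCell` (default interval [0.01, 0.03], i.e. each mature cell
expresses about 2% of all TSAs). Per-TSA expression rates rise mildly with
`t` (factor `0.6 + 0.8t`), so the *mean over expressed members* grows
gradually while the *mean over all members* surges late — the two modes of
`meanSetExpression()` separate these regimes.

**Lineage reporter.** The reporter transcript (`ZsGreen`) is an ordinary
gene row. A cell is reporter-positive iff it has entered an Aire-expressing
state and its onset precedes its pseudotime by at least `reporterLag`
(default 0.15 pseudotime units, a free parameter of the model — the
biological lag between driver expression and a detectable indelible label
is not quantified anywhere we could anchor it). Recently induced cells
(`Aire`+, reporter−) therefore concentrate in the TAC-TEC population, and a
configurable 30% of `Ccl21a`-high cells carry an old onset, making them
reporter-positive without current `Aire` — both patterns the annotation
module is meant to detect.

**Counts.** Gene rates are assembled per cell (housekeeping 1.2,
mitochondrial 1.4, population markers 4 with lineage-primed TAC-TECs at an
intermediate 1.5, branch-specific maturation gradients `0.1 + 3t` plus a
shared immature program `0.1 + 3(1-t)`, `Ccl21a` and `Krt10` at genuinely
high rates so the standard positivity cutoffs of 4 and 2 on the
log-normalised scale are meaningful, and a long tail of log-normal
baseline genes). A library size is drawn log-normally (median 5000 UMIs,
sdlog 0.25) and the cell's counts are one multinomial draw over its
normalised rates — totals are exact, which is what gives UMI down-sampling
its clean multivariate-hypergeometric semantics downstream.

**Ablation time course.** Each sample scales only the three Aire-branch
populations by per-timepoint depletion factors and multiplies TSA
activation by a per-timepoint activity. The preset mimics transient
receptor-signalling blockade: week 2 retains mostly late cells, week 4 is
the nadir of the Aire-positive compartment (factor 0.10, TSA activity 0.2)
while early cells have begun to return, week 6 is intermediate and week 10
matches the two untreated controls. `Ccl21a`-branch absolute counts are
identical at every timepoint, so only the Aire branch is perturbed.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: batch effects and multi-sample integration,
ambient RNA and doublets, spliced/unspliced kinetics, real TSA
co-expression structure (planted TSAs are independent Bernoulli draws, real
TSA groups are correlated), cluster-overlapping population boundaries, and
any form of technical depth variation beyond the log-normal library model.

# Pipeline and numerical choices

* **QC bounds are closed**: "between 200–7500 genes" keeps cells with
  exactly 200 or exactly 7500 detected genes; the mitochondrial fraction
  cutoff (≤ 0.10) is computed over UMIs, and mitochondrial genes default to
  the mouse `mt-` identifier prefix. Cells are filtered before genes
  (detected in ≥ 3 retained cells).
* **Natural log everywhere**; fold changes are
  `ln[(mean(expm1 x) + 1)/(mean(expm1 y) + 1)]`, and the dependent-gene
  thresholds are strict (`adjusted p < 0.05`, `lfc > 1`; a natural-log
  fold change of 1 ≈ 2.7-fold, with both thresholds exposed as parameters
  because published definitions of knockout-dependence vary between
  "2-fold" and "lfc > 1").
* **Wilcoxon tests** use exact enumeration when both groups have ≤ 25
  untied observations and the normal approximation with tie correction and
  continuity correction otherwise; BH adjustment is applied across genes
  within each contrast. Uniqueness of a cluster signature is evaluated
  one-vs-rest by default (the pairwise contrast is available) because the
  "upregulated in this cluster and no other" filter is unambiguous there.
* **Hypergeometric enrichment** is the exact upper tail `P(X ≥ k)`
  computed in log space, provably identical to the one-sided Fisher exact
  test on the induced 2×2 table (property-tested against `fisher.test`).
  For the canonical worked example in this field — an overlap of 21
  between a 35-gene cluster-unique list and a 173-gene transit-amplifying
  signature in a universe of 20,309 genes — the exact tail is
  2.06×10⁻³⁵ (fold enrichment 70.4). A widely quoted p of 1.44×10⁻³⁴ for
  these counts is not reproducible from them under any standard tail
  convention; it corresponds to a universe of roughly 18,500 genes, which
  suggests the quoted figure was computed on a filtered gene universe
  rather than the stated total. The package reports the exact tail for the
  stated counts.
* **UMI down-sampling** draws the target number of molecules uniformly
  without replacement from the whole matrix (per-sample totals are what
  the detection statistics need equalised); a per-cell variant can be
  obtained by applying the function per column. "Expressed" always means
  raw count > 0, which coincides with normalised value > 0.
* **The subsampling null** reports a one-sided lower-tail p by default
  (the scientific question is depletion); two-sided and upper-tail are
  flags. When every replicate is identical (sd = 0) the z-score is
  undefined and the p-value is set to 1 if the observation is at or above
  the null mean, 0 otherwise.
* **Trajectory**: the method is deliberately a simplification — MST over
  cluster centroids rooted at the start cluster, root-to-leaf lineages,
  orthogonal projection onto the piecewise-linear curve. Terminal segments
  are extended beyond their end centroids so extreme cells keep a strict
  ordering, and pseudotime is arc length under a single global min-max
  affine map. We chose the global map over per-lineage min-max scaling
  because the two desiderata "per-lineage [0,1]" and "identical values on
  the shared pre-branch segment" are incompatible when lineage lengths
  differ; comparability of profiles across branches won. Principal-curve
  refinement is not performed. Ground-truth recovery on synthetic data —
  not equality with any external trajectory package — is the validation
  criterion.
* **Cell-cycle genes are excluded from the trajectory embedding** (the
  analogue of regressing out cell-cycle effects before ordering): cycling
  is confined to the branch point, so cycle genes displace the start
  cluster orthogonally to maturation and, if kept, can reroute the
  centroid MST around it.
* **Densities** use a Gaussian kernel with Silverman's rule on a common
  200-point grid, renormalised to integrate to 1 on the grid; a histogram
  variant is available.
* **Label transfer** votes over reference-labelled cells only, breaks
  exact ties lexicographically and flags them; behaviour under genuinely
  ambiguous (near 50/50) clusters is a documented policy, not something
  the data can decide.
* **Quadrant cutoffs are strict** (`value > cutoff`), so a cutoff of 0 on
  log-normalised data means "any count detected" and cells at exactly the
  cutoff are negative.

# Test problem sizes

The suite validates the pipeline at sizes chosen to make the planted
structure statistically unambiguous while keeping the whole suite fast: a
2,000-cell control dataset (2,000 genes, 600 TSAs) for trajectory,
program-ordering and simulator-contract checks; six samples of 1,000
baseline cells for the ablation time course; 300–600 cells for unit tests;
1,000 replicates for Monte-Carlo and subsampling-null checks, with
brute-force enumeration oracles on instances small enough to enumerate
(≤ 6 cells, ≤ 4 genes; 4-vs-4 rank configurations).

# Known limitations

The trajectory method assumes cluster centroids trace the developmental
topology; it will not recover cycles, very short branches hidden inside a
cluster, or branches whose centroid geometry is dominated by off-trajectory
programs (hence the cell-cycle exclusion above). The pair-based phase
classifier reproduces the documented scoring rule, not the internal
randomisation of any published classifier. The subsampling null treats
cells as exchangeable within the reference population. The generator's
parameter defaults are study conditions, not estimates fitted to any real
dataset.
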