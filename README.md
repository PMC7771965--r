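# tecdyn

Quantitative procedures for dissecting the development of medullary thymic
epithelial cells (mTECs) from droplet single-cell RNA-seq. mTECs enforce
central immune tolerance by collectively expressing tissue-specific
antigens (TSAs) — genes detected in five or fewer peripheral tissues — with
each mature cell expressing only 1–3% of the TSA repertoire under the
control of *Aire* and *Fezf2*. The package is for computational biologists
who need the bespoke statistics of this system as tested, reusable
functions rather than one-off scripts: cell-cycle calls from marker-gene
pairs, TSA gene-set curation and kinetics, depth-equalised detection
statistics with resampling nulls, overlap enrichment, start-anchored
branching pseudotime, and reference-based annotation — plus a synthetic
branching-trajectory generator with full ground truth that makes every
stage testable without external data.

## The statistics at the core

* Log-normalisation: `value(g,c) = ln(1 + s·x(g,c)/total(c))`, `s = 1000`.
* Pair-based phase score: for each phase `P` with marker pairs `(aᵢ, bᵢ)`,
  `score_P(c) = meanᵢ[1·(x(aᵢ,c) > x(bᵢ,c)) + ½·(x(aᵢ,c) = x(bᵢ,c))]`;
  G1/G2M are called at score ≥ ½ (larger wins; ties → S).
* TSA curation: `{g : tissues(g) ≤ 5 and protein-coding(g)}`; per-cell
  percent of set `|{g ∈ S : x(g,c) > 0}| / |S|`.
* Overlap enrichment: `p = P(X ≥ k)`, `X ~ Hypergeom(N, K, n)`, computed
  in log space; identical to the one-sided Fisher exact test on the 2×2
  table `[[k, n−k], [K−k, N−n−K+k]]`.
* UMI down-sampling: a multivariate-hypergeometric draw of exactly
  `target` molecules from the matrix, so per-entry expectation is
  `x · target/total` and totals are conserved exactly.
* Subsampling null: the detection fraction of `n` reference cells drawn
  without replacement, 1000 times; the observation is scored with
  `z = (obs − mean)/sd` and a lower-tail normal p (depletion test).
* Pseudotime: MST over cluster centroids rooted at the start cluster;
  cells project orthogonally onto root-to-leaf polylines; pseudotime is
  arc length, min-max rescaled once globally.

## Worked example

```r
library(tecdyn)
library(SummarizedExperiment)

sce <- simulateDataset(simConfig(nCellsPerSample = 800, seed = 42))
counts <- assay(sce, "counts")
nm <- logNormalize(filterQC(counts))

# TSA mosaic: mature Aire-branch cells express ~2% of the 600-gene TSA pool
pct <- percentSetPerCell(counts, geneSets(sce)$TSA)
mean(pct[sce$population %in% c("Aire-positive", "Late-Aire")])
#> [1] 0.021

# pair-based phase calls localise G2/M to the transit-amplifying population
pa <- scorePhases(nm, S4Vectors::metadata(sce)$markerPairs)
round(phaseByCluster(pa, sce$population)$phase_fraction[, "G2M"], 3)
#> Aire-positive   Ccl21a-high          cTEC     Late-Aire       TAC-TEC
#>         0.000         0.026         0.000         0.000         0.974
#>          Tuft
#>         0.000

# overlap of a 35-gene cluster-unique list with a 173-gene published
# signature: 21 shared genes in a universe of 20,309
enr <- hypergeomEnrichment(k = 21, n = 35, K = 173, N = 20309)
sprintf("p = %.3g, fold = %.1f", enr$p_value, enr$fold_enrichment)
#> [1] "p = 2.06e-35, fold = 70.4"
```

97% of G2/M calls land in the TAC-TEC population — cycling is confined to
the branch point — and the mean per-cell TSA fraction sits inside the
configured 1–3% mosaic. The enrichment p-value is the exact upper
hypergeometric tail and equals the one-sided Fisher exact p for the same
table.

## The methods vignette

`vignettes/mtec-trajectory-kinetics.Rmd` documents the generator's model
and defaults, the pipeline's numerical choices (tie rules, thresholds,
tail conventions), the trajectory design decisions, and known limitations.
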