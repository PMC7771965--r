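# Shared fixtures. The larger simulated datasets are built once per session
# and cached; everything is generated in code under fixed seeds.

library(Matrix)
suppressPackageStartupMessages(library(SummarizedExperiment))

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, maker(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a compact configuration for fast unit tests
smallConfig <- function(nCells = 300, seed = 2, ...) {
  simConfig(nCellsPerSample = nCells, nGenes = 800,
            genePartition = c(housekeeping = 30, markers = 122, cycle = 90,
                              tsa = 150, reporter = 1, mito = 10,
                              other = 397),
            tsaSubPools = c(aire = 75, fezf2 = 45), seed = seed, ...)
}

# the default study-condition dataset (2000 cells) used by the trajectory
# and simulator-contract checks
default_sim <- function() cached("default_sim", function()
  simulateDataset(simConfig(seed = 11)))

# ablation/recovery time course under the preset conditions
ablation_sim <- function() cached("ablation_sim", function()
  simulateTimecourse(ablationPreset(seed = 5)))

# trajectory fit on the default dataset: variable genes minus cell-cycle
# markers (the cycle-regression analogue), PCA, planted populations as
# clusters, TAC-TEC as the start cluster
default_traj <- function() cached("default_traj", function() {
  sce <- default_sim()
  tr <- simTruth(sce)
  m <- assay(sce, "counts")
  nm <- logNormalize(m)
  traj <- tr$population %in% c("TAC-TEC", "Aire-positive", "Late-Aire",
                               "Ccl21a-high")
  vg <- selectVariableGenes(nm[, traj])
  vg <- vg[!grepl("^Cc\\.", vg)]
  pc <- embedPCA(nm[, traj], vg, 10)
  pt <- fitPseudotime(pc, tr$population[traj], "TAC-TEC")
  list(sce = sce, truth = tr, counts = m, nm = nm, traj = traj, vg = vg,
       coords = pc, pt = pt)
})

# small deterministic count matrix
toy_counts <- function(nGenes = 50, nCells = 20, seed = 1, lambda = 2) {
  set.seed(seed)
  m <- matrix(rpois(nGenes * nCells, lambda), nGenes, nCells,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("c%03d", seq_len(nCells))))
  as(m, "CsparseMatrix")
}
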