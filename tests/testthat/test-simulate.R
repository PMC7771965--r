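test_that("identical configuration and seed give bit-identical output", {
  a <- simulateDataset(smallConfig(120, seed = 42))
  b <- simulateDataset(smallConfig(120, seed = 42))
  expect_identical(as.matrix(assay(a, "counts")), as.matrix(assay(b, "counts")))
  expect_identical(as.data.frame(simTruth(a)), as.data.frame(simTruth(b)))
  c <- simulateDataset(smallConfig(120, seed = 43))
  expect_false(identical(as.matrix(assay(a, "counts")),
                         as.matrix(assay(c, "counts"))))
})

test_that("counts are non-negative integers and totals follow the log-normal library model", {
  sce <- default_sim()
  m <- assay(sce, "counts")
  expect_true(all(m@x > 0), info = "sparse slots store only positives")
  expect_true(all(m@x == round(m@x)))
  tot <- Matrix::colSums(m)
  ks <- suppressWarnings(ks.test(log(tot), "pnorm", log(5000), 0.25))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted pseudotime medians are strictly ordered along the Aire branch", {
  tr <- simTruth(default_sim())
  med <- tapply(tr$pseudotime, tr$population, median, na.rm = TRUE)
  expect_lt(med[["TAC-TEC"]], med[["Aire-positive"]])
  expect_lt(med[["Aire-positive"]], med[["Late-Aire"]])
})

test_that("simulated tissue tables are recovered exactly by TSA curation", {
  genes <- sprintf("g%03d", 1:200)
  tsa <- sprintf("g%03d", 1:40)
  tab <- simulateTissueTable(genes, nTissues = 30, tsaIds = tsa, seed = 6)
  expect_true(all(tab$detected_tissues[tab$gene_id %in% tsa] <= 5))
  expect_true(all(tab$detected_tissues[!tab$gene_id %in% tsa] > 5))
  got <- curateTsas(tab)
  expect_setequal(geneIds(got), tsa)
  # seed determinism
  expect_identical(tab, simulateTissueTable(genes, 30, tsa, seed = 6))
  # non-coding TSAs are excluded by curation
  nc <- tsa[1:4]
  tab2 <- simulateTissueTable(genes, 30, tsa, seed = 6, nonCodingIds = nc)
  expect_setequal(geneIds(curateTsas(tab2)), setdiff(tsa, nc))
  expect_error(simulateTissueTable(genes, 5, tsa), "exceed 5")
})

test_that("reporter lag boundaries behave as specified", {
  tr <- simTruth(default_sim())
  r0 <- simulateReporter(tr, lag = 0)
  # lag 0: every cell that has ever expressed Aire is reporter-positive
  expect_true(all(r0[tr$ever_aire] > 0))
  expect_true(all(r0[!tr$ever_aire] == 0))
  expect_true(all(r0[tr$aire_expressing] > 0))
  # lag of a full pseudotime unit: nobody is positive
  expect_true(all(simulateReporter(tr, lag = 1) == 0))
  expect_error(simulateReporter(tr, lag = -0.1), "non-negative")
})

test_that("the lagged reporter concentrates Aire+/reporter- cells at the branch point", {
  tr <- simTruth(default_sim())
  ar <- tr$aire_expressing & !tr$reporter_on
  fTac <- mean(ar[tr$population == "TAC-TEC"])
  fPos <- mean(ar[tr$population == "Aire-positive"])
  expect_gt(fTac, fPos)
  expect_gt(fTac, 0)
})

test_that("a control-only time course has identical per-sample composition", {
  cfg <- smallConfig(200, seed = 9,
                     samples = list(a = list(), b = list(), c = list()))
  tc <- simulateTimecourse(cfg)
  tr <- simTruth(tc)
  tab <- table(tr$sample, tr$population)
  expect_true(all(tab[1, ] == tab[2, ]))
  expect_true(all(tab[1, ] == tab[3, ]))
})

test_that("the ablation preset depletes only the Aire branch, with the nadir as configured", {
  tr <- simTruth(ablation_sim())
  tab <- table(tr$sample, tr$population)
  # Ccl21a-high absolute counts identical across all timepoints
  expect_equal(max(tab[, "Ccl21a-high"]) - min(tab[, "Ccl21a-high"]), 0)
  expect_lt(diff(range(tab[, "cTEC"])), 1)
  # Aire-positive proportion minimal at the planted week-4 nadir
  pr <- proportionsBySample(tr)
  expect_equal(names(which.min(pr[, "Aire-positive"])), "wk4")
  expect_gt(pr["ctrl_wk10", "Aire-positive"], 2 * pr["wk4", "Aire-positive"])
  expect_error(simulateTimecourse(smallConfig(50, samples = list(a = list()))),
               ">= 2")
})

test_that("cycle pairs satisfy the planted within-phase inequality noise-free", {
  cfg <- smallConfig(150, seed = 12)
  sce <- simulateDataset(cfg, keepRates = TRUE)
  rates <- assay(sce, "rates")
  tr <- simTruth(sce)
  pairs <- simulateCyclePairs(10, seed = 2, config = cfg)
  for (ph in c("G1", "S", "G2M")) {
    pp <- pairs[pairs$phase == ph, ]
    cells <- which(tr$phase == ph)
    a <- as.matrix(rates[pp$gene_a, cells, drop = FALSE])
    b <- as.matrix(rates[pp$gene_b, cells, drop = FALSE])
    expect_true(all(a > b), info = paste("phase", ph))
  }
  expect_identical(simulateCyclePairs(10, seed = 2, config = cfg),
                   simulateCyclePairs(10, seed = 2, config = cfg))
  expect_error(simulateCyclePairs(99, seed = 2, config = cfg), "1..30")
})

test_that("configuration errors are caught", {
  expect_error(simConfig(nGenes = 100), "sum to nGenes")
  expect_error(smallConfig(100, tsaFractionPerCell = c(0.03, 0.01)),
               "increasing interval")
  expect_error(smallConfig(100, reporterLag = -1), ">= 0")
  expect_error(smallConfig(100, samples = list(
    a = list(), b = list(depletion = c("TAC-TEC" = -1)))), ">= 0")
})

test_that("truth is planted before counts: removing TSA rows leaves truth unchanged", {
  sce <- simulateDataset(smallConfig(100, seed = 33))
  tsa <- geneIds(geneSets(sce)$TSA)
  pruned <- assay(sce, "counts")[setdiff(rownames(sce), tsa), ]
  # truth columns make no reference to the count realisation
  expect_identical(as.data.frame(simTruth(sce)),
                   as.data.frame(simTruth(simulateDataset(smallConfig(100, seed = 33)))))
  expect_equal(nrow(pruned), nrow(sce) - length(tsa))
})
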