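test_that("TSA curation applies the tissue cutoff and coding filter, monotonically", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    detected_tissues = c(3, 6, 5, 5),
                    protein_coding = c(TRUE, TRUE, FALSE, TRUE))
  got <- curateTsas(tab)
  expect_setequal(geneIds(got), c("a", "d"))   # <=5 tissues and coding
  # monotone in the cutoff
  sizes <- sapply(1:8, function(k) {
    g <- suppressWarnings(curateTsas(tab, maxTissues = k))
    if (is.null(g)) 0L else length(g)
  })
  expect_true(all(diff(sizes) >= 0))
  expect_warning(curateTsas(tab, maxTissues = 0), "no gene")
})

test_that("dependent-gene thresholds are strict on both sides", {
  de <- data.frame(gene = c("x", "y", "z", "w"),
                   lfc = c(1.5, 0.9, 2.0, 1.0),
                   adjusted_p = c(0.01, 0.01, 0.2, 0.01))
  got <- thresholdDependentGenes(de, minLfc = 1, maxAdjP = 0.05)
  expect_identical(geneIds(got), "x")   # y fails lfc>1, z fails p, w: lfc==1
})

test_that("Wilcoxon markers match enumeration, BH step-up and degenerate cases", {
  # complete separation at 4 vs 4: exact two-sided p is 2/70
  nm <- rbind(sep = c(1, 2, 3, 4, 10, 11, 12, 13),
              flat = rep(2, 8))
  colnames(nm) <- paste0("c", 1:8)
  de <- deMarkers(nm, rep(c("a", "b"), each = 4), minLfc = 0.1)
  expect_equal(de$p_value[de$gene == "sep" & de$group == "a"], 2 / 70,
               tolerance = 1e-12)
  flat <- de[de$gene == "flat" & de$group == "a", ]
  expect_equal(flat$lfc, 0)
  expect_equal(flat$p_value, 1)
  expect_false(flat$significant)
  # BH adjustment equals a hand-rolled step-up on the same raw p-values
  stepup <- function(p) {
    m <- length(p); o <- order(p); ro <- order(o)
    pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))[ro]
  }
  set.seed(3)
  nm2 <- matrix(rnorm(20 * 16), 20, 16,
                dimnames = list(paste0("g", 1:20), paste0("c", 1:16)))
  de2 <- deMarkers(nm2, rep(c("a", "b"), each = 8))
  pa <- de2[de2$group == "a", ]
  expect_equal(pa$adjusted_p, stepup(pa$p_value), tolerance = 1e-12)
  expect_true(all(pa$adjusted_p >= pa$p_value))
})

test_that("marker p-values are uniform under the null", {
  set.seed(4)
  X <- matrix(rnorm(300 * 60), 300, 60,
              dimnames = list(paste0("g", 1:300), paste0("c", 1:60)))
  de <- deMarkers(X, rep(c("a", "b"), each = 30))
  p <- de$p_value[de$group == "a"]
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("uniquely upregulated genes are the set difference against all other clusters", {
  up <- list(TAC = c("A", "B", "C"), other1 = "B", other2 = character())
  expect_setequal(uniqueUpregulated(up, "TAC"), c("A", "C"))
  expect_length(uniqueUpregulated(list(TAC = character(), o = "B"), "TAC"), 0)
  expect_error(uniqueUpregulated(up, "absent"), "not present")
})

test_that("planted branch-point markers are recovered as the cluster-unique signature", {
  sce <- cached("de_sim", function() simulateDataset(smallConfig(600, seed = 21)))
  tr <- simTruth(sce)
  nm <- logNormalize(assay(sce, "counts"))
  de <- deMarkers(nm, tr$population)
  up <- split(de$gene[de$significant], de$group[de$significant])
  uniq <- uniqueUpregulated(up, "TAC-TEC")
  planted <- c("Hmgb2", "H2afz", "Hmgn2", "Hmgb1", "Hmgn1",
               grep("^Mk\\.TACTEC", rownames(sce), value = TRUE))
  expect_gte(mean(uniq %in% planted), 0.9)      # precision
  expect_gte(mean(planted %in% uniq), 0.9)      # recall
})

test_that("hypergeometric enrichment matches enumeration and Fisher's exact test", {
  # exhaustive: overlap >=2 drawing 3 from a universe of 10 with 4 marked
  got <- hypergeomEnrichment(k = 2, n = 3, K = 4, N = 10)
  expect_equal(got$p_value, 40 / 120, tolerance = 1e-12)
  expect_equal(hypergeomEnrichment(0, 3, 4, 10)$p_value, 1)
  expect_equal(got$fold_enrichment, (2 / 3) / (4 / 10))
  # equality with one-sided Fisher on random instances
  set.seed(11)
  for (i in 1:100) {
    N <- sample(20:500, 1)
    n <- sample(1:(N - 1), 1)
    K <- sample(1:(N - 1), 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    f <- stats::fisher.test(matrix(c(k, n - k, K - k, N - n - K + k), 2, 2),
                            alternative = "greater")$p.value
    expect_equal(hypergeomEnrichment(k, n, K, N)$p_value, f,
                 tolerance = 1e-9)
  }
  expect_error(hypergeomEnrichment(5, 3, 4, 10), "inconsistent")
})

test_that("the four curated sets partition the coding universe", {
  sce <- default_sim()
  gs <- geneSets(sce)
  universe <- rownames(sce)
  core <- union(geneIds(gs$TSA),
                union(geneIds(gs$Aire_dependent), geneIds(gs$Fezf2_dependent)))
  other <- setdiff(universe, core)
  expect_length(intersect(other, core), 0)
  expect_setequal(c(other, core), universe)
  # dependent sub-pools sit inside the TSA pool by construction
  expect_true(all(geneIds(gs$Aire_dependent) %in% geneIds(gs$TSA)))
})
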