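test_that("QC bounds are closed and applied in the stated order", {
  set.seed(7)
  m <- matrix(0, 300, 5,
              dimnames = list(sprintf("g%03d", 1:300), paste0("c", 1:5)))
  m[1:150, 1] <- 1          # 150 detected genes: below the closed minimum
  m[1:200, 2] <- 1          # exactly 200: kept
  m[1:250, 3] <- 1          # mid-range: kept
  m[1:300, 4] <- 1          # 300 detected: kept
  m[1:250, 5] <- 1          # will fail on mito fraction
  mt <- rbind(m, "mt-x" = c(0, 0, 0, 0, 40))  # 40/290 > 10% for c5
  out <- filterQC(mt, minGenes = 200, maxGenes = 7500,
                  maxMitoFraction = 0.10, minCellsPerGene = 3)
  expect_setequal(colnames(out), c("c2", "c3", "c4"))
  # gene detected in exactly 2 surviving cells is removed, in 3 kept
  expect_false("g250" %in% rownames(out))  # detected in c3, c4 only
  expect_true("g200" %in% rownames(out))   # detected in c2, c3, c4
  expect_error(filterQC(mt, minGenes = 400, maxGenes = 7500), "every cell")
})

test_that("QC filtering is idempotent on the default dataset", {
  m <- assay(default_sim(), "counts")
  once <- filterQC(m)
  twice <- filterQC(once)
  expect_identical(dim(once), dim(twice))
  expect_true(all(once == twice))
})

test_that("log-normalisation matches its closed form and is scale invariant", {
  m <- matrix(c(10, 990, 0, 5, 495, 0), 3, 2,
              dimnames = list(c("a", "b", "c"), c("x", "y")))
  nm <- logNormalize(m, scaleFactor = 1000)
  expect_equal(nm["a", "x"], log(11), tolerance = 1e-12)
  expect_equal(nm["c", "x"], 0)
  # y is x scaled by 0.5: identical normalised vectors
  expect_equal(as.numeric(nm[, "x"]), as.numeric(nm[, "y"]), tolerance = 1e-12)
  m0 <- m; m0[, 2] <- 0
  expect_error(logNormalize(m0), "zero total")
})

test_that("log-normalisation commutes with a full-total down-sample", {
  m <- toy_counts(30, 10, seed = 5)
  expect_equal(as.matrix(logNormalize(downsampleUmis(m, sum(m), seed = 1))),
               as.matrix(logNormalize(m)))
})

test_that("variable-gene selection finds planted over-dispersion and ignores constants", {
  set.seed(9)
  n <- 500
  lam <- runif(400, 0.5, 3)              # background spans a range of means
  bg <- matrix(rpois(400 * n, rep(lam, n)), 400, n)
  nb <- rnbinom(n, mu = 1.5, size = 0.3) # over-dispersed, mid-range mean
  cst <- rep(1, n)                       # zero variance
  M <- rbind(bg, nb = nb, cst = cst)
  rownames(M) <- c(sprintf("g%03d", 1:400), "nb", "cst")
  colnames(M) <- sprintf("c%03d", 1:n)
  vg <- selectVariableGenes(logNormalize(M))
  expect_true("nb" %in% vg)
  expect_false("cst" %in% vg)
})

test_that("identically distributed genes yield a z-threshold-tail-sized selection", {
  set.seed(21)
  n <- 400
  M <- matrix(rpois(500 * n, 1), 500, n,
              dimnames = list(sprintf("g%03d", 1:500), sprintf("c%03d", 1:n)))
  vg <- selectVariableGenes(logNormalize(M))
  frac <- length(vg) / 500
  # all genes share one distribution, so selection is just the z >= 0.5 tail
  expect_gt(frac, 0.10)
  expect_lt(frac, 0.50)
})

test_that("PCA embedding is deterministic and captures planar structure", {
  set.seed(4)
  basis <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:2]
  x <- matrix(rnorm(200 * 2), 200, 2) %*% t(basis)  # exactly 2-dimensional
  nm <- t(x) + 5
  dimnames(nm) <- list(paste0("g", 1:10), paste0("c", 1:200))
  pc <- embedPCA(nm, nComponents = 3, scale. = FALSE)
  v <- apply(pc, 2, var)
  expect_gt(sum(v[1:2]) / sum(v), 0.999)
  expect_identical(pc, embedPCA(nm, nComponents = 3, scale. = FALSE))
  expect_error(embedPCA(nm, nComponents = 0), "nComponents")
  expect_error(embedPCA(nm, nComponents = 50), "nComponents")
})

test_that("k-means clustering separates blobs and is seed-stable", {
  set.seed(8)
  xy <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 8), 50, 2))
  rownames(xy) <- paste0("c", 1:100)
  cl <- clusterCells(xy, k = 2, seed = 3)
  truth <- rep(0:1, each = 50)
  expect_equal(mclust::adjustedRandIndex(cl, truth), 1)
  expect_identical(cl, clusterCells(xy, k = 2, seed = 3))
  expect_equal(length(unique(clusterCells(xy, k = 1, seed = 3))), 1)
  expect_error(clusterCells(xy, k = 200), "k must")
})

test_that("UMI down-sampling conserves the target exactly and never exceeds originals", {
  m <- toy_counts(40, 15, seed = 2, lambda = 3)
  expect_identical(downsampleUmis(m, sum(m), seed = 1), m)
  expect_equal(sum(downsampleUmis(m, 0, seed = 1)), 0)
  for (s in 1:20) {
    tgt <- sample.int(sum(m), 1)
    d <- downsampleUmis(m, tgt, seed = s)
    expect_equal(sum(d), tgt)
    expect_true(all(d <= m))
    expect_true(all(d@x >= 0))
  }
})

test_that("cell subsampling is uniform, order-preserving in genes, and seeded", {
  m <- toy_counts(20, 12, seed = 3)
  all12 <- subsampleCells(m, 12, seed = 4)
  expect_setequal(colnames(all12), colnames(m))
  expect_identical(rownames(all12), rownames(m))
  one <- subsampleCells(m, 1, seed = 4)
  expect_true(colnames(one) %in% colnames(m))
  expect_identical(subsampleCells(m, 5, seed = 9), subsampleCells(m, 5, seed = 9))
  expect_error(subsampleCells(m, 0), "must lie")
  expect_error(subsampleCells(m, 13), "must lie")
})

test_that("housekeeping dropout is the zero-count fraction and shrinks after depth equalisation", {
  m <- matrix(c(0, 0, 2, 1, 1, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("hk1", "hk2"), c("a", "b", "c")))
  d <- housekeepingDropout(m, c("hk1", "hk2", "absent"))
  expect_equal(unname(d["hk1"]), 2 / 3)
  z <- rbind(m, hk3 = 0)
  expect_equal(unname(housekeepingDropout(z, "hk3")["hk3"]), 1)
  expect_error(housekeepingDropout(m, "nope"), "none of")

  # two samples at different depths: equalising UMIs narrows the dropout gap
  set.seed(14)
  rate <- rgamma(200, 2, 2)
  deep <- sapply(1:80, function(i) rpois(200, rate * 5))
  shallow <- sapply(1:80, function(i) rpois(200, rate))
  dimnames(deep) <- list(sprintf("g%03d", 1:200), sprintf("d%02d", 1:80))
  dimnames(shallow) <- list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:80))
  hk <- sprintf("g%03d", 1:10)
  gapRaw <- mean(abs(housekeepingDropout(deep, hk) -
                     housekeepingDropout(shallow, hk)))
  eq <- downsampleUmis(deep, sum(shallow), seed = 6)
  gapEq <- mean(abs(housekeepingDropout(eq, hk) -
                    housekeepingDropout(shallow, hk)))
  expect_lt(gapEq, gapRaw)
})
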