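mini <- function() {
  m <- matrix(c(2, 0, 0, 0,
                1, 3, 0, 0,
                0, 0, 0, 0,
                4, 4, 4, 4,
                0, 1, 0, 0), 5, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  as(m, "CsparseMatrix")
}

test_that("percent-of-set and genes-per-cell satisfy their exact identity", {
  m <- mini()
  s <- GeneSet("s", paste0("g", 1:4))
  pct <- percentSetPerCell(m, s)
  expect_equal(unname(pct), c(3 / 4, 2 / 4, 1 / 4, 1 / 4))
  expect_true(all(pct >= 0 & pct <= 1))
  gpc <- genesPerCell(m, s)
  expect_identical(gpc, as.integer(pct * 4))
  # a cell expressing every member scores 1
  expect_equal(unname(percentSetPerCell(m, "g4")), rep(1, 4))
  expect_error(percentSetPerCell(m, "absent"), "no members")
  # identity on random fixtures
  r <- toy_counts(30, 10, seed = 6)
  s2 <- rownames(r)[c(1, 5, 9, 20, 28)]
  expect_equal(genesPerCell(r, s2), as.integer(percentSetPerCell(r, s2) * 5))
})

test_that("mean set expression distinguishes all-members from expressed-only", {
  nm <- matrix(c(2, 0, 0, 0), 4, 1,
               dimnames = list(paste0("g", 1:4), "c1"))
  s <- paste0("g", 1:4)
  expect_equal(unname(meanSetExpression(nm, s, "all")), 0.5)
  expect_equal(unname(meanSetExpression(nm, s, "expressed_only")), 2)
  zero <- nm * 0
  expect_equal(unname(meanSetExpression(zero, s, "all")), 0)
  expect_equal(unname(meanSetExpression(zero, s, "expressed_only")), 0)
})

test_that("on the Aire branch all-member means rise late while expressed-only rises gradually", {
  sce <- default_sim()
  tr <- simTruth(sce)
  nm <- logNormalize(assay(sce, "counts"))
  tsa <- geneSets(sce)$TSA
  mature <- !is.na(tr$pseudotime) & tr$branch == "Aire" &
    tr$population %in% c("Aire-positive", "Late-Aire")
  t <- tr$pseudotime[mature]
  allm <- meanSetExpression(nm[, mature], tsa, "all")
  expr <- meanSetExpression(nm[, mature], tsa, "expressed_only")
  early <- t < quantile(t, 1 / 3); late <- t > quantile(t, 2 / 3)
  ratioAll <- mean(allm[late]) / mean(allm[early])
  ratioExpr <- mean(expr[late]) / mean(expr[early])
  expect_gt(ratioAll, 2 * ratioExpr)   # late surge in how many genes are on
  expect_gt(ratioExpr, 1)              # gradual rise of per-gene level
  expect_lt(ratioExpr, 2)
})

test_that("cumulative detection is a monotone set-union statistic", {
  m <- mini()
  s <- paste0("g", 1:5)
  d1 <- cumulativeFractionDetected(m, s, cells = "c1")
  expect_equal(d1$fraction_detected, 3 / 5)
  dAll <- cumulativeFractionDetected(m, s)
  expect_equal(dAll$fraction_detected, 4 / 5)
  expect_equal(dAll$n_detected_genes, 4L)
  # adding cells never decreases the fraction
  fracs <- sapply(1:4, function(k)
    cumulativeFractionDetected(m, s, cells = paste0("c", 1:k))$fraction_detected)
  expect_true(all(diff(fracs) >= 0))
  expect_error(cumulativeFractionDetected(m, s, cells = character()), "empty")
})

test_that("down-sampling UMIs never increases detection in expectation", {
  m <- toy_counts(40, 12, seed = 8, lambda = 1)
  s <- rownames(m)[1:20]
  before <- cumulativeFractionDetected(m, s)$fraction_detected
  after <- mean(sapply(1:200, function(sd)
    cumulativeFractionDetected(downsampleUmis(m, round(sum(m) / 3), seed = sd),
                               s)$fraction_detected))
  expect_lte(after, before)
})

test_that("the recovery curve finds its minimum at the planted nadir", {
  tc <- ablation_sim()
  tr <- simTruth(tc)
  rc <- cached("recovery", function()
    recoveryCurve(assay(tc, "counts"), tr, geneSets(tc)$TSA,
                  "Aire-positive", seed = 7))
  expect_identical(rc$sample, levels(tr$sample))
  expect_equal(rc$sample[which.min(rc$fraction_detected)], "wk4")
  # identical control replicates agree within sampling error
  ctrl <- rc$fraction_detected[rc$sample %in% c("ctrl_wk2", "ctrl_wk10")]
  expect_lt(abs(diff(ctrl)), 0.1)
  w <- capture_warnings(
    rcMissing <- recoveryCurve(assay(tc, "counts"), tr, geneSets(tc)$TSA,
                               "no-such-pop", equalize = FALSE))
  expect_true(any(grepl("no 'no-such-pop' cells", w)))
  expect_true(all(is.na(rcMissing$fraction_detected)))
})

test_that("the subsampling null matches brute-force enumeration on a tiny instance", {
  ref <- matrix(c(1, 0, 0, 2, 0, 1,
                  0, 0, 0, 1, 1, 0,
                  3, 1, 0, 0, 0, 0,
                  0, 0, 0, 0, 0, 4), 4, 6, byrow = TRUE,
                dimnames = list(paste0("g", 1:4), paste0("c", 1:6)))
  cmb <- utils::combn(6, 3)
  exact <- mean(apply(cmb, 2, function(cols)
    mean(rowSums(ref[, cols, drop = FALSE] > 0) > 0)))
  sn <- subsampleNull(ref, paste0("g", 1:4), 3, observedFraction = 0.5,
                      nReps = 2000, seed = 8)
  se <- sd(sn$replicate_values) / sqrt(sn$n_reps)
  expect_lt(abs(sn$mean - exact), 3 * se)
  expect_length(sn$replicate_values, 2000)
  expect_equal(sn$z, (0.5 - sn$mean) / sn$sd)
})

test_that("degenerate and self-consistent subsampling nulls behave as documented", {
  ones <- matrix(1, 3, 5, dimnames = list(paste0("g", 1:3), paste0("c", 1:5)))
  sn <- subsampleNull(ones, paste0("g", 1:3), 2, observedFraction = 1,
                      nReps = 100, seed = 1)
  expect_equal(sn$sd, 0)
  expect_equal(sn$p_value, 1)
  expect_error(subsampleNull(ones, paste0("g", 1:3), 2, 1, nReps = 1), "at least 2")
  # observation drawn from the reference itself scores |z| < 3
  m <- toy_counts(60, 40, seed = 9, lambda = 0.3)
  s <- rownames(m)[1:30]
  obs <- cumulativeFractionDetected(subsampleCells(m, 15, seed = 77), s)$fraction_detected
  snc <- subsampleNull(m, s, 15, obs, nReps = 500, seed = 10)
  expect_lt(abs(snc$z), 3)
})
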