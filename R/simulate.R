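# Synthetic branching-trajectory generator.
#
# Emulates the structure the downstream analyses assume: a TAC-TEC branch
# point feeding an Aire lineage (Aire-positive -> Late-Aire) and a
# Ccl21a-high lineage, cycling confined to the branch point, a lagged
# indelible lineage reporter (ZsGreen), a stochastic tissue-specific-antigen
# (TSA) mosaic in which each mature cell expresses only a small percentage of
# the TSA pool, Fezf2 program onset before the Aire peak before the TSA peak,
# and an ablation/recovery time course that depletes only the Aire branch.
# Counts are drawn per cell as a multinomial over program-derived gene rates
# with log-normal library sizes, so per-cell totals are exact and UMI
# down-sampling semantics are preserved.

.TEC_POPULATIONS <- c("cTEC", "Ccl21a-high", "TAC-TEC", "Aire-positive",
                      "Late-Aire", "Tuft")

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic mTEC generator.
#' Defaults encode the study conditions the analyses are tested under: a
#' six-population control thymus with the branch point at pseudotime 0.3,
#' cycling confined to TAC-TECs, each mature Aire-branch cell expressing on
#' average \code{mean(tsaFractionPerCell)} of the TSA pool, and the Fezf2
#' activation midpoint before the Aire peak before the TSA activation
#' midpoint.
#'
#' @param nCellsPerSample cells per sample before any ablation depletion.
#' @param nGenes total genes; must equal \code{sum(genePartition)}.
#' @param genePartition named sizes for the gene classes
#'   \code{housekeeping}, \code{markers}, \code{cycle}, \code{tsa},
#'   \code{reporter}, \code{mito}, \code{other}. \code{markers} covers the
#'   Aire/Fezf2 program genes, 12 markers per population and an even split of
#'   maturation-gradient genes; \code{cycle} must be divisible by 3.
#' @param tsaSubPools named sizes \code{c(aire=, fezf2=)} of the
#'   Aire-dependent and Fezf2-dependent TSA sub-pools (remainder is neither).
#' @param tsaFractionPerCell interval for the expected fraction of the TSA
#'   pool expressed per mature Aire-branch cell; activation ceilings are
#'   scaled so the planted mean sits at the interval midpoint.
#' @param reporterLag pseudotime lag between Aire onset and reporter
#'   positivity (the ZsGreen transcription/translation delay).
#' @param librarySizeLogMean,librarySizeLogSd log-normal library-size model.
#' @param cyclingFractionTac,cyclingFractionOther fraction of cycling (S or
#'   G2M) cells in TAC-TEC and in every other population.
#' @param cclPrimedFraction fraction of TAC-TECs primed toward the Ccl21a
#'   fate (the rest are Aire-primed).
#' @param cclEverAireFraction fraction of Ccl21a-high cells that passed
#'   through an Aire-expressing state (reporter-positive at the default lag).
#' @param populationWeights named per-population composition weights.
#' @param samples optional named list of time-course samples, each a list
#'   with elements \code{depletion} (named factors for \code{TAC-TEC},
#'   \code{Aire-positive}, \code{Late-Aire}) and \code{tsaActivity}
#'   (multiplier on TSA activation probabilities). \code{NULL} means a single
#'   control sample.
#' @param seed integer master seed; identical configurations are
#'   bit-reproducible.
#' @return a validated list of class \code{SimConfig}.
#' @seealso \code{\link{simulateDataset}}, \code{\link{simulateTimecourse}},
#'   \code{\link{ablationPreset}}
#' @export
simConfig <- function(nCellsPerSample = 2000, nGenes = 2000,
                      genePartition = c(housekeeping = 100, markers = 122,
                                        cycle = 90, tsa = 600, reporter = 1,
                                        mito = 20, other = 1067),
                      tsaSubPools = c(aire = 300, fezf2 = 180),
                      tsaFractionPerCell = c(0.01, 0.03),
                      reporterLag = 0.15,
                      librarySizeLogMean = log(5000),
                      librarySizeLogSd = 0.25,
                      cyclingFractionTac = 0.6,
                      cyclingFractionOther = 0.01,
                      cclPrimedFraction = 0.3,
                      cclEverAireFraction = 0.3,
                      populationWeights = c("cTEC" = 0.10, "Ccl21a-high" = 0.25,
                                            "TAC-TEC" = 0.15,
                                            "Aire-positive" = 0.25,
                                            "Late-Aire" = 0.18, "Tuft" = 0.07),
                      samples = NULL, seed = 1L) {
  need <- c("housekeeping", "markers", "cycle", "tsa", "reporter", "mito",
            "other")
  if (!setequal(names(genePartition), need))
    stop("genePartition must name exactly: ", paste(need, collapse = ", "),
         call. = FALSE)
  genePartition <- genePartition[need]
  if (sum(genePartition) != nGenes)
    stop("genePartition sizes must sum to nGenes", call. = FALSE)
  if (genePartition["cycle"] %% 3 != 0)
    stop("the cycle block must be divisible by 3 phases", call. = FALSE)
  if (genePartition["housekeeping"] < 5 || genePartition["mito"] < 1 ||
      genePartition["reporter"] != 1)
    stop("need >=5 housekeeping genes, >=1 mito gene, exactly 1 reporter",
         call. = FALSE)
  nGrad <- genePartition["markers"] - 2 - 12 * length(.TEC_POPULATIONS)
  if (nGrad < 3 || nGrad %% 3 != 0)
    stop("markers block must be 74 + a multiple of 3 gradient genes",
         call. = FALSE)
  if (sum(tsaSubPools) > genePartition["tsa"])
    stop("TSA sub-pools exceed the TSA pool", call. = FALSE)
  if (length(tsaFractionPerCell) != 2 || any(tsaFractionPerCell <= 0) ||
      any(tsaFractionPerCell >= 1) || diff(tsaFractionPerCell) <= 0)
    stop("tsaFractionPerCell must be an increasing interval inside (0,1)",
         call. = FALSE)
  if (reporterLag < 0) stop("reporterLag must be >= 0", call. = FALSE)
  if (!setequal(names(populationWeights), .TEC_POPULATIONS))
    stop("populationWeights must name the six populations", call. = FALSE)
  populationWeights <- populationWeights[.TEC_POPULATIONS]
  if (any(populationWeights < 0) || sum(populationWeights) <= 0)
    stop("populationWeights must be non-negative and normalisable",
         call. = FALSE)
  populationWeights <- populationWeights / sum(populationWeights)
  if (!is.null(samples)) {
    if (is.null(names(samples)) || anyDuplicated(names(samples)))
      stop("samples must be a uniquely named list", call. = FALSE)
    samples <- lapply(samples, function(s) {
      depl <- c("TAC-TEC" = 1, "Aire-positive" = 1, "Late-Aire" = 1)
      if (!is.null(s$depletion)) depl[names(s$depletion)] <- s$depletion
      if (any(depl < 0)) stop("depletion factors must be >= 0", call. = FALSE)
      act <- if (is.null(s$tsaActivity)) 1 else s$tsaActivity
      if (act < 0) stop("tsaActivity must be >= 0", call. = FALSE)
      list(depletion = depl, tsaActivity = act)
    })
    for (nm in names(samples)) {
      w <- populationWeights
      w[names(samples[[nm]]$depletion)] <-
        w[names(samples[[nm]]$depletion)] * samples[[nm]]$depletion
      if (sum(w) <= 0)
        stop("sample '", nm, "' has all-zero population weights",
             call. = FALSE)
    }
  }
  structure(list(nCellsPerSample = as.integer(nCellsPerSample),
                 nGenes = as.integer(nGenes), genePartition = genePartition,
                 tsaSubPools = tsaSubPools,
                 tsaFractionPerCell = tsaFractionPerCell,
                 reporterLag = reporterLag,
                 librarySizeLogMean = librarySizeLogMean,
                 librarySizeLogSd = librarySizeLogSd,
                 cyclingFractionTac = cyclingFractionTac,
                 cyclingFractionOther = cyclingFractionOther,
                 cclPrimedFraction = cclPrimedFraction,
                 cclEverAireFraction = cclEverAireFraction,
                 populationWeights = populationWeights,
                 samples = samples, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Anti-RANKL ablation/recovery preset
#'
#' A time-course configuration emulating transient ablation of the Aire
#' branch by RANKL blockade: two untreated controls plus recovery samples at
#' weeks 2, 4, 6 and 10. Depletion factors empty the Aire-positive
#' compartment most deeply at the week-4 nadir while early cells (TAC-TECs)
#' have begun to return, week 2 retains mostly late (Late-Aire) cells, and
#' week 10 matches the controls. TSA activation is suppressed alongside
#' (nadir at week 4, full recovery by week 10). Ccl21a-branch absolute cell
#' counts are untouched at every timepoint.
#'
#' @param nCellsPerSample baseline cells per sample.
#' @param seed master seed.
#' @param ... further arguments passed to \code{\link{simConfig}}.
#' @return a \code{SimConfig} with six samples.
#' @export
ablationPreset <- function(nCellsPerSample = 1000, seed = 1L, ...) {
  samples <- list(
    ctrl_wk2 = list(depletion = c("TAC-TEC" = 1, "Aire-positive" = 1,
                                  "Late-Aire" = 1), tsaActivity = 1),
    wk2 = list(depletion = c("TAC-TEC" = 0.3, "Aire-positive" = 0.25,
                             "Late-Aire" = 0.8), tsaActivity = 0.35),
    wk4 = list(depletion = c("TAC-TEC" = 0.8, "Aire-positive" = 0.10,
                             "Late-Aire" = 0.15), tsaActivity = 0.2),
    wk6 = list(depletion = c("TAC-TEC" = 1, "Aire-positive" = 0.6,
                             "Late-Aire" = 0.3), tsaActivity = 0.45),
    wk10 = list(depletion = c("TAC-TEC" = 1, "Aire-positive" = 1,
                              "Late-Aire" = 1), tsaActivity = 1),
    ctrl_wk10 = list(depletion = c("TAC-TEC" = 1, "Aire-positive" = 1,
                                   "Late-Aire" = 1), tsaActivity = 1))
  simConfig(nCellsPerSample = nCellsPerSample,
            populationWeights = c("cTEC" = 0.13, "Ccl21a-high" = 0.33,
                                  "TAC-TEC" = 0.08, "Aire-positive" = 0.18,
                                  "Late-Aire" = 0.13, "Tuft" = 0.15),
            samples = samples, seed = seed, ...)
}

# ------------------------------------------------------------ gene catalogue

.sim_genes <- function(cfg) {
  p <- cfg$genePartition
  hk <- c("Gapdh", "Chmp2a", "Emc7", "Psmb4", "Vcp",
          if (p["housekeeping"] > 5)
            sprintf("Hk%03d", seq_len(p["housekeeping"] - 5)))
  seedMarkers <- list(
    "cTEC" = c("Ackr4", "Prss16"),
    "Ccl21a-high" = c("Ccl21a", "Krt5"),
    "TAC-TEC" = c("Hmgb2", "H2afz", "Hmgn2", "Hmgb1", "Hmgn1"),
    "Aire-positive" = character(),
    "Late-Aire" = "Krt10",
    "Tuft" = c("Trpm5", "Dclk1"))
  popMarkers <- lapply(.TEC_POPULATIONS, function(pp) {
    extra <- 12 - length(seedMarkers[[pp]])
    c(seedMarkers[[pp]],
      sprintf("Mk.%s.%02d", gsub("[^A-Za-z0-9]", "", pp), seq_len(extra)))
  })
  names(popMarkers) <- .TEC_POPULATIONS
  nGrad <- (p["markers"] - 2 - 12 * length(.TEC_POPULATIONS)) / 3
  matAire <- sprintf("MatA%02d", seq_len(nGrad))
  matCcl <- sprintf("MatC%02d", seq_len(nGrad))
  matDn <- sprintf("Matdn%02d", seq_len(nGrad))
  nCyc <- p["cycle"] / 3
  cyc <- lapply(c(G1 = "G1", S = "S", G2M = "G2M"),
                function(ph) sprintf("Cc.%s.%02d", ph, seq_len(nCyc)))
  nA <- cfg$tsaSubPools["aire"]; nF <- cfg$tsaSubPools["fezf2"]
  nN <- p["tsa"] - nA - nF
  tsa <- list(aire = sprintf("Tsa.A.%03d", seq_len(nA)),
              fezf2 = sprintf("Tsa.F.%03d", seq_len(nF)),
              neither = if (nN > 0) sprintf("Tsa.N.%03d", seq_len(nN))
                        else character())
  mito <- sprintf("mt-Gene%02d", seq_len(p["mito"]))
  other <- sprintf("Gene%04d", seq_len(p["other"]))
  ids <- c(hk, "Aire", "Fezf2", unlist(popMarkers, use.names = FALSE),
           matAire, matCcl, matDn, unlist(cyc, use.names = FALSE),
           unlist(tsa, use.names = FALSE), "ZsGreen", mito, other)
  stopifnot(length(ids) == cfg$nGenes, !anyDuplicated(ids))
  list(ids = ids, hk = hk, popMarkers = popMarkers, matAire = matAire,
       matCcl = matCcl, matDn = matDn, cyc = cyc, tsa = tsa, mito = mito,
       other = other)
}

# ------------------------------------------------------------ program curves

.aire_curve <- function(t) 6 * exp(-((t - 0.55) / 0.22)^2)
.fezf2_curve <- function(t) 3.5 * exp(-((t - 0.30) / 0.25)^2)
# TSA activation probability profiles (shape only; scaled to the configured
# per-cell fraction): Fezf2-dependent genes switch on early and stay on,
# Aire-dependent (and unassigned) genes switch on after the Aire peak.
.tsa_profile <- function(t, pool) {
  switch(pool,
         aire = stats::plogis((t - 0.55) / 0.09),
         fezf2 = stats::plogis((t - 0.28) / 0.10),
         neither = stats::plogis((t - 0.55) / 0.09))
}
.TSA_CEILING <- c(aire = 0.045, fezf2 = 0.025, neither = 0.030)

# Expected fraction of the TSA pool active in a mature Aire-branch cell at
# unit activation scale, integrated over the configured mature pseudotime
# distribution; used to scale ceilings to the requested per-cell fraction.
.tsa_scale <- function(cfg) {
  w <- cfg$populationWeights
  wA <- w["Aire-positive"] / (w["Aire-positive"] + w["Late-Aire"])
  tA <- seq(0.3, 0.7, length.out = 201)
  tL <- seq(0.7, 1.0, length.out = 201)
  nT <- cfg$genePartition["tsa"]
  sizes <- c(aire = unname(cfg$tsaSubPools["aire"]),
             fezf2 = unname(cfg$tsaSubPools["fezf2"]))
  sizes["neither"] <- nT - sum(sizes)
  f0 <- sum(vapply(names(sizes), function(pl) {
    m <- wA * mean(.tsa_profile(tA, pl)) + (1 - wA) * mean(.tsa_profile(tL, pl))
    sizes[pl] * .TSA_CEILING[pl] * m
  }, numeric(1))) / nT
  mean(cfg$tsaFractionPerCell) / f0
}

# ------------------------------------------------------------ planted truth

.sim_truth <- function(cfg, sampleName, depletion, tsaActivity, genes) {
  nPop <- round(cfg$nCellsPerSample * cfg$populationWeights)
  nPop[names(depletion)] <- round(nPop[names(depletion)] * depletion)
  nPop <- nPop[nPop > 0]
  population <- rep(names(nPop), nPop)
  n <- length(population)
  t <- rep(NA_real_, n)
  t[population == "TAC-TEC"] <- stats::runif(sum(population == "TAC-TEC"), 0.05, 0.3)
  t[population == "Aire-positive"] <- stats::runif(sum(population == "Aire-positive"), 0.3, 0.7)
  t[population == "Late-Aire"] <- stats::runif(sum(population == "Late-Aire"), 0.7, 1.0)
  t[population == "Ccl21a-high"] <- stats::runif(sum(population == "Ccl21a-high"), 0.3, 1.0)
  branch <- rep("none", n)
  branch[population %in% c("Aire-positive", "Late-Aire")] <- "Aire"
  branch[population == "Ccl21a-high"] <- "Ccl21a"
  isTac <- population == "TAC-TEC"
  branch[isTac] <- ifelse(stats::runif(sum(isTac)) < cfg$cclPrimedFraction,
                          "Ccl21a", "Aire")
  # phases: cycling confined to the branch point
  cycFrac <- ifelse(isTac, cfg$cyclingFractionTac, cfg$cyclingFractionOther)
  cycling <- stats::runif(n) < cycFrac
  phase <- rep("G1", n)
  phase[cycling] <- sample(c("S", "G2M"), sum(cycling), replace = TRUE)
  # Aire onset/offset: onset precedes the branch point; ever_aire cells on
  # the Ccl21a branch passed through Aire earlier in their history
  onset <- rep(NA_real_, n)
  onAire <- branch == "Aire" & population %in%
    c("TAC-TEC", "Aire-positive", "Late-Aire")
  onset[onAire] <- stats::runif(sum(onAire), 0.12, 0.28)
  cclEver <- population == "Ccl21a-high" &
    stats::runif(n) < cfg$cclEverAireFraction
  onset[cclEver] <- stats::runif(sum(cclEver), 0.12, 0.28)
  offset <- rep(NA_real_, n)
  offset[onAire] <- stats::runif(sum(onAire), 0.75, 0.95)
  everAire <- !is.na(onset) & !is.na(t) & t >= onset
  aireOn <- onAire & everAire & t <= offset
  reporterOn <- everAire & (t - onset >= cfg$reporterLag)
  krt10Hi <- population == "Late-Aire" & stats::runif(n) < 0.2
  # TSA mosaic: Bernoulli subset of the pool, probability scaled so the
  # expected per-mature-cell fraction hits the configured interval
  sc <- .tsa_scale(cfg)
  branchFactor <- ifelse(population %in% c("TAC-TEC", "Aire-positive",
                                           "Late-Aire") & branch == "Aire", 1,
                  ifelse(population == "Ccl21a-high", 0.05, 0))
  tsaIds <- unlist(genes$tsa, use.names = FALSE)
  pools <- rep(names(genes$tsa), lengths(genes$tsa))
  expressedTsas <- vector("list", n)
  tEff <- ifelse(is.na(t), 0, t)
  for (pl in unique(pools)) {
    idx <- which(pools == pl)
    q <- pmin(1, .TSA_CEILING[pl] * sc * .tsa_profile(tEff, pl) *
                branchFactor * tsaActivity)
    draw <- matrix(stats::runif(length(idx) * n), length(idx), n) <
      rep(q, each = length(idx))
    hit <- which(draw, arr.ind = TRUE)
    byCell <- split(tsaIds[idx][hit[, 1]], factor(hit[, 2], levels = seq_len(n)))
    expressedTsas <- Map(c, expressedTsas, byCell)
  }
  cellIds <- sprintf("%s_c%04d", sampleName, seq_len(n))
  truth <- S4Vectors::DataFrame(
    cell_id = cellIds, sample = sampleName, population = population,
    branch = branch, pseudotime = t, phase = phase, aire_onset = onset,
    aire_offset = offset, ever_aire = everAire, aire_expressing = aireOn,
    reporter_on = reporterOn, krt10_hi = krt10Hi,
    n_tsas = lengths(expressedTsas), row.names = cellIds)
  names(expressedTsas) <- cellIds
  list(truth = truth, expressedTsas = expressedTsas)
}

# ------------------------------------------------------------ rate model

# Gene-by-cell expected expression rates (arbitrary units; normalised per
# cell before multinomial sampling). Exposed to tests through the optional
# "rates" assay: with rates as expression the planted structure is noise-free.
.sim_rates <- function(cfg, genes, truth, expressedTsas, otherBase) {
  ids <- genes$ids
  n <- nrow(truth)
  base <- numeric(length(ids))
  names(base) <- ids
  base[genes$hk] <- 1.2
  base[genes$mito] <- 1.4
  base[genes$other] <- otherBase
  base[unlist(genes$popMarkers, use.names = FALSE)] <- 0.04
  base[unlist(genes$cyc, use.names = FALSE)] <- 0.15
  R <- matrix(base, length(ids), n, dimnames = list(ids, truth$cell_id))
  pop <- truth$population
  t <- ifelse(is.na(truth$pseudotime), 0, truth$pseudotime)
  onBranch <- pop %in% c("TAC-TEC", "Aire-positive", "Late-Aire",
                         "Ccl21a-high")
  for (pp in .TEC_POPULATIONS)
    R[genes$popMarkers[[pp]], pop == pp] <- 4
  # lineage-primed TAC-TECs already express their fate's markers at an
  # intermediate level (Aire- vs Ccl21a-primed sub-states)
  R[genes$popMarkers[["Aire-positive"]],
    pop == "TAC-TEC" & truth$branch == "Aire"] <- 1.5
  R[genes$popMarkers[["Ccl21a-high"]],
    pop == "TAC-TEC" & truth$branch == "Ccl21a"] <- 1.5
  # Ccl21a and Krt10 need genuinely high expression: quadrant cutoffs sit at
  # 4 and 2 on the log-normalised scale
  R["Ccl21a", ] <- 0.04
  R["Ccl21a", pop == "Ccl21a-high"] <- 45
  R["Ccl21a", pop == "TAC-TEC" & truth$branch == "Ccl21a"] <- 12
  R["Krt10", ] <- 0.02
  R["Krt10", truth$krt10_hi] <- 10
  R[genes$matAire, ] <- 0.1
  R[genes$matCcl, ] <- 0.1
  R[genes$matDn, ] <- 0.1
  brA <- onBranch & truth$branch == "Aire"
  brC <- onBranch & truth$branch == "Ccl21a"
  R[genes$matAire, brA] <- rep(0.1 + 3.0 * t[brA],
                               each = length(genes$matAire))
  R[genes$matCcl, brC] <- rep(0.1 + 3.0 * t[brC],
                              each = length(genes$matCcl))
  R[genes$matDn, onBranch] <- rep(0.1 + 3.0 * (1 - t[onBranch]),
                                  each = length(genes$matDn))
  for (ph in names(genes$cyc))
    R[genes$cyc[[ph]], truth$phase == ph] <- 2.5
  aireLineage <- pop %in% c("TAC-TEC", "Aire-positive", "Late-Aire") &
    truth$branch == "Aire"
  R["Aire", ] <- 0
  R["Aire", truth$aire_expressing] <- .aire_curve(t[truth$aire_expressing])
  R["Fezf2", ] <- 0
  fz <- pop %in% c("TAC-TEC", "Aire-positive", "Late-Aire")
  R["Fezf2", fz] <- .fezf2_curve(t[fz])
  R["Fezf2", pop == "Ccl21a-high"] <- 0.05
  R["ZsGreen", ] <- 0
  R["ZsGreen", truth$reporter_on] <- 5
  tsaIds <- unlist(genes$tsa, use.names = FALSE)
  R[tsaIds, ] <- 0
  for (j in seq_len(n)) {
    ex <- expressedTsas[[j]]
    if (length(ex)) R[ex, j] <- 0.43 * (0.6 + 0.8 * t[j])
  }
  R
}

.sim_counts <- function(rates, cfg) {
  n <- ncol(rates)
  libs <- pmax(1, round(stats::rlnorm(n, cfg$librarySizeLogMean,
                                      cfg$librarySizeLogSd)))
  iL <- vector("list", n); xL <- vector("list", n)
  for (j in seq_len(n)) {
    x <- stats::rmultinom(1, libs[j], rates[, j])[, 1]
    nz <- which(x > 0)
    iL[[j]] <- nz; xL[[j]] <- x[nz]
  }
  Matrix::sparseMatrix(i = unlist(iL),
                       j = rep.int(seq_len(n), lengths(iL)),
                       x = unlist(xL), dims = dim(rates),
                       dimnames = dimnames(rates))
}

.sim_gene_sets <- function(genes) {
  list(TSA = GeneSet("TSA", unlist(genes$tsa, use.names = FALSE)),
       Aire_dependent = GeneSet("Aire_dependent", genes$tsa$aire),
       Fezf2_dependent = GeneSet("Fezf2_dependent", genes$tsa$fezf2),
       housekeeping = GeneSet("housekeeping", genes$hk))
}

# ------------------------------------------------------------ entry points

#' Simulate a control mTEC dataset with full ground truth
#'
#' Draws one sample under the configuration and returns an
#' \linkS4class{mTECExperiment} whose \code{colData} carries the planted
#' truth (population, branch, pseudotime, phase, Aire onset, ever-Aire flag,
#' reporter state) and whose \code{metadata} carries the gene sets actually
#' used (TSA, Aire-dependent, Fezf2-dependent, housekeeping), the per-cell
#' expressed-TSA sets, the cell-cycle marker pairs and the configuration.
#' Truth is planted before counts are drawn, so it is independent of the
#' count realisation.
#'
#' @param config a \code{\link{simConfig}}.
#' @param keepRates keep the noise-free gene-by-cell rate matrix as an extra
#'   assay \code{"rates"} (useful for noise-free oracles).
#' @return an \code{mTECExperiment}.
#' @examples
#' sce <- simulateDataset(simConfig(nCellsPerSample = 100, seed = 7))
#' table(sce$population)
#' @export
simulateDataset <- function(config, keepRates = FALSE) {
  stopifnot(inherits(config, "SimConfig"))
  .with_seed(config$seed, {
    genes <- .sim_genes(config)
    otherBase <- stats::rlnorm(length(genes$other), log(0.25), 0.5)
    st <- .sim_truth(config, "control",
                     c("TAC-TEC" = 1, "Aire-positive" = 1, "Late-Aire" = 1),
                     1, genes)
    rates <- .sim_rates(config, genes, st$truth, st$expressedTsas, otherBase)
    counts <- .sim_counts(rates, config)
    se <- mTECExperiment(counts, cellData = st$truth,
                         geneSets = .sim_gene_sets(genes),
                         truth = st$truth, expressedTsas = st$expressedTsas,
                         markerPairs = .cycle_pairs(config, min(20, length(genes$cyc$G1))),
                         config = config)
    if (keepRates)
      SummarizedExperiment::assay(se, "rates") <-
        methods::as(methods::as(rates, "generalMatrix"), "CsparseMatrix")
    se
  })
}

#' Simulate an ablation/recovery time course
#'
#' Draws every sample named in \code{config$samples} (at least two, e.g.
#' \code{\link{ablationPreset}}) and concatenates them. Per-sample Aire-branch
#' population counts follow the configured depletion factors while
#' Ccl21a-branch absolute counts are identical across timepoints; TSA
#' activation follows the per-sample activity multiplier.
#'
#' @inheritParams simulateDataset
#' @return an \code{mTECExperiment} with a \code{sample} column ordered as in
#'   the configuration.
#' @export
simulateTimecourse <- function(config, keepRates = FALSE) {
  stopifnot(inherits(config, "SimConfig"))
  if (is.null(config$samples) || length(config$samples) < 2)
    stop("a time course needs >= 2 configured samples", call. = FALSE)
  .with_seed(config$seed, {
    genes <- .sim_genes(config)
    otherBase <- stats::rlnorm(length(genes$other), log(0.25), 0.5)
    parts <- lapply(names(config$samples), function(nm) {
      s <- config$samples[[nm]]
      st <- .sim_truth(config, nm, s$depletion, s$tsaActivity, genes)
      rates <- .sim_rates(config, genes, st$truth, st$expressedTsas, otherBase)
      list(counts = .sim_counts(rates, config), truth = st$truth,
           expressedTsas = st$expressedTsas)
    })
    counts <- do.call(cbind, lapply(parts, `[[`, "counts"))
    truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
    truth$sample <- factor(truth$sample, levels = names(config$samples))
    expressedTsas <- do.call(c, lapply(parts, `[[`, "expressedTsas"))
    mTECExperiment(counts, cellData = truth,
                   geneSets = .sim_gene_sets(genes), truth = truth,
                   expressedTsas = expressedTsas,
                   markerPairs = .cycle_pairs(config, min(20, length(genes$cyc$G1))),
                   config = config)
  })
}

#' Reporter intensity from planted truth
#'
#' Recomputes the per-cell lineage-reporter rate for an arbitrary lag: a cell
#' is reporter-positive iff it has entered an Aire-expressing state
#' (\code{ever_aire}) and its Aire onset precedes its current pseudotime by
#' at least \code{lag}. With \code{lag = 0} every Aire-experienced cell is
#' positive; a lag of a full pseudotime unit silences the reporter entirely.
#'
#' @param truth a truth table (\code{simTruth} of a simulated experiment)
#'   with columns \code{pseudotime}, \code{aire_onset}.
#' @param lag non-negative pseudotime lag.
#' @param intensity rate given to reporter-positive cells.
#' @return numeric vector of reporter rates, named by cell.
#' @export
simulateReporter <- function(truth, lag, intensity = 5) {
  if (!is.numeric(lag) || length(lag) != 1 || is.na(lag) || lag < 0)
    stop("'lag' must be a single non-negative number", call. = FALSE)
  t <- truth$pseudotime
  onset <- truth$aire_onset
  on <- !is.na(onset) & !is.na(t) & (t - onset >= lag)
  stats::setNames(ifelse(on, intensity, 0), truth$cell_id)
}

#' Simulate a gene-by-tissue detection table
#'
#' Emulates a peripheral-tissue expression atlas for TSA curation: genes in
#' \code{tsaIds} are detected in a uniformly random 1--5 tissues, all other
#' genes in more than 5; genes are protein-coding unless listed in
#' \code{nonCodingIds}.
#'
#' @param geneIds all gene identifiers.
#' @param nTissues total number of tissues (> 5).
#' @param tsaIds subset of \code{geneIds} to plant as tissue-restricted.
#' @param seed integer seed.
#' @param nonCodingIds genes flagged as non-coding.
#' @return data.frame with columns \code{gene_id}, \code{detected_tissues},
#'   \code{protein_coding}.
#' @export
simulateTissueTable <- function(geneIds, nTissues, tsaIds, seed = 1L,
                                nonCodingIds = character()) {
  if (nTissues <= 5) stop("nTissues must exceed 5", call. = FALSE)
  if (!all(tsaIds %in% geneIds))
    stop("tsaIds must be a subset of geneIds", call. = FALSE)
  .with_seed(seed, {
    isTsa <- geneIds %in% tsaIds
    det <- integer(length(geneIds))
    det[isTsa] <- sample(1:5, sum(isTsa), replace = TRUE)
    det[!isTsa] <- sample(6:nTissues, sum(!isTsa), replace = TRUE)
    data.frame(gene_id = geneIds, detected_tissues = det,
               protein_coding = !(geneIds %in% nonCodingIds))
  })
}

.cycle_pairs <- function(cfg, nPairsPerPhase) {
  nCyc <- cfg$genePartition["cycle"] / 3
  if (nPairsPerPhase < 1 || nPairsPerPhase > nCyc)
    stop("nPairsPerPhase must be in 1..", nCyc, " (cycle genes per phase)",
         call. = FALSE)
  i <- seq_len(nPairsPerPhase)
  partner <- function() sample(seq_len(nCyc))[i]
  # gene_a is the phase's own marker; gene_b belongs to the phase whose
  # markers are off both in this phase and in the third one, so the pair
  # inequality reverses inside gene_b's phase and vanishes elsewhere
  rbind(
    data.frame(phase = "G1", gene_a = sprintf("Cc.G1.%02d", i),
               gene_b = sprintf("Cc.S.%02d", partner())),
    data.frame(phase = "S", gene_a = sprintf("Cc.S.%02d", i),
               gene_b = sprintf("Cc.G1.%02d", partner())),
    data.frame(phase = "G2M", gene_a = sprintf("Cc.G2M.%02d", i),
               gene_b = sprintf("Cc.S.%02d", partner())))
}

#' Simulate cell-cycle marker pairs
#'
#' Emits per-phase (gene_a, gene_b) pairs consistent with the generator's
#' rate model: within each phase gene_a's rate exceeds gene_b's, and the
#' inequality reverses (or both genes are off) outside it.
#'
#' @param nPairsPerPhase pairs per phase (at most the per-phase cycle-gene
#'   count of \code{config}).
#' @param seed integer seed.
#' @param config a \code{\link{simConfig}} fixing the cycle-gene catalogue.
#' @return data.frame with columns \code{phase}, \code{gene_a},
#'   \code{gene_b}.
#' @export
simulateCyclePairs <- function(nPairsPerPhase, seed = 1L,
                               config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  .with_seed(seed, .cycle_pairs(config, nPairsPerPhase))
}
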