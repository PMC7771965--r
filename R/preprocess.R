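# QC filtering, log-normalisation, variable-gene selection, embedding and
# clustering plumbing, and the two down-sampling procedures (UMIs within a
# matrix, whole cells).

#' Quality-control filtering of cells and genes
#'
#' Keeps cells whose detected-gene count lies in
#' \code{[minGenes, maxGenes]} (closed interval) and whose mitochondrial UMI
#' fraction is at most \code{maxMitoFraction}; then keeps genes detected
#' (count > 0) in at least \code{minCellsPerGene} of the retained cells.
#' Gene and cell order is preserved. Mitochondrial genes are identified by a
#' configurable identifier prefix (mouse convention \code{"mt-"}) unless an
#' explicit vector is given.
#'
#' @param m genes x cells count matrix (or \code{mTECExperiment}).
#' @param minGenes,maxGenes closed bounds on detected genes per cell.
#' @param maxMitoFraction maximum mitochondrial count fraction per cell.
#' @param minCellsPerGene minimum retained cells a gene must be detected in.
#' @param mitoGenes explicit mitochondrial gene identifiers; \code{NULL}
#'   means every gene whose identifier starts with \code{mitoPrefix}.
#' @param mitoPrefix identifier prefix marking mitochondrial genes.
#' @return filtered count matrix (\code{dgCMatrix}).
#' @export
filterQC <- function(m, minGenes = 200, maxGenes = 7500,
                     maxMitoFraction = 0.10, minCellsPerGene = 3,
                     mitoGenes = NULL, mitoPrefix = "mt-") {
  m <- .as_counts(m)
  if (minGenes >= maxGenes) stop("minGenes must be < maxGenes", call. = FALSE)
  if (maxMitoFraction < 0 || maxMitoFraction > 1)
    stop("maxMitoFraction must lie in [0, 1]", call. = FALSE)
  if (is.null(mitoGenes)) mitoGenes <- grep(paste0("^", mitoPrefix),
                                            rownames(m), value = TRUE)
  mitoGenes <- intersect(mitoGenes, rownames(m))
  detected <- Matrix::colSums(m > 0)
  totals <- Matrix::colSums(m)
  mito <- if (length(mitoGenes))
    Matrix::colSums(m[mitoGenes, , drop = FALSE]) else numeric(ncol(m))
  mitoFrac <- ifelse(totals > 0, mito / totals, 0)
  keepCells <- detected >= minGenes & detected <= maxGenes &
    mitoFrac <= maxMitoFraction
  if (!any(keepCells))
    stop("QC filtering removed every cell", call. = FALSE)
  m <- m[, keepCells, drop = FALSE]
  keepGenes <- Matrix::rowSums(m > 0) >= minCellsPerGene
  m[keepGenes, , drop = FALSE]
}

#' Library-size log-normalisation
#'
#' \code{value(g, c) = ln(1 + scaleFactor * count(g, c) / total(c))}
#' (natural log). A cell's normalised vector is invariant to rescaling its
#' raw counts by a positive constant.
#'
#' @param m genes x cells count matrix.
#' @param scaleFactor positive scale (default 1000).
#' @return sparse genes x cells matrix of normalised log expression.
#' @examples
#' m <- Matrix::sparseMatrix(1, 1, x = 10, dims = c(2, 1),
#'                           dimnames = list(c("a", "b"), "c1"))
#' m["b", 1] <- 990
#' logNormalize(m)["a", 1]  # ln(11)
#' @export
logNormalize <- function(m, scaleFactor = 1000) {
  m <- .as_counts(m)
  if (scaleFactor <= 0) stop("scaleFactor must be positive", call. = FALSE)
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    stop("cells with zero total counts cannot be normalised", call. = FALSE)
  out <- m
  if (length(out@x))
    out@x <- log1p(scaleFactor * out@x /
                     rep.int(totals, diff(out@p)))
  out
}

#' Mean/dispersion variable-gene selection
#'
#' Computes per-gene mean and dispersion of \code{exp(value) - 1} (the
#' de-logged normalised expression), where dispersion is
#' \code{log(variance/mean)}; z-scores dispersion within equal-width bins of
#' the mean and returns genes whose mean lies strictly inside
#' \code{(meanLow, meanHigh)} and whose binned dispersion z-score is at least
#' \code{dispersionMin}.
#'
#' @param nm normalised log-expression matrix.
#' @param meanLow,meanHigh exclusive bounds on the de-logged mean
#'   (defaults 0.0125 and 3).
#' @param dispersionMin minimum binned dispersion z-score (default 0.5).
#' @param nBins number of equal-width mean bins (default 20; reduced with a
#'   warning when there are fewer genes than bins).
#' @return character vector of selected gene identifiers.
#' @export
selectVariableGenes <- function(nm, meanLow = 0.0125, meanHigh = 3,
                                dispersionMin = 0.5, nBins = 20) {
  nm <- .as_values(nm)
  if (ncol(nm) < 2) stop("need at least 2 cells", call. = FALSE)
  if (nrow(nm) < nBins) {
    warning("fewer genes than bins; reducing to ", nrow(nm), " bins")
    nBins <- nrow(nm)
  }
  ex <- expm1(as.matrix(nm))
  mu <- rowMeans(ex)
  v <- apply(ex, 1, stats::var)
  disp <- ifelse(mu > 0 & v > 0, log(v / mu), NA_real_)
  bins <- cut(mu, breaks = nBins, include.lowest = TRUE)
  z <- rep(NA_real_, length(mu))
  for (b in levels(bins)) {
    i <- which(bins == b & !is.na(disp))
    if (!length(i)) next
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  rownames(nm)[!is.na(z) & mu > meanLow & mu < meanHigh & z >= dispersionMin]
}

#' PCA embedding with a fixed sign convention
#'
#' Centred (optionally unit-variance) principal components of cells over the
#' chosen genes. The embedding is deterministic: each component's sign is
#' fixed so that its largest-magnitude gene loading is positive.
#'
#' @param nm normalised log-expression matrix.
#' @param genes gene identifiers to use (e.g. variable genes).
#' @param nComponents number of components
#'   (\code{1 <= nComponents <= min(|genes|, nCells) - 1}).
#' @param scale. divide genes by their standard deviation (zero-variance
#'   genes are dropped).
#' @return cells x components score matrix.
#' @export
embedPCA <- function(nm, genes = rownames(nm), nComponents = 10,
                     scale. = TRUE) {
  nm <- .as_values(nm)
  genes <- intersect(genes, rownames(nm))
  if (!length(genes)) stop("no usable genes", call. = FALSE)
  x <- t(as.matrix(nm[genes, , drop = FALSE]))
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    x <- x[, sds > 0, drop = FALSE]
  }
  if (nComponents < 1 || nComponents > min(dim(x)) - 1)
    stop("nComponents must lie in 1..min(genes, cells)-1", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = scale., rank. = nComponents)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  scores <- sweep(pc$x, 2, flip, `*`)
  rownames(scores) <- colnames(nm)
  scores
}

#' Deterministic k-means clustering of embedded cells
#'
#' Clustering is pluggable throughout the package (any per-cell label vector
#' is accepted downstream); the built-in method is k-means on embedding
#' coordinates under a fixed seed, returning integer labels \code{0..k-1}.
#'
#' @param coords cells x components coordinate matrix.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param nstart random restarts passed to \code{\link[stats]{kmeans}}.
#' @return integer cluster labels named by cell.
#' @export
clusterCells <- function(coords, k, seed = 1L, nstart = 10) {
  if (k < 1 || k > nrow(coords))
    stop("k must lie in 1..number of cells", call. = FALSE)
  .with_seed(seed, {
    km <- stats::kmeans(coords, centers = k, nstart = nstart, iter.max = 100)
    stats::setNames(km$cluster - 1L, rownames(coords))
  })
}

#' Down-sample UMIs to an exact target total
#'
#' Samples \code{targetTotal} molecules uniformly without replacement from
#' the multiset of all molecules in the matrix (multivariate hypergeometric),
#' so the output total equals the target exactly and each entry's
#' expectation is \code{count * targetTotal / total}. Used to equalise
#' sequencing depth between samples before detection statistics.
#'
#' @param m genes x cells count matrix.
#' @param targetTotal number of molecules to keep
#'   (\code{0 <= targetTotal <= sum(m)}).
#' @param seed integer seed.
#' @return down-sampled count matrix of identical shape and dimnames.
#' @export
downsampleUmis <- function(m, targetTotal, seed = 1L) {
  m <- .as_counts(m)
  total <- sum(m)
  .stopifnot_scalar(targetTotal, "targetTotal")
  if (targetTotal < 0 || targetTotal > total)
    stop("targetTotal must lie in 0..", total, call. = FALSE)
  if (targetTotal == total) return(m)
  tr <- Matrix::summary(m)
  bounds <- cumsum(tr$x)
  keep <- .with_seed(seed, sample.int(total, targetTotal))
  hit <- findInterval(keep - 1L, c(0, bounds), rightmost.closed = FALSE)
  newx <- tabulate(hit, nbins = nrow(tr))
  nz <- newx > 0
  Matrix::sparseMatrix(i = tr$i[nz], j = tr$j[nz], x = newx[nz],
                       dims = dim(m), dimnames = dimnames(m))
}

#' Subsample cells without replacement
#'
#' @param m genes x cells count matrix.
#' @param n number of cells to keep (\code{1 <= n <= nCells}).
#' @param seed integer seed.
#' @return matrix restricted to a uniform sample of \code{n} columns; gene
#'   order unchanged.
#' @export
subsampleCells <- function(m, n, seed = 1L) {
  m <- .as_counts(m)
  if (n < 1 || n > ncol(m))
    stop("n must lie in 1..", ncol(m), call. = FALSE)
  cols <- .with_seed(seed, sample.int(ncol(m), n))
  m[, cols, drop = FALSE]
}

#' Housekeeping-gene dropout fractions
#'
#' Fraction of cells with a zero count for each listed gene; used to verify
#' that UMI down-sampling equalised dropout between samples.
#'
#' @param m genes x cells count matrix.
#' @param genes a \linkS4class{GeneSet} or character vector (e.g. Chmp2a,
#'   Emc7, Psmb4, Vcp, Gapdh).
#' @return named numeric vector of dropout fractions.
#' @export
housekeepingDropout <- function(m, genes) {
  m <- .as_counts(m)
  ids <- if (is(genes, "GeneSet")) geneIds(genes) else genes
  ids <- intersect(ids, rownames(m))
  if (!length(ids))
    stop("none of the listed genes are present", call. = FALSE)
  apply(m[ids, , drop = FALSE] == 0, 1, mean)
}
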