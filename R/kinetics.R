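# Gene-set kinetics: per-cell percent-of-set and mean-expression statistics,
# per-sample cumulative detection fractions, genes-per-cell counts, the
# ablation-recovery detection curve (with UMI-depth equalisation), and the
# cell-subsampling null distribution with z-score p-value.

.set_ids <- function(m, s) {
  ids <- if (is(s, "GeneSet")) geneIds(s) else as.character(s)
  ids <- intersect(ids, rownames(m))
  if (!length(ids))
    stop("gene set has no members in the matrix", call. = FALSE)
  ids
}

#' Percent of a gene set expressed per cell
#'
#' For each cell, the number of set members with a count above zero divided
#' by the number of set members present in the matrix (the per-cell TSA
#' mosaic statistic: mature mTECs express only a few percent of all TSAs).
#'
#' @param m genes x cells count matrix.
#' @param s a \linkS4class{GeneSet} or character vector.
#' @return numeric vector in [0, 1], named by cell.
#' @export
percentSetPerCell <- function(m, s) {
  m <- .as_counts(m)
  ids <- .set_ids(m, s)
  Matrix::colSums(m[ids, , drop = FALSE] > 0) / length(ids)
}

#' Mean gene-set expression per cell
#'
#' Total normalised expression over the set divided either by the full set
#' size (\code{mode = "all"}) or by the number of expressed members
#' (\code{mode = "expressed_only"}; 0 when no member is expressed). The two
#' modes separate "more genes on" from "each gene higher".
#'
#' @param nm normalised log-expression matrix.
#' @param s a \linkS4class{GeneSet} or character vector.
#' @param mode \code{"all"} or \code{"expressed_only"}.
#' @return numeric vector named by cell.
#' @export
meanSetExpression <- function(nm, s, mode = c("all", "expressed_only")) {
  nm <- .as_values(nm)
  mode <- match.arg(mode)
  ids <- .set_ids(nm, s)
  sub <- nm[ids, , drop = FALSE]
  tot <- Matrix::colSums(sub)
  if (mode == "all") return(tot / length(ids))
  nExpr <- Matrix::colSums(sub > 0)
  ifelse(nExpr > 0, tot / nExpr, 0)
}

#' Cumulative fraction of a gene set detected in a cell subset
#'
#' A gene counts as detected when at least one selected cell has a count
#' above zero; the fraction is over set members present in the matrix.
#' Monotone non-decreasing in the cell subset.
#'
#' @param m genes x cells count matrix.
#' @param s a \linkS4class{GeneSet} or character vector.
#' @param cells cell identifiers/indices to use (default all).
#' @param sample,setName labels copied into the output.
#' @return one-row data.frame: \code{sample}, \code{set_name},
#'   \code{n_cells}, \code{n_detected_genes}, \code{fraction_detected}.
#' @export
cumulativeFractionDetected <- function(m, s, cells = colnames(m),
                                       sample = NA_character_,
                                       setName = NULL) {
  m <- .as_counts(m)
  if (!length(cells)) stop("empty cell subset", call. = FALSE)
  ids <- .set_ids(m, s)
  det <- Matrix::rowSums(m[ids, cells, drop = FALSE] > 0) > 0
  data.frame(sample = sample,
             set_name = if (!is.null(setName)) setName
                        else if (is(s, "GeneSet")) setName(s) else "set",
             n_cells = length(cells), n_detected_genes = sum(det),
             fraction_detected = mean(det))
}

#' Number of expressed gene-set members per cell
#'
#' Integer count of set members with a count above zero in each cell; equals
#' \code{\link{percentSetPerCell}} times the set size exactly.
#'
#' @inheritParams percentSetPerCell
#' @return integer vector named by cell.
#' @export
genesPerCell <- function(m, s) {
  m <- .as_counts(m)
  ids <- .set_ids(m, s)
  as.integer(Matrix::colSums(m[ids, , drop = FALSE] > 0))
}

#' Gene-set detection across an ablation/recovery time course
#'
#' Per-timepoint cumulative detection fractions of a gene set restricted to
#' one population, after equalising sequencing depth: each sample's matrix
#' is down-sampled (multivariate hypergeometric,
#' \code{\link{downsampleUmis}}) to the smallest per-sample UMI total before
#' detection is measured, so differences reflect expression, not depth.
#'
#' @param m genes x cells count matrix covering all samples.
#' @param cellData per-cell data with columns \code{sample} and
#'   \code{population} (e.g. \code{colData} of a simulated time course).
#' @param s a \linkS4class{GeneSet} or character vector.
#' @param population population to restrict to (e.g. "Aire-positive").
#' @param equalize down-sample every sample to the minimum total first.
#' @param seed integer seed for the down-sampling.
#' @return data.frame with one row per sample (in factor/appearance order);
#'   samples with no cells in the population get \code{NA} fractions with a
#'   warning.
#' @export
recoveryCurve <- function(m, cellData, s, population, equalize = TRUE,
                          seed = 1L) {
  m <- .as_counts(m)
  if (!all(c("sample", "population") %in% names(cellData)))
    stop("cellData needs 'sample' and 'population' columns", call. = FALSE)
  if (nrow(cellData) != ncol(m))
    stop("cellData must have one row per cell of m", call. = FALSE)
  samples <- if (is.factor(cellData$sample)) levels(cellData$sample)
             else unique(as.character(cellData$sample))
  mats <- lapply(samples, function(sm)
    m[, as.character(cellData$sample) == sm, drop = FALSE])
  names(mats) <- samples
  if (equalize) {
    totals <- vapply(mats, sum, numeric(1))
    target <- min(totals)
    mats <- lapply(seq_along(mats), function(i)
      downsampleUmis(mats[[i]], target, seed = seed + i))
    names(mats) <- samples
  }
  rows <- lapply(samples, function(sm) {
    inPop <- as.character(cellData$sample) == sm &
      !is.na(cellData$population) & cellData$population == population
    cells <- colnames(m)[inPop]
    if (!length(cells)) {
      warning("sample '", sm, "' has no '", population, "' cells")
      return(data.frame(sample = sm, set_name = NA, n_cells = 0L,
                        n_detected_genes = NA_integer_,
                        fraction_detected = NA_real_))
    }
    cumulativeFractionDetected(mats[[sm]], s, cells = cells, sample = sm)
  })
  do.call(rbind, rows)
}

#' Cell-subsampling null distribution for a detection fraction
#'
#' Builds the null distribution of the cumulative detection fraction by
#' repeatedly subsampling \code{nCells} cells (without replacement) from a
#' reference matrix, and scores an observed fraction with
#' \code{z = (observed - mean)/sd} and a normal-tail p-value (default
#' lower tail: a test for depletion; the paper's direction of interest).
#' When the null is degenerate (sd = 0) the p-value is 1 if the observation
#' is at or above the null mean and 0 otherwise.
#'
#' @param reference genes x cells count matrix (e.g. control sample).
#' @param s a \linkS4class{GeneSet} or character vector.
#' @param nCells cells per replicate (at most the reference cell count).
#' @param observedFraction the fraction to score.
#' @param nReps replicates (default 1000; at least 2).
#' @param seed integer seed.
#' @param alternative \code{"less"} (default), \code{"greater"} or
#'   \code{"two.sided"}.
#' @return list of class \code{SubsampleNull}: \code{n_reps},
#'   \code{replicate_values}, \code{observed}, \code{mean}, \code{sd},
#'   \code{z}, \code{p_value}.
#' @export
subsampleNull <- function(reference, s, nCells, observedFraction,
                          nReps = 1000, seed = 1L,
                          alternative = c("less", "greater", "two.sided")) {
  reference <- .as_counts(reference)
  alternative <- match.arg(alternative)
  if (nReps < 2) stop("nReps must be at least 2", call. = FALSE)
  if (nCells < 1 || nCells > ncol(reference))
    stop("nCells must lie in 1..", ncol(reference), call. = FALSE)
  ids <- .set_ids(reference, s)
  sub <- reference[ids, , drop = FALSE] > 0
  sub <- methods::as(sub, "CsparseMatrix") * 1
  reps <- .with_seed(seed, vapply(seq_len(nReps), function(r) {
    cols <- sample.int(ncol(sub), nCells)
    mean(Matrix::rowSums(sub[, cols, drop = FALSE]) > 0)
  }, numeric(1)))
  mu <- mean(reps); sdv <- stats::sd(reps)
  if (sdv == 0) {
    z <- if (observedFraction == mu) 0
         else sign(observedFraction - mu) * Inf
    p <- switch(alternative,
                less = if (observedFraction >= mu) 1 else 0,
                greater = if (observedFraction <= mu) 1 else 0,
                two.sided = if (observedFraction == mu) 1 else 0)
  } else {
    z <- (observedFraction - mu) / sdv
    p <- switch(alternative,
                less = stats::pnorm(z),
                greater = stats::pnorm(z, lower.tail = FALSE),
                two.sided = 2 * stats::pnorm(-abs(z)))
  }
  structure(list(n_reps = nReps, replicate_values = reps,
                 observed = observedFraction, mean = mu, sd = sdv,
                 z = z, p_value = p, alternative = alternative),
            class = "SubsampleNull")
}

#' @export
print.SubsampleNull <- function(x, ...) {
  cat(sprintf(
    "SubsampleNull: %d reps, null %.4f +/- %.4f, observed %.4f, z = %.2f, p = %.3g (%s)\n",
    x$n_reps, x$mean, x$sd, x$observed, x$z, x$p_value, x$alternative))
  invisible(x)
}
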