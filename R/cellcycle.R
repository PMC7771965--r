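# Pair-based cell-cycle phase scoring: each phase is scored by the fraction
# of its marker pairs whose first gene is the more highly expressed within
# the cell, so scores depend only on within-cell expression order and are
# invariant to any monotone per-cell transformation.

#' Score and assign cell-cycle phases from marker pairs
#'
#' For each phase, \code{score = mean over usable pairs of [1 if
#' expr_a > expr_b, 0.5 if equal, 0 otherwise]}. Assignment: G1 when the G1
#' score reaches 0.5 and the G2/M score does not; G2/M symmetrically; when
#' both reach 0.5 the larger wins (ties go to S); otherwise S. Pairs with a
#' missing gene are dropped with a warning; a phase with no usable pair is
#' an error.
#'
#' @param nm normalised log-expression matrix (any per-cell monotone scale).
#' @param pairs data.frame with columns \code{phase}, \code{gene_a},
#'   \code{gene_b} (see \code{\link{readMarkerPairs}},
#'   \code{\link{simulateCyclePairs}}).
#' @return a \code{DataFrame} with columns \code{score_g1}, \code{score_s},
#'   \code{score_g2m} and \code{phase}, one row per cell.
#' @examples
#' nm <- matrix(c(3, 1, 0, 2), 4, 1,
#'              dimnames = list(c("a", "b", "c", "d"), "cell1"))
#' pairs <- data.frame(phase = c("G1", "S", "G2M"),
#'                     gene_a = c("a", "c", "c"), gene_b = c("b", "a", "d"))
#' scorePhases(nm, pairs)$phase  # "G1"
#' @export
scorePhases <- function(nm, pairs) {
  nm <- .as_values(nm)
  .check_marker_pairs(pairs)
  usable <- pairs$gene_a %in% rownames(nm) & pairs$gene_b %in% rownames(nm)
  if (any(!usable))
    warning(sum(!usable), " pairs dropped (gene not in matrix)")
  pairs <- pairs[usable, , drop = FALSE]
  score1 <- function(ph) {
    pp <- pairs[pairs$phase == ph, , drop = FALSE]
    if (!nrow(pp))
      stop("no usable pairs for phase ", ph, call. = FALSE)
    a <- as.matrix(nm[pp$gene_a, , drop = FALSE])
    b <- as.matrix(nm[pp$gene_b, , drop = FALSE])
    colMeans((a > b) + 0.5 * (a == b))
  }
  g1 <- score1("G1"); s <- score1("S"); g2m <- score1("G2M")
  phase <- ifelse(g1 >= 0.5 & g2m < 0.5, "G1",
           ifelse(g2m >= 0.5 & g1 < 0.5, "G2M",
           ifelse(g1 >= 0.5 & g2m >= 0.5,
                  ifelse(g1 > g2m, "G1", ifelse(g2m > g1, "G2M", "S")),
                  "S")))
  S4Vectors::DataFrame(score_g1 = g1, score_s = s, score_g2m = g2m,
                       phase = phase, row.names = colnames(nm))
}

#' Cluster-by-phase contingency summary
#'
#' Counts of scored cells per (cluster, phase) with row fractions (phase
#' composition within each cluster) and column fractions (how each phase
#' distributes over clusters; in the study design the G2/M column
#' concentrates in the TAC-TEC cluster).
#'
#' @param pa result of \code{\link{scorePhases}} (or any per-cell phase
#'   vector).
#' @param clusters per-cell cluster labels aligned with \code{pa}.
#' @return list with \code{counts} (cluster x phase matrix),
#'   \code{cluster_fraction} and \code{phase_fraction}.
#' @export
phaseByCluster <- function(pa, clusters) {
  phase <- if (is(pa, "DataFrame") || is.data.frame(pa)) pa$phase else pa
  if (length(phase) != length(clusters))
    stop("phase and cluster vectors must align", call. = FALSE)
  if (any(is.na(clusters)))
    stop("every scored cell needs a cluster label", call. = FALSE)
  counts <- table(cluster = clusters,
                  phase = factor(phase, levels = c("G1", "S", "G2M")))
  counts <- unclass(counts)
  list(counts = counts,
       cluster_fraction = counts / pmax(1, rowSums(counts)),
       phase_fraction = sweep(counts, 2, pmax(1, colSums(counts)), `/`))
}
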