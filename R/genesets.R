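# Gene-set curation (TSAs from tissue detection tables, knockout-dependent
# sets from differential-expression thresholds), Wilcoxon marker detection,
# the uniquely-upregulated filter, and hypergeometric overlap enrichment.

#' Curate tissue-specific antigens from a tissue detection table
#'
#' A gene is a TSA when it is detected in \code{maxTissues} or fewer
#' peripheral tissues and is protein-coding. Monotone in \code{maxTissues}.
#'
#' @param tissueTable data.frame with columns \code{gene_id},
#'   \code{detected_tissues}, \code{protein_coding}
#'   (see \code{\link{simulateTissueTable}}).
#' @param maxTissues inclusive tissue cutoff (default 5).
#' @param name name for the returned set.
#' @return a \linkS4class{GeneSet} (empty result gives a warning and a
#'   zero-length character member list is not allowed, so \code{NULL} is
#'   returned in that degenerate case).
#' @export
curateTsas <- function(tissueTable, maxTissues = 5, name = "TSA") {
  need <- c("gene_id", "detected_tissues", "protein_coding")
  if (!all(need %in% names(tissueTable)))
    stop("tissueTable needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(tissueTable)) stop("tissueTable is empty", call. = FALSE)
  if (anyDuplicated(tissueTable$gene_id))
    stop("one row per gene required", call. = FALSE)
  keep <- tissueTable$detected_tissues <= maxTissues &
    tissueTable$protein_coding
  if (!any(keep)) {
    warning("no gene satisfied the TSA criteria; returning NULL")
    return(NULL)
  }
  GeneSet(name, tissueTable$gene_id[keep])
}

#' Threshold a differential-expression table into a dependent-gene set
#'
#' Genes with \code{adjusted_p < maxAdjP} and \code{lfc > minLfc} (both
#' strict), the rule used to call knockout-dependent genes (e.g.
#' Fezf2-dependent genes from a Fezf2-knockout contrast).
#'
#' @param de data.frame with columns \code{gene}, \code{lfc} (natural-log
#'   fold change) and \code{adjusted_p}, as returned by
#'   \code{\link{deMarkers}}.
#' @param minLfc strict lower bound on the log fold change (default 1).
#' @param maxAdjP strict upper bound on the adjusted p-value (default 0.05).
#' @param name name for the returned set.
#' @return a \linkS4class{GeneSet}, or \code{NULL} when empty.
#' @export
thresholdDependentGenes <- function(de, minLfc = 1, maxAdjP = 0.05,
                                    name = "dependent") {
  if (!all(c("gene", "lfc", "adjusted_p") %in% names(de)))
    stop("de needs columns gene, lfc, adjusted_p", call. = FALSE)
  keep <- de$adjusted_p < maxAdjP & de$lfc > minLfc
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    warning("no gene passed the thresholds; returning NULL")
    return(NULL)
  }
  GeneSet(name, de$gene[keep])
}

# Wilcoxon rank-sum p-value: exact enumeration for small untied groups,
# normal approximation with tie correction (and continuity correction)
# otherwise -- the behaviour of standard implementations at these sizes.
.wilcox_p <- function(x, y, exactMax = 25) {
  n1 <- length(x); n2 <- length(y)
  if (n1 <= exactMax && n2 <= exactMax && !anyDuplicated(c(x, y))) {
    return(stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- (n1 * n2 / 12) *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sig2 == 0) return(1)
  z <- w - mu
  z <- sign(z) * max(0, abs(z) - 0.5)  # continuity correction
  min(1, 2 * stats::pnorm(-abs(z) / sqrt(sig2)))
}

# ln[(mean(expm1(x)) + 1) / (mean(expm1(y)) + 1)] -- fold change on the
# de-logged scale with unit pseudocount, natural log throughout.
.log_fc <- function(x, y) log((mean(expm1(x)) + 1) / (mean(expm1(y)) + 1))

#' Wilcoxon differential-expression marker detection
#'
#' Per-gene two-sided Wilcoxon rank-sum tests with Benjamini-Hochberg
#' adjustment across the tested genes of each contrast, and natural-log fold
#' changes of de-logged means. Contrasts are either each group against all
#' remaining cells (\code{"one_vs_rest"}) or all ordered group pairs
#' (\code{"pairwise"}).
#'
#' @param nm normalised log-expression matrix.
#' @param labels per-cell group labels aligned with the columns of
#'   \code{nm}.
#' @param contrast \code{"one_vs_rest"} (default) or \code{"pairwise"}.
#' @param minLfc,maxAdjP thresholds (strict) recorded in the
#'   \code{significant} column; defaults 1 and 0.05.
#' @param exactMax largest group size for exact Wilcoxon enumeration.
#' @return data.frame with columns \code{gene}, \code{group},
#'   \code{versus}, \code{lfc}, \code{p_value}, \code{adjusted_p},
#'   \code{significant}.
#' @export
deMarkers <- function(nm, labels, contrast = c("one_vs_rest", "pairwise"),
                      minLfc = 1, maxAdjP = 0.05, exactMax = 25) {
  nm <- .as_values(nm)
  contrast <- match.arg(contrast)
  if (length(labels) != ncol(nm))
    stop("labels must align with the cells", call. = FALSE)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (any(table(labels) < 3))
    stop("every group needs at least 3 cells", call. = FALSE)
  dense <- as.matrix(nm)
  runContrast <- function(g, versus, selA, selB) {
    a <- dense[, selA, drop = FALSE]; b <- dense[, selB, drop = FALSE]
    p <- vapply(seq_len(nrow(dense)),
                function(i) .wilcox_p(a[i, ], b[i, ], exactMax), numeric(1))
    lfc <- vapply(seq_len(nrow(dense)),
                  function(i) .log_fc(a[i, ], b[i, ]), numeric(1))
    adj <- stats::p.adjust(p, method = "BH")
    data.frame(gene = rownames(dense), group = g, versus = versus,
               lfc = lfc, p_value = p, adjusted_p = adj,
               significant = adj < maxAdjP & lfc > minLfc,
               row.names = NULL)
  }
  out <- if (contrast == "one_vs_rest") {
    do.call(rbind, lapply(groups, function(g)
      runContrast(g, "rest", labels == g, labels != g)))
  } else {
    prs <- utils::combn(groups, 2, simplify = FALSE)
    do.call(rbind, lapply(prs, function(pr) rbind(
      runContrast(pr[1], pr[2], labels == pr[1], labels == pr[2]),
      runContrast(pr[2], pr[1], labels == pr[2], labels == pr[1]))))
  }
  out
}

#' Genes upregulated in one cluster and no other
#'
#' Set difference of the focus cluster's upregulated genes against the union
#' of every other cluster's (the rule behind the TAC-TEC-unique signature).
#'
#' @param deByCluster named list mapping cluster to its upregulated genes
#'   (\linkS4class{GeneSet}s or character vectors), e.g. built from the
#'   \code{significant} rows of \code{\link{deMarkers}}.
#' @param focusCluster name of the cluster of interest.
#' @return character vector of uniquely upregulated genes (possibly empty).
#' @export
uniqueUpregulated <- function(deByCluster, focusCluster) {
  if (!focusCluster %in% names(deByCluster))
    stop("focusCluster not present", call. = FALSE)
  ids <- function(g) if (is(g, "GeneSet")) geneIds(g) else as.character(g)
  others <- unlist(lapply(deByCluster[setdiff(names(deByCluster),
                                              focusCluster)], ids))
  setdiff(ids(deByCluster[[focusCluster]]), others)
}

#' Hypergeometric gene-set overlap enrichment
#'
#' Upper-tail probability \code{P(X >= k)} for
#' \code{X ~ Hypergeometric(N, K, n)} -- the chance of observing at least
#' \code{k} genes shared between a set of \code{n} and a set of \code{K}
#' drawn from a universe of \code{N} -- computed in log space, together with
#' the fold enrichment \code{(k/n) / (K/N)}. Identical to the one-sided
#' Fisher exact test on the induced 2x2 table.
#'
#' @param k observed overlap.
#' @param n size of the first set (e.g. cluster-unique genes).
#' @param K size of the second set (e.g. a published signature).
#' @param N universe size (e.g. all genes tested).
#' @return list with \code{p_value}, \code{log_p} (natural log) and
#'   \code{fold_enrichment}.
#' @examples
#' hypergeomEnrichment(k = 2, n = 3, K = 4, N = 10)$p_value  # 1/3
#' @export
hypergeomEnrichment <- function(k, n, K, N) {
  for (v in c(k, n, K, N)) .stopifnot_scalar(v, "count")
  if (k < 0 || n < 0 || K < 0 || k > min(n, K) || n > N || K > N)
    stop("inconsistent counts: need k <= min(n, K) and n, K <= N",
         call. = FALSE)
  logp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  list(p_value = exp(logp), log_p = logp,
       fold_enrichment = if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_)
}
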