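# Population annotation: majority-vote label transfer from reference cells
# shared with each cluster, reporter/marker quadrant frequencies at fixed
# cutoffs, and per-sample population proportions.

#' Transfer population labels to clusters by reference-cell majority
#'
#' Each cluster receives the majority label among its reference-labelled
#' members (unlabelled cells do not dilute the vote); clusters without any
#' labelled member are \code{"unassigned"}; exact ties are broken
#' lexicographically and flagged.
#'
#' @param clusters per-cell cluster labels.
#' @param referenceLabels per-cell reference labels aligned with
#'   \code{clusters}; \code{NA} for cells outside the reference sample.
#' @return data.frame with one row per cluster: \code{cluster},
#'   \code{label}, \code{n_labeled}, \code{tie}; plus a \code{cell_labels}
#'   attribute giving the transferred per-cell labels.
#' @export
transferLabels <- function(clusters, referenceLabels) {
  if (length(clusters) != length(referenceLabels))
    stop("clusters and referenceLabels must align", call. = FALSE)
  if (all(is.na(referenceLabels)))
    stop("no reference-labelled cells", call. = FALSE)
  cl <- as.character(clusters)
  out <- lapply(sort(unique(cl)), function(g) {
    labs <- referenceLabels[cl == g & !is.na(referenceLabels)]
    if (!length(labs))
      return(data.frame(cluster = g, label = "unassigned", n_labeled = 0L,
                        tie = FALSE))
    tab <- sort(table(labs), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    data.frame(cluster = g, label = sort(top)[1], n_labeled = length(labs),
               tie = length(top) > 1)
  })
  out <- do.call(rbind, out)
  attr(out, "cell_labels") <- out$label[match(cl, out$cluster)]
  out
}

#' Reporter/marker quadrant frequencies
#'
#' Classifies cells by two genes at fixed cutoffs on the normalised log
#' scale -- positive means strictly above the cutoff, so a cutoff of 0
#' equals "any count detected" -- and reports per-group fractions for the
#' four quadrants in the order
#' (x+, y+), (x+, y-), (x-, y+), (x-, y-). Fractions sum to 1 per group;
#' empty groups are recorded as missing.
#'
#' @param nm normalised log-expression matrix.
#' @param geneX,geneY gene identifiers (e.g. ZsGreen and Ccl21a).
#' @param cutoffX,cutoffY strict positivity cutoffs (e.g. 0 and 4).
#' @param groups per-cell group labels (populations); default one group.
#' @return matrix groups x 4 with columns \code{double_positive},
#'   \code{x_only}, \code{y_only}, \code{double_negative}.
#' @export
quadrantFrequencies <- function(nm, geneX, geneY, cutoffX = 0, cutoffY = 0,
                                groups = NULL) {
  nm <- .as_values(nm)
  for (g in c(geneX, geneY))
    if (!g %in% rownames(nm)) stop("gene '", g, "' absent", call. = FALSE)
  if (is.null(groups)) groups <- rep("all", ncol(nm))
  if (length(groups) != ncol(nm))
    stop("groups must align with cells", call. = FALSE)
  x <- as.numeric(nm[geneX, ]) > cutoffX
  y <- as.numeric(nm[geneY, ]) > cutoffY
  lvls <- unique(as.character(groups))
  out <- matrix(NA_real_, length(lvls), 4,
                dimnames = list(lvls, c("double_positive", "x_only",
                                        "y_only", "double_negative")))
  for (g in lvls) {
    sel <- as.character(groups) == g
    n <- sum(sel)
    if (n == 0) next
    out[g, ] <- c(sum(x[sel] & y[sel]), sum(x[sel] & !y[sel]),
                  sum(!x[sel] & y[sel]), sum(!x[sel] & !y[sel])) / n
  }
  out
}

#' Population proportions per sample
#'
#' Row-stochastic sample x population fraction table; cells with an
#' unassigned population are excluded and their count reported via the
#' \code{n_excluded} attribute.
#'
#' @param cellData per-cell data with columns \code{sample} and
#'   \code{population}.
#' @return matrix of fractions (rows sum to 1) with attribute
#'   \code{n_excluded}.
#' @export
proportionsBySample <- function(cellData) {
  if (!all(c("sample", "population") %in% names(cellData)))
    stop("cellData needs 'sample' and 'population' columns", call. = FALSE)
  ok <- !is.na(cellData$population)
  nExcl <- sum(!ok)
  if (nExcl) message(nExcl, " cells without population excluded")
  tab <- table(sample = as.character(cellData$sample)[ok],
               population = as.character(cellData$population)[ok])
  smp <- cellData$sample
  if (is.factor(smp)) tab <- tab[intersect(levels(smp), rownames(tab)), ,
                                 drop = FALSE]
  out <- unclass(tab) / rowSums(tab)
  attr(out, "n_excluded") <- nExcl
  out
}
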