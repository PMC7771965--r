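#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assays colData rowData
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

# ---------------------------------------------------------------- GeneSet ----

#' Named gene set
#'
#' A minimal container for a named collection of gene identifiers (TSA,
#' Aire-dependent, Fezf2-dependent, housekeeping, co-expression groups).
#' Members are unique, non-empty identifier strings; gene identity is the
#' identifier string itself, with no symbol/ID disambiguation.
#'
#' @slot name single string naming the set.
#' @slot members character vector of unique gene identifiers.
#'
#' @examples
#' gs <- GeneSet("housekeeping", c("Gapdh", "Vcp"))
#' geneIds(gs)
#' @aliases GeneSet-class
#' @export GeneSet
#' @exportClass GeneSet
GeneSet <- setClass("GeneSet",
  representation(name = "character", members = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
      msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@members) == 0L)
      msg <- c(msg, "'members' must be non-empty")
    if (anyDuplicated(object@members))
      msg <- c(msg, "'members' must not contain duplicates")
    if (any(is.na(object@members)))
      msg <- c(msg, "'members' must not contain NA")
    if (is.null(msg)) TRUE else msg
  }
)

#' @param name single string.
#' @param members character vector of gene identifiers (duplicates removed).
#' @rdname GeneSet-class
#' @export
GeneSet <- function(name, members) {
  new("GeneSet", name = as.character(name),
      members = unique(as.character(members)))
}

#' @describeIn GeneSet-class gene identifiers in the set.
#' @param x a \code{GeneSet}.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneSet-class
#' @export
setMethod("geneIds", "GeneSet", function(x) x@members)

#' @describeIn GeneSet-class name of the set.
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @rdname GeneSet-class
#' @export
setMethod("setName", "GeneSet", function(x) x@name)

#' @rdname GeneSet-class
#' @export
setMethod("length", "GeneSet", function(x) length(x@members))

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet '", object@name, "' with ", length(object@members),
      " genes\n", sep = "")
  head_ids <- utils::head(object@members, 5L)
  cat("  ", paste(head_ids, collapse = ", "),
      if (length(object@members) > 5L) ", ..." else "", "\n", sep = "")
})

# --------------------------------------------------------- mTECExperiment ----

#' Single-cell mTEC experiment container
#'
#' A \linkS4class{SingleCellExperiment} subclass carrying a UMI count matrix
#' (genes x cells), per-cell metadata in \code{colData} (sample, timepoint,
#' cluster, population, phase, pseudotime, branch, reference label as
#' available), and named \linkS4class{GeneSet} objects plus simulation truth in
#' \code{metadata}. Validity enforces the count-matrix contract: non-negative
#' integer entries and unique gene/cell identifiers.
#'
#' @aliases mTECExperiment-class
#' @export
#' @exportClass mTECExperiment
setClass("mTECExperiment", contains = "SingleCellExperiment")

setValidity("mTECExperiment", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene and cell identifiers are required")
  else {
    if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate cell identifiers")
  }
  x <- if (is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(x) && (any(x < 0) || any(x != round(x))))
    msg <- c(msg, "counts must be non-negative integers")
  pt <- object$pseudotime
  if (!is.null(pt) && any(!is.na(pt) & (pt < 0 | pt > 1)))
    msg <- c(msg, "pseudotime must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' @param counts genes x cells matrix of non-negative integer UMI counts with
#'   gene identifiers as rownames and cell identifiers as colnames.
#' @param cellData optional per-cell \code{DataFrame}/\code{data.frame} aligned
#'   with the columns of \code{counts}.
#' @param geneSets optional named list of \code{GeneSet} objects.
#' @param ... further arguments stored in \code{metadata}.
#' @rdname mTECExperiment-class
#' @export
mTECExperiment <- function(counts, cellData = NULL, geneSets = list(), ...) {
  counts <- .as_counts(counts)
  cd <- if (is.null(cellData)) S4Vectors::DataFrame(row.names = colnames(counts))
        else S4Vectors::DataFrame(cellData, row.names = colnames(counts))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
  S4Vectors::metadata(sce) <- c(list(geneSets = geneSets), list(...))
  new("mTECExperiment", sce)
}

#' @describeIn mTECExperiment-class named list of \code{GeneSet}s carried by
#'   the experiment.
#' @param x an \code{mTECExperiment}.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname mTECExperiment-class
#' @export
setMethod("geneSets", "mTECExperiment", function(x) S4Vectors::metadata(x)$geneSets)

#' @describeIn mTECExperiment-class simulation ground truth (\code{DataFrame}
#'   of planted per-cell labels) or \code{NULL} for real data.
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @rdname mTECExperiment-class
#' @export
setMethod("simTruth", "mTECExperiment", function(x) S4Vectors::metadata(x)$truth)

setMethod("show", "mTECExperiment", function(object) {
  callNextMethod()
  gs <- geneSets(object)
  if (length(gs))
    cat("geneSets(", length(gs), "): ", paste(names(gs), collapse = " "),
        "\n", sep = "")
})

# -------------------------------------------------------- PseudotimeResult ----

#' Start-anchored branching pseudotime result
#'
#' Per-cell pseudotime scores and lineage assignments from
#' \code{\link{fitPseudotime}}, together with the ordered cluster path and the
#' piecewise-linear curve (control points in embedding space) of each lineage.
#' Pseudotime is arc length along the assigned lineage curve, min-max
#' rescaled by one global affine map, so values lie in [0, 1], the shared
#' pre-branch segment receives identical values in every lineage, and 0 is
#' attained on the start-cluster side.
#'
#' @slot cellIds cell identifiers, in input order.
#' @slot pseudotime numeric pseudotime per cell.
#' @slot branch lineage label per cell.
#' @slot lineages named list of ordered cluster-label paths (root to leaf).
#' @slot curves named list of control-point matrices (cluster centroids).
#'
#' @aliases PseudotimeResult-class
#' @exportClass PseudotimeResult
setClass("PseudotimeResult",
  representation(cellIds = "character", pseudotime = "numeric",
                 branch = "character", lineages = "list", curves = "list"),
  validity = function(object) {
    n <- length(object@cellIds)
    if (length(object@pseudotime) != n || length(object@branch) != n)
      return("pseudotime and branch must align with cellIds")
    if (any(object@pseudotime < 0 | object@pseudotime > 1, na.rm = TRUE))
      return("pseudotime must lie in [0, 1]")
    if (!identical(names(object@lineages), names(object@curves)))
      return("lineages and curves must share names")
    TRUE
  }
)

#' @describeIn PseudotimeResult-class per-cell pseudotime, named by cell.
#' @param x a \code{PseudotimeResult}.
#' @export
setGeneric("pseudotime", function(x) standardGeneric("pseudotime"))

#' @rdname PseudotimeResult-class
#' @export
setMethod("pseudotime", "PseudotimeResult",
          function(x) stats::setNames(x@pseudotime, x@cellIds))

#' @describeIn PseudotimeResult-class per-cell lineage assignment.
#' @export
setGeneric("cellBranch", function(x) standardGeneric("cellBranch"))

#' @rdname PseudotimeResult-class
#' @export
setMethod("cellBranch", "PseudotimeResult",
          function(x) stats::setNames(x@branch, x@cellIds))

#' @describeIn PseudotimeResult-class ordered cluster paths, one per lineage.
#' @export
setGeneric("lineagePaths", function(x) standardGeneric("lineagePaths"))

#' @rdname PseudotimeResult-class
#' @export
setMethod("lineagePaths", "PseudotimeResult", function(x) x@lineages)

#' @describeIn PseudotimeResult-class lineage curve control points.
#' @export
setGeneric("lineageCurves", function(x) standardGeneric("lineageCurves"))

#' @rdname PseudotimeResult-class
#' @export
setMethod("lineageCurves", "PseudotimeResult", function(x) x@curves)

setMethod("show", "PseudotimeResult", function(object) {
  cat("PseudotimeResult:", length(object@cellIds), "cells,",
      length(object@lineages), "lineages\n")
  for (nm in names(object@lineages))
    cat("  ", nm, ": ", paste(object@lineages[[nm]], collapse = " -> "),
        " (", sum(object@branch == nm), " cells)\n", sep = "")
})
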