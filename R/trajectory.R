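# Start-anchored branching pseudotime: a minimum-spanning tree over cluster
# centroids rooted at the start cluster defines root-to-leaf lineages; each
# cell is assigned to the nearest lineage polyline and scored by the arc
# length of its orthogonal projection. This is a deliberate simplification
# of published principal-curve trajectory methods: the contract downstream
# analyses need is a start-anchored branching ordering, validated against
# planted ground truth rather than against any external implementation.

#' @importFrom igraph graph_from_adjacency_matrix mst degree V
#'   shortest_paths
NULL

# Project point p onto segment a->b; the projection parameter is clamped to
# [lo, hi] (terminal segments of a lineage are extended to infinity so cells
# beyond the end clusters keep a strict ordering instead of piling up at the
# endpoints).
.proj_segment <- function(p, a, b, lo = 0, hi = 1) {
  d <- b - a
  len2 <- sum(d * d)
  tt <- if (len2 == 0) 0 else max(lo, min(hi, sum((p - a) * d) / len2))
  q <- a + tt * d
  c(offset = tt * sqrt(len2), dist2 = sum((p - q)^2))
}

# Arc-length position and distance of each cell along a polyline (rows =
# ordered control points); the first and last segment extend beyond their
# control points.
.proj_polyline <- function(coords, curve) {
  segStart <- c(0, cumsum(sqrt(rowSums(diff(curve)^2))))
  nSeg <- nrow(curve) - 1
  best <- matrix(NA_real_, nrow(coords), 2,
                 dimnames = list(NULL, c("arc", "dist2")))
  for (i in seq_len(nrow(coords))) {
    p <- coords[i, ]
    bd <- Inf; ba <- 0
    for (sdx in seq_len(nSeg)) {
      pr <- .proj_segment(p, curve[sdx, ], curve[sdx + 1, ],
                          lo = if (sdx == 1) -Inf else 0,
                          hi = if (sdx == nSeg) Inf else 1)
      if (pr["dist2"] < bd) {
        bd <- pr["dist2"]
        ba <- segStart[sdx] + pr["offset"]
      }
    }
    best[i, ] <- c(ba, bd)
  }
  best
}

#' Fit start-anchored branching pseudotime
#'
#' Builds a minimum-spanning tree over cluster centroids in the embedding,
#' roots it at \code{startCluster}, takes every root-to-leaf path as a
#' lineage, assigns each cell to the lineage polyline it is closest to, and
#' scores it by the arc length of its projection (terminal segments extend
#' beyond the end centroids so extreme cells stay strictly ordered), min-max
#' rescaled over all cells by a single affine map. Pseudotime is therefore in
#' [0, 1], 0 is attained on the start-cluster side, branches share the
#' pre-branch path and the shared segment receives identical values in every
#' lineage; shorter lineages top out below 1.
#'
#' @param coords cells x components embedding (e.g. \code{\link{embedPCA}}).
#' @param clusters per-cell cluster labels aligned with \code{coords} rows.
#' @param startCluster label of the root cluster.
#' @return a \linkS4class{PseudotimeResult}; lineages are named
#'   \code{"to_<leaf cluster>"}.
#' @examples
#' xy <- cbind(c(1:30), 0)
#' cl <- rep(c("a", "b", "c"), each = 10)
#' pt <- fitPseudotime(xy, cl, "a")
#' cor(pseudotime(pt), 1:30, method = "spearman")  # 1
#' @export
fitPseudotime <- function(coords, clusters, startCluster) {
  coords <- as.matrix(coords)
  clusters <- as.character(clusters)
  if (nrow(coords) != length(clusters))
    stop("clusters must align with coords rows", call. = FALSE)
  labs <- unique(clusters)
  if (!startCluster %in% labs)
    stop("start cluster '", startCluster, "' not present", call. = FALSE)
  if (length(labs) < 2) stop("need at least 2 clusters", call. = FALSE)
  cent <- t(vapply(labs, function(l)
    colMeans(coords[clusters == l, , drop = FALSE]), numeric(ncol(coords))))
  if (anyDuplicated(cent))
    stop("duplicate cluster centroids: degenerate geometry", call. = FALSE)
  D <- as.matrix(stats::dist(cent))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  root <- match(startCluster, labs)
  deg <- igraph::degree(tree)
  leaves <- setdiff(which(deg == 1), root)
  if (!length(leaves)) leaves <- setdiff(seq_along(labs), root)
  paths <- igraph::shortest_paths(tree, from = root, to = leaves)$vpath
  lineages <- lapply(paths, function(p) labs[as.integer(p)])
  names(lineages) <- vapply(lineages, function(p)
    paste0("to_", p[length(p)]), character(1))
  curves <- lapply(lineages, function(p)
    cent[match(p, labs), , drop = FALSE])
  proj <- lapply(curves, function(cv) .proj_polyline(coords, cv))
  dists <- vapply(proj, function(pp) pp[, "dist2"], numeric(nrow(coords)))
  if (is.null(dim(dists))) dists <- matrix(dists, nrow = 1)
  pick <- apply(dists, 1, which.min)
  arc <- vapply(seq_len(nrow(coords)),
                function(i) proj[[pick[i]]][i, "arc"], numeric(1))
  # one global affine rescale: arc length is comparable across lineages
  # (shared pre-branch values identical), 0 at the earliest projection
  rng <- range(arc)
  pt <- if (diff(rng) > 0) (arc - rng[1]) / diff(rng) else rep(0, length(arc))
  cellIds <- if (!is.null(rownames(coords))) rownames(coords)
             else sprintf("cell%05d", seq_len(nrow(coords)))
  new("PseudotimeResult", cellIds = cellIds, pseudotime = pt,
      branch = names(lineages)[pick], lineages = lineages, curves = curves)
}

#' Sliding-window profile of a statistic over pseudotime
#'
#' Orders the cells of one lineage by pseudotime and evaluates a
#' sliding-window mean (window = \code{windowFraction} of the lineage cell
#' count, centred on the nearest cells in pseudotime) on a fixed grid;
#' reports the grid location of the profile maximum. Used for gene and
#' gene-set kinetics (e.g. the Fezf2-before-Aire-before-TSA ordering).
#'
#' @param values per-cell statistic named by cell (log expression, percent
#'   of TSAs, ...).
#' @param pt a \linkS4class{PseudotimeResult}.
#' @param lineage lineage name (default: first lineage).
#' @param windowFraction window size as a fraction of the lineage cell
#'   count (default 0.1).
#' @param gridN grid resolution.
#' @return data.frame \code{grid}, \code{mean}, \code{sd}, plus attribute
#'   \code{argmax} (grid location of the maximum mean).
#' @export
profileOverPseudotime <- function(values, pt, lineage = NULL,
                                  windowFraction = 0.1, gridN = 100) {
  stopifnot(is(pt, "PseudotimeResult"))
  if (is.null(lineage)) lineage <- names(pt@lineages)[1]
  if (!lineage %in% names(pt@lineages))
    stop("unknown lineage '", lineage, "'", call. = FALSE)
  on <- pt@branch == lineage
  if (sum(on) < 10)
    stop("need at least 10 cells on the lineage", call. = FALSE)
  t <- pt@pseudotime[on]
  ids <- pt@cellIds[on]
  v <- if (!is.null(names(values))) values[ids] else values[on]
  if (any(is.na(v)))
    stop("statistic missing for some lineage cells", call. = FALSE)
  w <- max(2L, round(windowFraction * length(t)))
  if (w > length(t))
    stop("window larger than the lineage population", call. = FALSE)
  grid <- seq(min(t), max(t), length.out = gridN)
  ord <- order(t)
  t <- t[ord]; v <- v[ord]
  mu <- sdv <- numeric(gridN)
  for (i in seq_len(gridN)) {
    sel <- order(abs(t - grid[i]))[seq_len(w)]
    mu[i] <- mean(v[sel])
    sdv[i] <- stats::sd(v[sel])
  }
  out <- data.frame(grid = grid, mean = mu, sd = sdv)
  attr(out, "argmax") <- grid[which.max(mu)]
  out
}

#' Per-sample cell density over pseudotime
#'
#' Gaussian kernel density (Silverman's rule bandwidth) of each sample's
#' cells along one lineage, evaluated on a common 200-point grid and
#' renormalised to integrate to 1 over the grid; a histogram variant is
#' available. Samples with fewer than \code{minCells} lineage cells are
#' recorded as missing with a warning.
#'
#' @param pt a \linkS4class{PseudotimeResult}.
#' @param samples per-cell sample labels named by cell (or aligned with the
#'   fit's cells).
#' @param lineage lineage name (default: first).
#' @param gridN grid resolution (default 200).
#' @param method \code{"kernel"} (default) or \code{"histogram"}.
#' @param minCells minimum cells per sample (default 5).
#' @return data.frame with \code{grid} and one density column per sample.
#' @export
densityBySample <- function(pt, samples, lineage = NULL, gridN = 200,
                            method = c("kernel", "histogram"),
                            minCells = 5) {
  stopifnot(is(pt, "PseudotimeResult"))
  method <- match.arg(method)
  if (is.null(lineage)) lineage <- names(pt@lineages)[1]
  if (!lineage %in% names(pt@lineages))
    stop("unknown lineage '", lineage, "'", call. = FALSE)
  on <- pt@branch == lineage
  t <- pt@pseudotime[on]
  smp <- if (!is.null(names(samples))) samples[pt@cellIds[on]]
         else samples[on]
  smp <- as.character(smp)
  grid <- seq(min(t), max(t), length.out = gridN)
  lvls <- unique(smp)
  out <- data.frame(grid = grid)
  for (sm in lvls) {
    x <- t[smp == sm]
    if (length(x) < minCells) {
      warning("sample '", sm, "' has fewer than ", minCells,
              " cells on the lineage; recorded missing")
      out[[sm]] <- NA_real_
      next
    }
    dens <- if (method == "kernel") {
      bw <- stats::bw.nrd0(x)
      stats::approx(stats::density(x, bw = bw, from = min(grid),
                                   to = max(grid), n = gridN),
                    xout = grid)$y
    } else {
      h <- graphics::hist(x, breaks = seq(min(grid), max(grid),
                                          length.out = 21), plot = FALSE)
      h$density[findInterval(grid, h$breaks, rightmost.closed = TRUE,
                             all.inside = TRUE)]
    }
    area <- sum((dens[-1] + dens[-gridN]) / 2 * diff(grid))
    out[[sm]] <- dens / area
  }
  out
}
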