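# 10x-style sparse triplet I/O and TSV readers for gene sets, marker pairs
# and cell tables. MatrixMarket triplets are 1-based on disk; all in-memory
# indexing is the usual R 1-based matrix indexing, so conversion happens only
# inside Matrix::readMM / the writer. Gzip inputs are auto-detected from the
# stream (gzfile() sniffs magic bytes), never from the file extension.

.find_file <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("none of ", paste(candidates, collapse = "/"), " found in '", dir, "'",
       call. = FALSE)
}

.read_tsv_col <- function(path, col = 1L) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  tab <- utils::read.table(con, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  as.character(tab[[min(col, ncol(tab))]])
}

#' Read a 10x-style sparse count directory
#'
#' Reads a MatrixMarket coordinate matrix plus gene and barcode tables
#' (plain or gzip-compressed; \code{matrix.mtx}, \code{genes.tsv} or
#' \code{features.tsv}, \code{barcodes.tsv}) into a sparse genes x cells
#' count matrix. File order of genes and barcodes is preserved exactly;
#' the reader never reorders.
#'
#' @param path directory containing the three files.
#' @return a \code{dgCMatrix} with gene identifiers as rownames and cell
#'   barcodes as colnames.
#' @seealso \code{\link{writeTenxMtx}} for the inverse operation.
#' @examples
#' d <- tempfile(); m <- Matrix::rsparsematrix(5, 3, 0.5, rand.x = function(n) rpois(n, 2) + 1)
#' dimnames(m) <- list(paste0("g", 1:5), paste0("c", 1:3))
#' writeTenxMtx(m, d)
#' m2 <- readTenxMtx(d)
#' all(m == m2)
#' @export
readTenxMtx <- function(path) {
  if (!dir.exists(path)) stop("'", path, "' is not a directory", call. = FALSE)
  mtx <- .find_file(path, c("matrix.mtx", "matrix.mtx.gz"))
  gf <- .find_file(path, c("genes.tsv", "genes.tsv.gz",
                           "features.tsv", "features.tsv.gz"))
  bf <- .find_file(path, c("barcodes.tsv", "barcodes.tsv.gz"))
  con <- gzfile(mtx, "rt")
  on.exit(close(con))
  m <- Matrix::readMM(con)
  genes <- .read_tsv_col(gf, 1L)
  cells <- .read_tsv_col(bf, 1L)
  if (nrow(m) != length(genes))
    stop("matrix header declares ", nrow(m), " genes but ", length(genes),
         " listed", call. = FALSE)
  if (ncol(m) != length(cells))
    stop("matrix header declares ", ncol(m), " cells but ", length(cells),
         " listed", call. = FALSE)
  if (anyDuplicated(genes)) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(cells)) stop("duplicate cell barcodes", call. = FALSE)
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  if (length(m@x)) {
    if (any(m@x != round(m@x)))
      stop("non-integer entries in count matrix", call. = FALSE)
    if (any(m@x < 0)) stop("negative entries in count matrix", call. = FALSE)
  }
  dimnames(m) <- list(genes, cells)
  m
}

#' Write a count matrix as a 10x-style sparse triplet directory
#'
#' Emits \code{matrix.mtx} (MatrixMarket "coordinate integer general",
#' 1-based triplets), \code{genes.tsv} and \code{barcodes.tsv}, readable by
#' \code{\link{readTenxMtx}}. The matrix is validated (non-negative integers,
#' unique identifiers) before anything is written.
#'
#' @param m genes x cells count matrix with dimnames.
#' @param path output directory (created if missing).
#' @return invisibly, the output directory.
#' @export
writeTenxMtx <- function(m, path) {
  m <- .as_counts(m)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create directory '", path, "'", call. = FALSE)
  tr <- Matrix::summary(m)  # 1-based i, j
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             paste(nrow(m), ncol(m), nrow(tr)),
             if (nrow(tr)) sprintf("%d %d %d", tr$i, tr$j, as.integer(tr$x)))
  writeLines(lines, file.path(path, "matrix.mtx"))
  utils::write.table(data.frame(rownames(m), rownames(m)),
                     file.path(path, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Read and write gene-set TSV files
#'
#' Gene sets travel as a two-column TSV (\code{set}, \code{gene}), one member
#' per line.
#'
#' @param path TSV file path.
#' @return \code{readGeneSets}: a named list of \linkS4class{GeneSet}s.
#' @export
readGeneSets <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  if (!all(c("set", "gene") %in% names(tab)))
    stop("gene-set file needs 'set' and 'gene' columns", call. = FALSE)
  sets <- split(tab$gene, tab$set)
  out <- lapply(names(sets), function(nm) GeneSet(nm, sets[[nm]]))
  stats::setNames(out, names(sets))
}

#' @param sets named list of \code{GeneSet} objects (or character vectors).
#' @rdname readGeneSets
#' @export
writeGeneSets <- function(sets, path) {
  rows <- lapply(names(sets), function(nm) {
    g <- sets[[nm]]
    data.frame(set = nm, gene = if (is(g, "GeneSet")) geneIds(g) else g)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write cell-cycle marker-pair TSV files
#'
#' Marker pairs travel as a TSV with columns \code{phase} (\code{G1},
#' \code{S} or \code{G2M}), \code{gene_a}, \code{gene_b}, where gene_a is
#' the member expected to be the more highly expressed in that phase.
#'
#' @param path TSV file path.
#' @return \code{readMarkerPairs}: a data.frame with the three columns.
#' @export
readMarkerPairs <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  .check_marker_pairs(tab)
  tab
}

#' @param pairs data.frame with columns phase, gene_a, gene_b.
#' @rdname readMarkerPairs
#' @export
writeMarkerPairs <- function(pairs, path) {
  .check_marker_pairs(pairs)
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.check_marker_pairs <- function(pairs) {
  if (!all(c("phase", "gene_a", "gene_b") %in% names(pairs)))
    stop("marker pairs need columns phase, gene_a, gene_b", call. = FALSE)
  if (!all(pairs$phase %in% c("G1", "S", "G2M")))
    stop("phase must be one of G1, S, G2M", call. = FALSE)
  if (any(pairs$gene_a == pairs$gene_b))
    stop("a pair may not compare a gene with itself", call. = FALSE)
  if (!all(c("G1", "S", "G2M") %in% pairs$phase))
    stop("every phase needs at least one pair", call. = FALSE)
  invisible(TRUE)
}
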