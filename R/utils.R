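# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never perturb user RNG.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Coerce a counts carrier to dgCMatrix and check the CountMatrix invariants:
# non-negative integer entries, unique non-empty gene and cell identifiers.
.as_counts <- function(m, what = "counts") {
  if (is(m, "mTECExperiment") || is(m, "SummarizedExperiment"))
    m <- SummarizedExperiment::assay(m, "counts")
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  .check_counts(m, what)
  m
}

.check_counts <- function(m, what = "counts") {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must carry gene (row) and cell (column) identifiers", call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate cell identifiers", call. = FALSE)
  x <- if (is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(x)) {
    if (any(x < 0)) stop(what, " must be non-negative", call. = FALSE)
    if (any(x != round(x))) stop(what, " must be integer-valued", call. = FALSE)
  }
  invisible(TRUE)
}

# Log-normalised carriers: any numeric matrix with dimnames.
.as_values <- function(m) {
  if (is(m, "SummarizedExperiment")) m <- SummarizedExperiment::assay(m, "logcounts")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must carry gene and cell identifiers", call. = FALSE)
  m
}

.stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("'", name, "' must be a single number", call. = FALSE)
  invisible(x)
}
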