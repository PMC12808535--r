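#' @importFrom Matrix readMM writeMM Diagonal colSums rowSums rowMeans t sparseMatrix
#' @importFrom SummarizedExperiment assay assay<- assayNames colData colData<-
#' @importFrom SingleCellExperiment SingleCellExperiment logcounts logcounts<- counts
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Assemble a single-cell cohort object
#'
#' Builds the `SingleCellExperiment` used throughout the package: raw
#' counts (genes x cells), per-cell library sizes, and optional patient
#' identifiers.  Cells with zero total counts are removed (normalization
#' is undefined for them) with a logged count.
#'
#' @param counts genes x cells matrix of non-negative integer counts,
#'   with unique rownames (genes) and colnames (cells).
#' @param patient optional character vector of patient identifiers, one
#'   per cell (named or in column order).
#' @param dropEmptyCells remove zero-count cells (default TRUE).
#' @param validate check that entries are non-negative integers (default
#'   TRUE; the simulator skips this for counts it generated itself).
#' @return A `SingleCellExperiment` with a `counts` assay and colData
#'   columns `library_size` and (if given) `patient_id`.
#' @export
makeCohort <- function(counts, patient = NULL, dropEmptyCells = TRUE,
                       validate = TRUE) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and cell colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell identifiers")
  if (validate) {
    vals <- if (is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
    if (any(vals < 0)) stop("counts contain negative entries")
    if (any(vals != floor(vals))) stop("counts contain non-integer entries")
  }
  lib <- Matrix::colSums(counts)
  if (dropEmptyCells && any(lib == 0)) {
    .msg(sum(lib == 0), " cell(s) with zero total counts removed")
    keep <- lib > 0
    counts <- counts[, keep, drop = FALSE]
    if (!is.null(patient) && length(patient) == ncol(counts) + sum(!keep))
      patient <- patient[keep]
    lib <- lib[keep]
  }
  cd <- DataFrame(library_size = as.integer(lib), row.names = colnames(counts))
  if (!is.null(patient)) {
    if (!is.null(names(patient))) patient <- patient[colnames(counts)]
    stopifnot(length(patient) == ncol(counts))
    cd$patient_id <- as.character(patient)
  }
  SingleCellExperiment(assays = list(counts = counts), colData = cd)
}

#' Read a sparse or dense count matrix into a cohort object
#'
#' Reads Matrix Market coordinate files (with one-identifier-per-line
#' gene and cell label files) or dense delimited text with gene/cell
#' identifiers in the header row and first column.  On-disk orientation
#' is declared via `orientation` (default `"genes_by_cells"`, the common
#' sparse-export convention); the returned object is always genes x
#' cells.
#'
#' @param matrixPath path to `.mtx` (Matrix Market) or dense `.tsv`.
#' @param genesPath,cellsPath label files for the `.mtx` case, one
#'   identifier per line; ignored for dense input.
#' @param orientation `"genes_by_cells"` or `"cells_by_genes"`:
#'   orientation of the on-disk matrix.
#' @param dropEmptyCells remove zero-count cells (default TRUE).
#' @return A `SingleCellExperiment` (see [makeCohort()]).
#' @export
readCounts <- function(matrixPath, genesPath = NULL, cellsPath = NULL,
                       orientation = c("genes_by_cells", "cells_by_genes"),
                       dropEmptyCells = TRUE) {
  orientation <- match.arg(orientation)
  if (grepl("\\.mtx$", matrixPath)) {
    m <- as(Matrix::readMM(matrixPath), "CsparseMatrix")
    if (is.null(genesPath) || is.null(cellsPath))
      stop("Matrix Market input requires gene and cell label files")
    genes <- readLines(genesPath, warn = FALSE)
    cells <- readLines(cellsPath, warn = FALSE)
    if (orientation == "cells_by_genes") m <- Matrix::t(m)
    if (nrow(m) != length(genes))
      stop(sprintf("gene label mismatch: %d labels vs %d matrix rows",
                   length(genes), nrow(m)))
    if (ncol(m) != length(cells))
      stop(sprintf("cell label mismatch: %d labels vs %d matrix columns",
                   length(cells), ncol(m)))
    dimnames(m) <- list(genes, cells)
  } else {
    d <- read.delim(matrixPath, row.names = 1L, check.names = FALSE)
    m <- as(as.matrix(d), "CsparseMatrix")
    if (orientation == "cells_by_genes") m <- Matrix::t(m)
  }
  makeCohort(m, dropEmptyCells = dropEmptyCells)
}

#' Write a cohort's counts as Matrix Market plus label files
#'
#' Inverse of [readCounts()]: writes `matrix.mtx`, `genes.txt` and
#' `cells.txt` (genes x cells orientation) into `dir`.
#'
#' @param x a `SingleCellExperiment` with a `counts` assay.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCounts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- as(counts(x), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x), file.path(dir, "genes.txt"))
  writeLines(colnames(x), file.path(dir, "cells.txt"))
  invisible(dir)
}

#' Attach per-cell metadata from a delimited file
#'
#' Reads a TSV with header columns `cell_id` and `patient_id` (further
#' columns are carried along as covariates), aligns rows to the cohort's
#' cell order, and recomputes `library_size` from the counts.  Cells of
#' the cohort missing from the metadata are fatal; metadata rows for
#' unknown cells are dropped with a warning.
#'
#' @param x a `SingleCellExperiment`.
#' @param path metadata TSV path.
#' @return `x` with updated `colData`.
#' @export
attachCellMeta <- function(x, path) {
  meta <- read.delim(path, check.names = FALSE, colClasses = "character")
  for (col in c("cell_id", "patient_id"))
    if (!col %in% names(meta)) stop("metadata lacks required column '", col, "'")
  if (anyDuplicated(meta$cell_id)) stop("duplicate cell_id in metadata")
  missing <- setdiff(colnames(x), meta$cell_id)
  if (length(missing))
    stop(sprintf("%d cell(s) missing from metadata; first %d: %s",
                 length(missing), min(10L, length(missing)),
                 paste(head(missing, 10L), collapse = ", ")))
  extra <- setdiff(meta$cell_id, colnames(x))
  if (length(extra)) {
    warning(sprintf("%d metadata row(s) for cells absent from the matrix dropped",
                    length(extra)))
    meta <- meta[meta$cell_id %in% colnames(x), , drop = FALSE]
  }
  meta <- meta[match(colnames(x), meta$cell_id), , drop = FALSE]
  cd <- colData(x)
  cd$patient_id <- meta$patient_id
  cd$library_size <- as.integer(Matrix::colSums(counts(x)))
  for (col in setdiff(names(meta), c("cell_id", "patient_id"))) {
    num <- suppressWarnings(as.numeric(meta[[col]]))
    cd[[col]] <- if (anyNA(num)) meta[[col]] else num
  }
  colData(x) <- cd
  x
}

#' Write per-cell metadata as TSV
#'
#' @param x a `SingleCellExperiment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCellMeta <- function(x, path) {
  df <- as.data.frame(colData(x))
  df <- cbind(cell_id = colnames(x), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Library-size normalization with log1p transform
#'
#' Adds a `logcounts` assay with entries
#' `ln(1 + count / library_size * scaleFactor)` (the standard
#' counts-per-`scaleFactor` log transform).  Zero counts map to exactly
#' zero, the sparsity pattern is preserved, and per-cell rescaling of the
#' raw counts leaves the result unchanged.
#'
#' @param x a `SingleCellExperiment` with a `counts` assay.
#' @param scaleFactor positive scale (default 1e4).
#' @return `x` with a `logcounts` assay.
#' @export
normalizeCohort <- function(x, scaleFactor = 1e4) {
  stopifnot(scaleFactor > 0)
  lib <- Matrix::colSums(counts(x))
  if (any(lib == 0))
    stop("zero library size for cell(s): ",
         paste(head(colnames(x)[lib == 0], 10L), collapse = ", "))
  if (is(counts(x), "sparseMatrix")) {
    m <- as(counts(x), "CsparseMatrix") %*% Diagonal(x = scaleFactor / lib)
    lc <- log1p(m)
  } else {
    m <- as.matrix(counts(x))
    lc <- log1p(m * rep(scaleFactor / lib, each = nrow(m)))
  }
  dimnames(lc) <- dimnames(x)
  logcounts(x) <- lc
  metadata(x)$scale_factor <- scaleFactor
  x
}

#' Log-normalized expression of one gene across cells
#'
#' @param x a `SingleCellExperiment` with `logcounts`.
#' @param gene gene identifier (matched case-sensitively).
#' @return named numeric vector over cells.
#' @export
geneExpression <- function(x, gene) {
  if (!gene %in% rownames(x)) stop("gene '", gene, "' not in the matrix")
  setNames(as.numeric(logcounts(x)[gene, ]), colnames(x))
}
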