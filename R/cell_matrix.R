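#' Construct a cell-by-gene count container
#'
#' Counts are stored genes x cells (the sparse-matrix convention of the
#' single-cell ecosystem); the conceptual orientation is cells x genes with
#' one condition and one cell-type label per cell.
#'
#' @param counts integer matrix or sparse Matrix, genes in rows (rownames =
#'   gene ids), cells in columns (colnames = barcodes).
#' @param cell_meta data frame with columns \code{barcode}, \code{condition},
#'   \code{cell_type}; barcodes must match \code{colnames(counts)} exactly
#'   (any order).
#' @return A \code{cell_gene_matrix}: list with elements \code{counts}
#'   (\code{dgCMatrix}) and \code{cell_meta} (aligned to the columns).
#' @export
cell_gene_matrix <- function(counts, cell_meta) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene ids as rownames and barcodes as colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("cell barcodes must be unique")
  v <- counts@x
  if (any(v < 0) || any(v != round(v))) {
    stop("counts must be nonnegative integers")
  }
  req <- c("barcode", "condition", "cell_type")
  if (!all(req %in% names(cell_meta))) {
    stop("cell_meta requires columns barcode, condition, cell_type")
  }
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  if (!setequal(cell_meta$barcode, colnames(counts)) ||
      anyDuplicated(cell_meta$barcode)) {
    stop("cell_meta barcodes must match matrix columns one-to-one")
  }
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$barcode), ,
                         drop = FALSE]
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "cell_gene_matrix")
}

#' @export
print.cell_gene_matrix <- function(x, ...) {
  cat(sprintf("cell_gene_matrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat("conditions:",
      paste(sort(unique(x$cell_meta$condition)), collapse = ", "), "\n")
  cat("cell types:",
      paste(sort(unique(x$cell_meta$cell_type)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cell_gene_matrix <- function(x) dim(x$counts)

# columns scaled so every cell sums to target_sum (zero-total cells stay zero)
.normalize_depth <- function(counts, target_sum = 1e4) {
  totals <- Matrix::colSums(counts)
  f <- ifelse(totals > 0, target_sum / totals, 0)
  counts %*% Matrix::Diagonal(x = f)
}

.select_cells <- function(m, population = NULL, condition = NULL) {
  meta <- m$cell_meta
  sel <- rep(TRUE, nrow(meta))
  if (!is.null(population)) {
    if (!population %in% meta$cell_type) {
      stop("unknown cell-type label '", population, "'")
    }
    sel <- sel & meta$cell_type == population
  }
  if (!is.null(condition)) {
    if (!condition %in% meta$condition) {
      stop("unknown condition label '", condition, "'")
    }
    sel <- sel & meta$condition == condition
  }
  which(sel)
}
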