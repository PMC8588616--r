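.open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.write_tsv <- function(df, path, col.names = TRUE) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = col.names)
}

#' Read peaks from a BED3/BED6 file
#'
#' @param path BED file (tab-delimited, no header; 3 or 6 columns).
#' @param condition_label condition label attached to the returned set.
#' @return A [peak_set()].
#' @export
read_peaks_bed <- function(path, condition_label = basename(path)) {
  con <- .open_maybe_gz(path)
  on.exit(close(con))
  x <- read.table(con, sep = "\t", header = FALSE,
                  colClasses = "character", fill = FALSE,
                  blank.lines.skip = TRUE)
  if (!ncol(x) %in% c(3L, 6L)) {
    stop("expected BED3 or BED6 in ", path, ", got ", ncol(x), " columns")
  }
  names(x)[1:3] <- c("chrom", "start", "end")
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (ncol(x) >= 6) {
    names(x)[4:6] <- c("name", "score", "strand")
    x$score <- suppressWarnings(as.numeric(x$score))
    x$score[is.na(x$score)] <- 0
  }
  peak_set(x, condition_label)
}

#' Write peaks as BED6
#'
#' Emits sorted, tab-delimited, newline-terminated BED6; missing names become
#' \code{"."}, missing scores 0, missing strands \code{"."}.
#'
#' @param x a [peak_set()].
#' @param path output path.
#' @export
write_peaks_bed <- function(x, path) {
  df <- data.frame(
    chrom = x$chrom, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = if ("strand" %in% names(x)) x$strand else ".",
    stringsAsFactors = FALSE
  )
  .write_tsv(df, path, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-delimited with a required header containing at least
#' \code{chrom, start, end, strand, id} (optionally \code{symbol}).
#'
#' @param path TSV path.
#' @return A [gene_table()].
#' @export
read_gene_table <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  gene_table(x)
}

#' Write a gene annotation table as TSV
#' @param x a [gene_table()].
#' @param path output path.
#' @export
write_gene_table <- function(x, path) {
  .write_tsv(x[, c("chrom", "start", "end", "strand", "id", "symbol")], path)
  invisible(path)
}

#' Read chromatin loops from a BEDPE file
#'
#' Seven tab-delimited columns, no header: chrom1, start1, end1, chrom2,
#' start2, end2, name. The two anchors must lie on the same chromosome with
#' anchor A strictly left of anchor B.
#'
#' @param path BEDPE path.
#' @return A [loop_set()].
#' @export
read_loops_bedpe <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 7) stop("expected 7-column BEDPE in ", path)
  names(x)[1:7] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                     "name")
  loop_set(data.frame(
    id = as.character(x$name), chrom = as.character(x$chrom1),
    a_start = as.integer(x$start1), a_end = as.integer(x$end1),
    b_start = as.integer(x$start2), b_end = as.integer(x$end2),
    chrom2 = as.character(x$chrom2), stringsAsFactors = FALSE
  ))
}

#' Write chromatin loops as BEDPE
#' @param x a [loop_set()].
#' @param path output path.
#' @export
write_loops_bedpe <- function(x, path) {
  df <- data.frame(x$chrom, x$a_start, x$a_end, x$chrom, x$b_start, x$b_end,
                   x$id)
  .write_tsv(df, path, col.names = FALSE)
  invisible(path)
}

#' Read a cell-by-gene count matrix from MTX + sidecars
#'
#' Expects the conventional layout: \code{matrix.mtx} (genes x cells),
#' \code{features.tsv} (gene ids, optionally a second symbol column),
#' \code{barcodes.tsv}, and \code{cell_meta.tsv} (header:
#' \code{barcode}, \code{condition}, \code{cell_type}).
#'
#' @param dir directory containing the four files.
#' @return A [cell_gene_matrix()].
#' @export
read_cell_matrix <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  counts <- as(counts, "CsparseMatrix")
  feats <- read.table(file.path(dir, "features.tsv"), sep = "\t",
                      header = FALSE, stringsAsFactors = FALSE)
  bcs <- read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                    header = FALSE, stringsAsFactors = FALSE)
  rownames(counts) <- feats[[1]]
  colnames(counts) <- bcs[[1]]
  meta <- read.table(file.path(dir, "cell_meta.tsv"), sep = "\t",
                     header = TRUE, stringsAsFactors = FALSE)
  cell_gene_matrix(counts, meta)
}

#' Write a cell-by-gene matrix as MTX + sidecars
#' @param m a [cell_gene_matrix()].
#' @param dir output directory (created if absent).
#' @export
write_cell_matrix <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(m$counts), file.path(dir, "barcodes.tsv"))
  .write_tsv(m$cell_meta, file.path(dir, "cell_meta.tsv"))
  invisible(dir)
}

#' Read a fragment table
#'
#' BED-like, tab-delimited, no header: chrom, start, end, barcode. A
#' \code{.gz} path is decompressed transparently.
#'
#' @param path fragment TSV path.
#' @return A \code{fragment_table} data frame sorted by (chrom, start).
#' @export
read_fragments <- function(path) {
  con <- .open_maybe_gz(path)
  on.exit(close(con))
  x <- read.table(con, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(x)[1:4] <- c("chrom", "start", "end", "barcode")
  fragment_table(x)
}

#' Write a fragment table
#' @param x a \code{fragment_table}.
#' @param path output path.
#' @export
write_fragments <- function(x, path) {
  .write_tsv(x[, c("chrom", "start", "end", "barcode")], path,
             col.names = FALSE)
  invisible(path)
}

#' Validate a fragment table
#'
#' @param x data frame with columns chrom, start, end, barcode.
#' @return the sorted table with class \code{fragment_table}.
#' @export
fragment_table <- function(x) {
  req <- c("chrom", "start", "end", "barcode")
  if (!all(req %in% names(x))) {
    stop("fragment table requires columns chrom, start, end, barcode")
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$barcode <- as.character(x$barcode)
  if (any(x$start >= x$end)) stop("fragments must satisfy start < end")
  if (any(!nzchar(x$barcode))) stop("fragment barcodes must be non-empty")
  x <- x[.bed_order(x$chrom, x$start, x$end), req, drop = FALSE]
  rownames(x) <- NULL
  structure(x, class = c("fragment_table", "data.frame"))
}

#' Read a ligand-receptor pair table
#'
#' Two tab-delimited columns with a header: \code{ligand}, \code{receptor}.
#' Duplicate pairs are an error.
#'
#' @param path TSV path.
#' @return data frame of unique (ligand, receptor) pairs.
#' @export
read_pair_table <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(x))) {
    stop("pair table requires header columns 'ligand' and 'receptor'")
  }
  if (anyDuplicated(x[, c("ligand", "receptor")])) {
    stop("duplicate ligand-receptor pairs in ", path)
  }
  x
}

#' Read a cell QC table
#'
#' Tab-delimited with header \code{barcode}, \code{n_fragments},
#' \code{promoter_ratio}.
#'
#' @param path TSV path.
#' @return data frame of QC records.
#' @export
read_qc_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write per-gene log fold-changes as TSV
#'
#' The condition pair, log base, pseudocount and normalization target are
#' recorded as \code{#}-prefixed metadata lines before the header.
#'
#' @param x a \code{gene_logfc} object from [cell_averaged_logfc()].
#' @param path output path.
#' @export
write_gene_logfc <- function(x, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf(
    "# log_base=2 numerator=%s denominator=%s pseudocount=%g target_sum=%g",
    attr(x, "numerator"), attr(x, "denominator"),
    attr(x, "pseudocount"), attr(x, "target_sum")), con)
  write.table(x[, c("gene_id", "logfc")], con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read per-gene log fold-changes written by [write_gene_logfc()]
#' @param path TSV path.
#' @return data frame with \code{gene_id}, \code{logfc}.
#' @export
read_gene_logfc <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}
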