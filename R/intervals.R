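#' Construct a validated peak set
#'
#' A peak set is a data frame of genomic intervals in BED convention
#' (0-based, half-open), sorted by (chrom, start, end), with no two rows
#' sharing identical coordinates. An optional nonnegative \code{score} and a
#' \code{name} column are carried through unchanged.
#'
#' @param x data frame with columns \code{chrom}, \code{start}, \code{end}
#'   and optionally \code{name}, \code{score}, \code{strand}.
#' @param condition_label free-text label for the condition the peaks were
#'   called in (e.g. \code{"WT"}).
#' @return A \code{peak_set}: the sorted data frame with attribute
#'   \code{condition}.
#' @export
peak_set <- function(x, condition_label = "unlabeled") {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x))) {
    stop("peak set requires columns chrom, start, end")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (nrow(x) > 0) {
    if (any(!nzchar(x$chrom))) stop("empty chromosome name in peak set")
    if (any(x$start < 0L)) stop("negative start coordinate in peak set")
    if (any(x$end <= x$start)) stop("peak intervals must satisfy end > start")
    if ("score" %in% names(x) && any(!is.na(x$score) & x$score < 0)) {
      stop("peak scores must be nonnegative")
    }
  }
  x <- x[.bed_order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  if (anyDuplicated(x[, req])) {
    stop("duplicate identical intervals in peak set '", condition_label, "'")
  }
  structure(x, condition = condition_label,
            class = c("peak_set", "data.frame"))
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d peaks on %d chromosome(s)\n",
              attr(x, "condition"), nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

.check_peaks_sorted <- function(x, label) {
  if (!.is_bed_sorted(x$chrom, x$start, x$end)) {
    stop("peak set '", label, "' is not sorted by (chrom, start)")
  }
}

#' Construct a validated gene table
#'
#' Gene bodies in BED convention with strand-aware transcription start sites:
#' \code{tss = start} on the plus strand and \code{tss = end - 1} on the minus
#' strand. Gene ids must be unique. The table is sorted by (chrom, start).
#'
#' @param x data frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{strand} (one of \code{+}, \code{-}, \code{.}), \code{id}, and
#'   optionally \code{symbol}.
#' @return A \code{gene_table} data frame with a derived \code{tss} column.
#' @export
gene_table <- function(x) {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end", "strand", "id")
  if (!all(req %in% names(x))) {
    stop("gene table requires columns chrom, start, end, strand, id")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$strand <- as.character(x$strand)
  x$id <- as.character(x$id)
  if (!"symbol" %in% names(x)) x$symbol <- x$id
  if (any(x$start < 0L) || any(x$end <= x$start)) {
    stop("gene intervals must satisfy 0 <= start < end")
  }
  if (!all(x$strand %in% c("+", "-", "."))) {
    stop("gene strand must be one of '+', '-', '.'")
  }
  if (anyDuplicated(x$id)) stop("gene ids must be unique")
  x$tss <- ifelse(x$strand == "-", x$end - 1L, x$start)
  x <- x[.bed_order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  structure(x, class = c("gene_table", "data.frame"))
}

#' Test whether two genomic intervals overlap
#'
#' Half-open semantics: intervals sharing only a boundary do not overlap, and
#' intervals on different chromosomes never overlap.
#'
#' @param a,b lists or one-row data frames with \code{chrom}, \code{start},
#'   \code{end}.
#' @return \code{TRUE} iff the intervals share at least one base.
#' @export
interval_overlaps <- function(a, b) {
  isTRUE(a$chrom == b$chrom && a$start < b$end && b$start < a$end)
}

#' All overlapping pairs between two sorted peak sets
#'
#' @param query,subject \code{peak_set} objects (or sorted BED data frames).
#' @param min_overlap minimum overlap in bp for a pair to count (default 1).
#' @return data frame with integer columns \code{query_idx}, \code{subject_idx}
#'   (row indices into the inputs), sorted by query index then subject index.
#' @export
find_overlaps_batch <- function(query, subject, min_overlap = 1L) {
  .check_peaks_sorted(query, attr(query, "condition") %||% "query")
  .check_peaks_sorted(subject, attr(subject, "condition") %||% "subject")
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(data.frame(query_idx = integer(), subject_idx = integer()))
  }
  hits <- .find_overlaps(.as_granges(query), .as_granges(subject),
                                      minoverlap = as.integer(min_overlap))
  out <- data.frame(query_idx = S4Vectors::queryHits(hits),
                    subject_idx = S4Vectors::subjectHits(hits))
  out[order(out$query_idx, out$subject_idx), , drop = FALSE]
}

#' Condition-specific peaks by subtraction
#'
#' Returns the peaks of \code{set_a} that have no overlap of at least
#' \code{min_overlap} bp with any peak of \code{set_b} -- a simple
#' presence/absence differential peak call between two conditions.
#'
#' @param set_a,set_b \code{peak_set} objects.
#' @param min_overlap minimum overlap in bp that counts as "shared"
#'   (default 1, i.e. any overlap removes a peak from the differential set).
#' @return A \code{peak_set} labeled \code{"<condA>_specific"}.
#' @export
differential_peaks <- function(set_a, set_b, min_overlap = 1L) {
  .check_peaks_sorted(set_a, attr(set_a, "condition") %||% "set_a")
  .check_peaks_sorted(set_b, attr(set_b, "condition") %||% "set_b")
  label <- paste0(attr(set_a, "condition") %||% "A", "_specific")
  if (nrow(set_a) == 0) {
    return(peak_set(as.data.frame(set_a)[0, , drop = FALSE], label))
  }
  if (nrow(set_b) == 0) {
    return(peak_set(as.data.frame(set_a), label))
  }
  hits <- .find_overlaps(.as_granges(set_a), .as_granges(set_b),
                                      minoverlap = as.integer(min_overlap))
  keep <- setdiff(seq_len(nrow(set_a)), unique(S4Vectors::queryHits(hits)))
  peak_set(as.data.frame(set_a)[keep, , drop = FALSE], label)
}

#' Assign peaks to the nearest gene within a distance cutoff
#'
#' Distance is the gap in bp between the peak interval and the gene body
#' (0 when they overlap or abut); strand is ignored. Ties on distance are
#' broken by the lexicographically smallest gene id. Peaks with no gene within
#' \code{max_dist} are reported with \code{NA}.
#'
#' @param peaks a \code{peak_set}.
#' @param genes a \code{gene_table}.
#' @param max_dist maximum gap in bp (default 25000).
#' @return data frame with one row per peak: \code{chrom}, \code{start},
#'   \code{end}, \code{gene_id}, \code{distance}.
#' @export
assign_peaks_to_genes <- function(peaks, genes, max_dist = 25000L) {
  .check_peaks_sorted(peaks, attr(peaks, "condition") %||% "peaks")
  if (!.is_bed_sorted(genes$chrom, genes$start, genes$end)) {
    stop("gene table is not sorted by (chrom, start)")
  }
  if (max_dist < 0) stop("max_dist must be nonnegative")
  out <- data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                    gene_id = NA_character_, distance = NA_integer_,
                    stringsAsFactors = FALSE)
  if (nrow(peaks) == 0 || nrow(genes) == 0) return(out)
  pgr <- .as_granges(peaks)
  ggr <- .as_granges(genes)
  hits <- .find_overlaps(pgr, ggr, maxgap = as.integer(max_dist))
  if (length(hits) == 0) return(out)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(pgr[qh], ggr[sh])
  gid <- genes$id[sh]
  o <- order(qh, d, gid, method = "radix")
  first <- !duplicated(qh[o])
  sel <- o[first]
  out$gene_id[qh[sel]] <- gid[sel]
  out$distance[qh[sel]] <- as.integer(d[sel])
  out
}

#' Single-cell ATAC cell quality control
#'
#' A barcode passes iff its fragment count is strictly greater than
#' \code{min_fragments} and its fraction of fragments in promoters is strictly
#' greater than \code{min_promoter_ratio}; boundary values fail.
#'
#' @param records data frame with columns \code{barcode}, \code{n_fragments},
#'   \code{promoter_ratio}.
#' @param min_fragments fragment-count threshold (default 1000, strict).
#' @param min_promoter_ratio promoter-ratio threshold (default 0.2, strict).
#' @return The input with an added logical \code{pass} column.
#' @export
atac_cell_qc <- function(records, min_fragments = 1000,
                         min_promoter_ratio = 0.2) {
  req <- c("barcode", "n_fragments", "promoter_ratio")
  if (!all(req %in% names(records))) {
    stop("QC records require columns barcode, n_fragments, promoter_ratio")
  }
  if (any(records$n_fragments < 0)) stop("n_fragments must be nonnegative")
  if (any(records$promoter_ratio < 0 | records$promoter_ratio > 1)) {
    stop("promoter_ratio must lie in [0, 1]")
  }
  records$pass <- records$n_fragments > min_fragments &
    records$promoter_ratio > min_promoter_ratio
  records
}
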