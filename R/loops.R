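#' Construct a validated chromatin-loop set
#'
#' A loop is a genomic span with two boundary-anchor intervals on the same
#' chromosome; anchor A must end at or before anchor B starts, and the span
#' runs from the start of anchor A to the end of anchor B (BED convention).
#'
#' @param x data frame with columns \code{id}, \code{chrom}, \code{a_start},
#'   \code{a_end}, \code{b_start}, \code{b_end}. An optional \code{chrom2}
#'   column (second BEDPE chromosome) is validated against \code{chrom} and
#'   dropped.
#' @return A \code{loop_set} data frame with derived \code{span_start},
#'   \code{span_end}, sorted by (chrom, span_start).
#' @export
loop_set <- function(x) {
  req <- c("id", "chrom", "a_start", "a_end", "b_start", "b_end")
  if (!all(req %in% names(x))) {
    stop("loop set requires columns id, chrom, a_start, a_end, b_start, b_end")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if ("chrom2" %in% names(x)) {
    if (any(x$chrom2 != x$chrom)) {
      stop("loop anchors must lie on the same chromosome")
    }
    x$chrom2 <- NULL
  }
  x$id <- as.character(x$id)
  x$chrom <- as.character(x$chrom)
  for (cl in c("a_start", "a_end", "b_start", "b_end")) {
    x[[cl]] <- as.integer(x[[cl]])
  }
  if (anyDuplicated(x$id)) stop("loop ids must be unique")
  if (any(x$a_start < 0L) || any(x$a_end <= x$a_start) ||
      any(x$b_end <= x$b_start)) {
    stop("loop anchors must be valid intervals")
  }
  if (any(x$a_end > x$b_start)) {
    stop("anchor A must end at or before anchor B starts")
  }
  x$span_start <- x$a_start
  x$span_end <- x$b_end
  x <- x[.bed_order(x$chrom, x$span_start, x$span_end), , drop = FALSE]
  rownames(x) <- NULL
  structure(x, class = c("loop_set", "data.frame"))
}

#' @export
print.loop_set <- function(x, ...) {
  cat(sprintf("loop_set: %d loops on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Genes whose TSS falls inside each loop span
#'
#' Membership is by transcription start site: a gene belongs to a loop iff its
#' TSS lies in \code{[span_start, span_end)} on the loop's chromosome. Member
#' ids are ordered by TSS position.
#'
#' @param loops a [loop_set()] (one or more rows).
#' @param genes a [gene_table()].
#' @return named list (by loop id) of character vectors of gene ids.
#' @export
genes_in_loop <- function(loops, genes) {
  g <- genes[order(genes$chrom, genes$tss, genes$id, method = "radix"), ,
             drop = FALSE]
  out <- vector("list", nrow(loops))
  names(out) <- loops$id
  for (i in seq_len(nrow(loops))) {
    sel <- g$chrom == loops$chrom[i] &
      g$tss >= loops$span_start[i] & g$tss < loops$span_end[i]
    out[[i]] <- g$id[sel]
  }
  out
}

#' Classify loops by differential boundary-peak status
#'
#' A loop is \emph{direct} iff a differential peak overlaps either boundary
#' anchor (each optionally extended by \code{boundary_flank} bp on both
#' sides); otherwise \emph{indirect} iff its span overlaps the span of at
#' least one direct loop; otherwise \emph{unaffected}. Indirectness does not
#' chain: overlapping only indirect loops leaves a loop unaffected.
#'
#' @param loops a [loop_set()].
#' @param diff_peaks a [peak_set()] of condition-specific (differential)
#'   peaks, e.g. from [differential_peaks()].
#' @param boundary_flank symmetric extension of each anchor in bp
#'   (default 0); lets bare BEDPE anchors stand in for wider boundary domains.
#' @return list with \code{labels} (data frame \code{loop_id}, \code{label})
#'   and \code{summary} (list of per-class counts and fractions; the fractions
#'   sum to 1).
#' @export
classify_loops <- function(loops, diff_peaks, boundary_flank = 0L) {
  if (boundary_flank < 0) stop("boundary_flank must be nonnegative")
  n <- nrow(loops)
  label <- rep("unaffected", n)
  if (n > 0 && nrow(diff_peaks) > 0) {
    anchors <- data.frame(
      chrom = rep(loops$chrom, 2L),
      start = pmax(0L, c(loops$a_start, loops$b_start) -
                     as.integer(boundary_flank)),
      end = c(loops$a_end, loops$b_end) + as.integer(boundary_flank)
    )
    hits <- .find_overlaps(.as_granges(anchors),
                                        .as_granges(diff_peaks))
    direct_idx <- unique((S4Vectors::queryHits(hits) - 1L) %% n + 1L)
    label[direct_idx] <- "direct"
    if (length(direct_idx) > 0 && length(direct_idx) < n) {
      spans <- data.frame(chrom = loops$chrom, start = loops$span_start,
                          end = loops$span_end)
      dhits <- .find_overlaps(
        .as_granges(spans), .as_granges(spans[direct_idx, , drop = FALSE]))
      touches <- unique(S4Vectors::queryHits(dhits))
      label[setdiff(touches, direct_idx)] <- "indirect"
    }
  }
  counts <- c(direct = sum(label == "direct"),
              indirect = sum(label == "indirect"),
              unaffected = sum(label == "unaffected"))
  fractions <- if (n > 0) counts / n else counts * NA_real_
  list(
    labels = data.frame(loop_id = loops$id, label = label,
                        stringsAsFactors = FALSE),
    summary = list(n_loops = n, counts = as.list(counts),
                   fractions = as.list(fractions))
  )
}
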