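#' Cut-site (or coverage) matrix around reference sites
#'
#' Builds the sites-by-bins count matrix behind "reads per 10 bp" heatmaps:
#' for every site (reference point = interval midpoint) a window of
#' \code{2 * window} bp is divided into \code{2 * window / bin_width} bins.
#' In the default \code{"cutsite"} mode both fragment ends -- the transposase
#' cut sites, positions \code{start} and \code{end - 1} -- are counted into
#' the bin containing them; in \code{"coverage"} mode every bin a fragment
#' overlaps is incremented. Rows of minus-strand sites are reversed when
#' \code{orient_by_strand} so that all rows read 5' to 3'.
#'
#' Overlapping site windows each count the same fragment (rows are
#' independent, matching per-site heatmap semantics).
#'
#' @param frags a [fragment_table()].
#' @param sites a [peak_set()] (optionally with \code{name} and \code{strand}
#'   columns; missing strands are treated as \code{+}).
#' @param window half-width of the window in bp (default 1000).
#' @param bin_width bin size in bp (default 10); must divide \code{window}.
#' @param orient_by_strand reverse bins of minus-strand sites (default TRUE).
#' @param mode \code{"cutsite"} (default) or \code{"coverage"}.
#' @return integer matrix, sites x bins, with site ids as rownames and
#'   attributes \code{window}, \code{bin_width}, \code{mode}.
#' @export
profile_matrix <- function(frags, sites, window = 1000L, bin_width = 10L,
                           orient_by_strand = TRUE,
                           mode = c("cutsite", "coverage")) {
  mode <- match.arg(mode)
  window <- as.integer(window)
  bin_width <- as.integer(bin_width)
  if (window %% bin_width != 0L) {
    stop("window (", window, ") must be divisible by bin_width (",
         bin_width, ")")
  }
  n_bins <- 2L * window %/% bin_width
  n_sites <- nrow(sites)
  ids <- if ("name" %in% names(sites) && !anyDuplicated(sites$name)) {
    as.character(sites$name)
  } else {
    sprintf("%s:%d-%d", sites$chrom, sites$start, sites$end)
  }
  mat <- matrix(0L, nrow = n_sites, ncol = n_bins, dimnames = list(ids, NULL))
  if (n_sites > 0 && nrow(frags) > 0) {
    centers <- (sites$start + sites$end) %/% 2L
    left <- centers - window
    win <- data.frame(chrom = sites$chrom, start = left,
                      end = centers + window)
    # windows near the chromosome origin may have negative BED starts; shift
    # all coordinates into GRanges space with a common offset instead
    off <- max(0L, -min(win$start))
    wgr <- GenomicRanges::GRanges(
      win$chrom, IRanges::IRanges(win$start + off + 1L, win$end + off))
    if (mode == "cutsite") {
      pos <- c(frags$start, frags$end - 1L)
      pchrom <- rep(frags$chrom, 2L)
      pgr <- GenomicRanges::GRanges(
        pchrom, IRanges::IRanges(pos + off + 1L, width = 1L))
      hits <- .find_overlaps(wgr, pgr)
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      if (length(qh)) {
        bin <- (pos[sh] - left[qh]) %/% bin_width
        tab <- table(factor(qh, levels = seq_len(n_sites)),
                     factor(bin, levels = 0:(n_bins - 1L)))
        mat <- mat + matrix(as.integer(tab), nrow = n_sites,
                            dimnames = list(ids, NULL))
      }
    } else {
      fgr <- GenomicRanges::GRanges(
        frags$chrom, IRanges::IRanges(frags$start + off + 1L,
                                      frags$end + off))
      hits <- .find_overlaps(wgr, fgr)
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      if (length(qh)) {
        b0 <- pmax(0L, (frags$start[sh] - left[qh]) %/% bin_width)
        b1 <- pmin(n_bins - 1L, (frags$end[sh] - 1L - left[qh]) %/% bin_width)
        reps <- b1 - b0 + 1L
        rows <- rep(qh, reps)
        bins <- sequence(reps) - 1L + rep(b0, reps)
        tab <- table(factor(rows, levels = seq_len(n_sites)),
                     factor(bins, levels = 0:(n_bins - 1L)))
        mat <- mat + matrix(as.integer(tab), nrow = n_sites,
                            dimnames = list(ids, NULL))
      }
    }
    if (orient_by_strand && "strand" %in% names(sites)) {
      minus <- which(sites$strand == "-")
      if (length(minus)) {
        mat[minus, ] <- mat[minus, n_bins:1, drop = FALSE]
      }
    }
  }
  structure(mat, window = window, bin_width = bin_width, mode = mode,
            class = c("signal_profile", class(mat)))
}

#' Column-mean profile of a signal matrix
#' @param mat a matrix from [profile_matrix()].
#' @return numeric vector of per-bin means across sites.
#' @export
profile_means <- function(mat) colMeans(unclass(mat))

#' Centered moving average with edge truncation
#'
#' @param profile numeric vector (e.g. per-bin column means).
#' @param span_bins odd window size in bins (default 5); near the edges the
#'   mean is taken over the available bins only, so length is preserved.
#' @return smoothed numeric vector of the same length.
#' @export
moving_average <- function(profile, span_bins = 5L) {
  span_bins <- as.integer(span_bins)
  if (span_bins < 1L || span_bins %% 2L == 0L) {
    stop("span_bins must be an odd positive integer")
  }
  n <- length(profile)
  k <- span_bins %/% 2L
  cs <- cumsum(c(0, profile))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Write a signal matrix as TSV (site ids as first column)
#' @param mat a [profile_matrix()] result.
#' @param path output path.
#' @export
write_profile_matrix <- function(mat, path) {
  df <- data.frame(site = rownames(mat), unclass(mat), check.names = FALSE)
  names(df)[-1] <- paste0("bin", seq_len(ncol(mat)) - 1L)
  .write_tsv(df, path)
  invisible(path)
}
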