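#' Mean log fold-change over a loop's member genes
#'
#' @param member_ids character vector of gene ids in the loop.
#' @param logfc a \code{gene_logfc} data frame (\code{gene_id},
#'   \code{logfc}).
#' @param min_genes minimum members with a fold-change for the loop to be
#'   scored (default 2).
#' @return the arithmetic mean, or \code{NA_real_} when fewer than
#'   \code{min_genes} members resolve (the caller logs and skips such loops).
#' @export
loop_mean_logfc <- function(member_ids, logfc, min_genes = 2L) {
  v <- logfc$logfc[match(member_ids, logfc$gene_id)]
  v <- v[!is.na(v)]
  if (length(v) < min_genes) return(NA_real_)
  mean(v)
}

#' Sliding-window null distribution for one chromosome
#'
#' The background against which an L-gene loop is judged: the mean fold-change
#' of every run of L consecutive genes (in TSS order) on the same chromosome,
#' values kept with multiplicity. Windows never span chromosome ends.
#'
#' @param chrom_logfc numeric vector of per-gene log fold-changes in TSS
#'   order along one chromosome.
#' @param window_len number of consecutive genes per window (L).
#' @param chrom chromosome name carried in the result (optional).
#' @return A \code{window_null}: list with \code{chrom}, \code{window_len},
#'   \code{values} (length \code{n_genes - L + 1}), \code{n_windows}.
#' @export
window_null <- function(chrom_logfc, window_len, chrom = NA_character_) {
  n <- length(chrom_logfc)
  L <- as.integer(window_len)
  if (L < 1L || L > n) {
    stop("window length ", L, " invalid for chromosome '", chrom,
         "' with ", n, " genes")
  }
  # plain mean() per slice: bit-identical to the loop means it is compared to
  vals <- vapply(seq_len(n - L + 1L),
                 function(i) mean(chrom_logfc[i:(i + L - 1L)]), numeric(1))
  structure(list(chrom = chrom, window_len = L, values = vals,
                 n_windows = length(vals)),
            class = "window_null")
}

#' Percentile of a loop mean within its window null
#'
#' Empirical CDF with ties counted: \code{100 * #(null <= x) / n_windows}.
#' When the loop's own window is part of the null the attainable floor is
#' \code{100 / n_windows}.
#'
#' @param mean_logfc the loop-averaged log fold-change.
#' @param null a [window_null()].
#' @return percentile in \code{[0, 100]}.
#' @export
loop_percentile <- function(mean_logfc, null) {
  if (null$n_windows < 1) stop("empty window null")
  100 * sum(null$values <= mean_logfc) / null$n_windows
}

#' Score every loop against its sliding-window null
#'
#' For each loop with at least \code{min_genes} member genes carrying a
#' fold-change, computes the member-mean log fold-change and its percentile in
#' the null of all same-length gene windows on the same chromosome. Nulls are
#' cached per (chromosome, window length). Gene order within a chromosome is
#' ascending TSS.
#'
#' @param loops a [loop_set()].
#' @param genes a [gene_table()].
#' @param logfc a \code{gene_logfc} data frame.
#' @param labels optional data frame (\code{loop_id}, \code{label}) from
#'   [classify_loops()]; merged into the output when given.
#' @param min_genes minimum resolvable member genes (default 2).
#' @param include_own_window keep the loop's own gene window in its null
#'   (default TRUE; setting FALSE removes one occurrence of that window).
#' @param compute_p also report a two-sided empirical p-value
#'   \code{2 * min(r, n + 1 - r) / (n + 1)} (r = rank count at or below) and
#'   its Benjamini-Hochberg adjustment across scored loops (default FALSE).
#' @return A data frame, one row per scored loop, ordered by
#'   (chrom, span_start): loop id, coordinates, \code{n_genes},
#'   \code{mean_logfc}, \code{null_size}, \code{percentile}, optional
#'   \code{label}, \code{p_value}, \code{q_value}. Skipped loops and reasons
#'   are attached as attribute \code{"skipped"}.
#' @export
score_all_loops <- function(loops, genes, logfc, labels = NULL,
                            min_genes = 2L, include_own_window = TRUE,
                            compute_p = FALSE) {
  g <- genes[order(genes$chrom, genes$tss, genes$id, method = "radix"), ,
             drop = FALSE]
  g$logfc <- logfc$logfc[match(g$id, logfc$gene_id)]
  miss <- sum(is.na(g$logfc))
  if (miss > 0) {
    warning(miss, " gene(s) without a fold-change dropped from the null")
    g <- g[!is.na(g$logfc), , drop = FALSE]
  }
  by_chrom <- split(g, g$chrom)
  members <- genes_in_loop(loops, genes)
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(loops))
  skipped <- list()
  for (i in seq_len(nrow(loops))) {
    chrom <- loops$chrom[i]
    ids <- intersect(members[[i]], g$id)
    L <- length(ids)
    if (L < min_genes) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        loop_id = loops$id[i],
        reason = sprintf("%d resolvable member gene(s) < min_genes = %d",
                         L, min_genes))
      next
    }
    cg <- by_chrom[[chrom]]
    key <- paste0(chrom, ":", L)
    if (is.null(cache[[key]])) {
      cache[[key]] <- window_null(cg$logfc, L, chrom = chrom)
    }
    null <- cache[[key]]
    mlfc <- mean(cg$logfc[match(ids, cg$id)])
    if (!include_own_window) {
      first <- match(ids[1], cg$id)
      vals <- null$values[-first]
      null <- structure(list(chrom = chrom, window_len = L, values = vals,
                             n_windows = length(vals)),
                        class = "window_null")
      if (null$n_windows == 0) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          loop_id = loops$id[i], reason = "null empty after own-window removal")
        next
      }
    }
    rows[[i]] <- data.frame(
      loop_id = loops$id[i], chrom = chrom,
      span_start = loops$span_start[i], span_end = loops$span_end[i],
      n_genes = L, mean_logfc = mlfc, null_size = null$n_windows,
      percentile = loop_percentile(mlfc, null),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    warning("no eligible loops to score")
    out <- data.frame(loop_id = character(), chrom = character(),
                      span_start = integer(), span_end = integer(),
                      n_genes = integer(), mean_logfc = numeric(),
                      null_size = integer(), percentile = numeric())
  }
  out <- out[.bed_order(out$chrom, out$span_start, out$span_end), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(labels)) {
    out$label <- labels$label[match(out$loop_id, labels$loop_id)]
  }
  if (compute_p && nrow(out) > 0) {
    r <- out$percentile * out$null_size / 100
    p <- 2 * pmin(r, out$null_size + 1 - r) / (out$null_size + 1)
    out$p_value <- pmin(p, 1)
    out$q_value <- p.adjust(out$p_value, method = "BH")
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(loop_id = character(), reason = character())
  attr(out, "include_own_window") <- include_own_window
  out
}

#' Beta distribution fit to the inter-quartile range of percentiles
#'
#' Restricts the percentile sample to values between its own 25th and 75th
#' empirical percentiles, rescales that subsample linearly onto \code{[0, 1]},
#' and fits a Beta distribution by the method of moments:
#' \code{k = m(1 - m)/v - 1}, \code{alpha = m k}, \code{beta = (1 - m) k}.
#' Q-Q points pair Beta quantiles at plotting positions \code{(i - 0.5)/n}
#' with the sorted observed percentiles (divided by 100) of the full sample.
#'
#' @param percentiles numeric vector of loop percentiles in \code{[0, 100]};
#'   at least 8 distinct values are required.
#' @return A \code{beta_qq}: list with \code{alpha}, \code{beta}, and
#'   \code{qq_points} (data frame \code{theoretical}, \code{observed}, both
#'   monotone).
#' @export
fit_beta_iqr <- function(percentiles) {
  p <- percentiles[!is.na(percentiles)]
  if (length(unique(p)) < 8) {
    stop("degenerate percentile distribution: fewer than 8 distinct values")
  }
  q <- quantile(p, c(0.25, 0.75), names = FALSE)
  sub <- p[p >= q[1] & p <= q[2]]
  if (q[2] <= q[1]) {
    stop("degenerate percentile distribution: zero-width inter-quartile range")
  }
  x <- (sub - q[1]) / (q[2] - q[1])
  m <- mean(x)
  v <- var(x)
  if (!is.finite(v) || v <= 0) {
    stop("degenerate percentile distribution: zero variance in IQR subsample")
  }
  k <- m * (1 - m) / v - 1
  if (k <= 0) {
    stop("method-of-moments Beta fit failed: variance too large for a Beta")
  }
  n <- length(p)
  structure(list(
    alpha = m * k, beta = (1 - m) * k,
    qq_points = data.frame(
      theoretical = qbeta((seq_len(n) - 0.5) / n, m * k, (1 - m) * k),
      observed = sort(p) / 100)
  ), class = "beta_qq")
}

#' @export
print.beta_qq <- function(x, ...) {
  cat(sprintf("Beta(alpha = %.3f, beta = %.3f) IQR fit; %d Q-Q points\n",
              x$alpha, x$beta, nrow(x$qq_points)))
  invisible(x)
}

#' Write loop scores as TSV
#' @param scores output of [score_all_loops()].
#' @param path output path.
#' @export
write_loop_scores <- function(scores, path) {
  .write_tsv(as.data.frame(scores), path)
  invisible(path)
}
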