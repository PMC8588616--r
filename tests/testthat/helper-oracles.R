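# Independent brute-force oracles and small fixture builders. These never
# call the package's interval/statistic machinery: everything is explicit
# enumeration so the dual-route checks stay honest.

bf_overlap <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 && s1 < e2 && s2 < e1
}

# all-pairs O(n*m) overlap enumeration on BED data frames
bf_find_overlaps <- function(q, s, min_overlap = 1L) {
  out <- list()
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(nrow(s))) {
      if (q$chrom[i] == s$chrom[j]) {
        ov <- min(q$end[i], s$end[j]) - max(q$start[i], s$start[j])
        if (ov >= min_overlap) out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(query_idx = integer(), subject_idx = integer()))
  }
  m <- do.call(rbind, out)
  df <- data.frame(query_idx = m[, 1], subject_idx = m[, 2])
  df[order(df$query_idx, df$subject_idx), , drop = FALSE]
}

bf_differential <- function(a, b) {
  keep <- vapply(seq_len(nrow(a)), function(i) {
    !any(vapply(seq_len(nrow(b)), function(j) {
      bf_overlap(a$chrom[i], a$start[i], a$end[i],
                 b$chrom[j], b$start[j], b$end[j])
    }, logical(1)))
  }, logical(1))
  a[keep, , drop = FALSE]
}

# gap distance between half-open intervals on one chromosome (0 if touching)
bf_gap <- function(s1, e1, s2, e2) {
  if (s1 < e2 && s2 < e1) return(0L)
  max(0L, max(s2 - e1, s1 - e2))
}

bf_nearest_gene <- function(peaks, genes, max_dist = 25000L) {
  gene_id <- rep(NA_character_, nrow(peaks))
  distance <- rep(NA_integer_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    best_d <- Inf
    best_id <- NA_character_
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      d <- bf_gap(peaks$start[i], peaks$end[i],
                  genes$start[j], genes$end[j])
      if (d < best_d || (d == best_d && !is.na(best_id) &&
                         genes$id[j] < best_id)) {
        best_d <- d
        best_id <- genes$id[j]
      }
    }
    if (is.finite(best_d) && best_d <= max_dist) {
      gene_id[i] <- best_id
      distance[i] <- as.integer(best_d)
    }
  }
  data.frame(gene_id = gene_id, distance = distance,
             stringsAsFactors = FALSE)
}

# naive loop percentile: enumerate every window of L consecutive genes
bf_loop_percentile <- function(chrom_logfc, member_idx) {
  L <- length(member_idx)
  n <- length(chrom_logfc)
  wins <- vapply(seq_len(n - L + 1L),
                 function(i) mean(chrom_logfc[i:(i + L - 1L)]), numeric(1))
  m <- mean(chrom_logfc[member_idx])
  100 * sum(wins <= m) / length(wins)
}

rand_peaks <- function(n, chroms = c("chr1", "chr2"), span = 10000L) {
  start <- sample.int(span, n, replace = TRUE) - 1L
  df <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                   start = start,
                   end = start + sample.int(500L, n, replace = TRUE),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  df[order(df$chrom, df$start, df$end, method = "radix"), , drop = FALSE]
}

# minimal gene table: k evenly spaced genes on one chromosome
toy_genes <- function(k, chrom = "chr1", spacing = 1000L, len = 300L,
                      prefix = "g") {
  start <- (seq_len(k) - 1L) * spacing + 100L
  gene_table(data.frame(
    chrom = chrom, start = start, end = start + len, strand = "+",
    id = sprintf("%s%03d", prefix, seq_len(k)),
    stringsAsFactors = FALSE))
}

# cell-by-gene matrix from a dense genes x cells matrix
toy_matrix <- function(counts, condition, cell_type = "neoplastic") {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  }
  cell_gene_matrix(counts, data.frame(
    barcode = colnames(counts), condition = condition,
    cell_type = rep_len(cell_type, ncol(counts)),
    stringsAsFactors = FALSE))
}

# logfc table from a named numeric vector
toy_logfc <- function(v) {
  structure(data.frame(gene_id = names(v), logfc = unname(v),
                       stringsAsFactors = FALSE),
            numerator = "KO", denominator = "WT", pseudocount = 1,
            target_sum = 1e4, class = c("gene_logfc", "data.frame"))
}

# drop profile_matrix attributes so flipped/subset comparisons see pure
# matrices
strip_profile <- function(m) {
  a <- attributes(m)
  attributes(m) <- a[intersect(names(a), c("dim", "dimnames"))]
  m
}
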