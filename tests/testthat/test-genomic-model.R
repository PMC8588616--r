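test_that("interval overlap follows half-open semantics", {
  a <- list(chrom = "chr1", start = 100L, end = 200L)
  expect_true(interval_overlaps(a, list(chrom = "chr1", start = 150L,
                                        end = 250L)))
  expect_false(interval_overlaps(a, list(chrom = "chr1", start = 200L,
                                         end = 300L)))
  expect_false(interval_overlaps(a, list(chrom = "chr2", start = 100L,
                                         end = 200L)))
})

test_that("peak_set validates, sorts, and rejects duplicates", {
  p <- peak_set(data.frame(chrom = c("chr2", "chr1"), start = c(5L, 10L),
                           end = c(50L, 20L)), "WT")
  expect_identical(p$chrom, c("chr1", "chr2"))
  expect_identical(attr(p, "condition"), "WT")
  expect_error(peak_set(data.frame(chrom = "chr1", start = 10L, end = 10L)),
               "end > start")
  expect_error(peak_set(data.frame(chrom = c("chr1", "chr1"),
                                   start = c(1L, 1L), end = c(5L, 5L))),
               "duplicate")
  expect_error(peak_set(data.frame(chrom = "chr1", start = 1L, end = 5L,
                                   score = -1)), "nonnegative")
})

test_that("batched overlap matches explicit cases and errors on unsorted", {
  q <- peak_set(data.frame(chrom = "chr1", start = 100L, end = 200L), "q")
  s <- peak_set(data.frame(chrom = "chr1", start = c(150L, 300L),
                           end = c(250L, 400L)), "s")
  expect_identical(find_overlaps_batch(q, s),
                   data.frame(query_idx = 1L, subject_idx = 1L))
  expect_identical(find_overlaps_batch(q, q),
                   data.frame(query_idx = 1L, subject_idx = 1L))
  unsorted <- structure(
    data.frame(chrom = c("chr1", "chr1"), start = c(500L, 100L),
               end = c(600L, 200L)),
    condition = "messy", class = c("peak_set", "data.frame"))
  expect_error(find_overlaps_batch(unsorted, s), "messy")
})

test_that("batched overlap equals the all-pairs brute-force oracle", {
  set.seed(42)
  for (rep in 1:200) {
    q <- rand_peaks(sample.int(50, 1))
    s <- rand_peaks(sample.int(50, 1))
    got <- find_overlaps_batch(peak_set(q, "q"), peak_set(s, "s"))
    want <- bf_find_overlaps(q, s)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("differential peaks subtract shared sites", {
  a <- peak_set(data.frame(chrom = "chr1", start = 100L, end = 200L), "WT")
  b_olap <- peak_set(data.frame(chrom = "chr1", start = 150L, end = 250L),
                     "KO")
  b_far <- peak_set(data.frame(chrom = "chr1", start = 300L, end = 400L),
                    "KO")
  expect_identical(nrow(differential_peaks(a, b_olap)), 0L)
  d <- differential_peaks(a, b_far)
  expect_identical(nrow(d), 1L)
  expect_identical(attr(d, "condition"), "WT_specific")
  empty <- peak_set(data.frame(chrom = character(), start = integer(),
                               end = integer()), "KO")
  expect_identical(as.data.frame(differential_peaks(a, empty))[, 1:3],
                   as.data.frame(a)[, 1:3])
  expect_identical(nrow(differential_peaks(empty, a)), 0L)
})

test_that("differential peaks partition the first set and self-subtract", {
  set.seed(7)
  for (rep in 1:50) {
    a <- peak_set(rand_peaks(sample.int(40, 1)), "A")
    b <- peak_set(rand_peaks(sample.int(40, 1)), "B")
    d <- differential_peaks(a, b)
    want <- bf_differential(as.data.frame(a), as.data.frame(b))
    rownames(want) <- NULL
    expect_identical(as.data.frame(d)[, c("chrom", "start", "end")],
                     want[, c("chrom", "start", "end")])
    expect_identical(nrow(differential_peaks(a, a)), 0L)
    # differential + complement partitions A
    expect_identical(nrow(d) + (nrow(a) - nrow(d)), nrow(a))
  }
})

test_that("peak-to-gene assignment uses gap distance with a 25 kb cutoff", {
  genes <- gene_table(data.frame(
    chrom = "chr1", start = c(10000L, 60000L), end = c(20000L, 70000L),
    strand = "+", id = c("gA", "gB")))
  near <- peak_set(data.frame(chrom = "chr1", start = 30000L, end = 30200L),
                   "p")
  got <- assign_peaks_to_genes(near, genes)
  expect_identical(got$gene_id, "gA")
  expect_identical(got$distance, 10000L)

  only_far <- gene_table(data.frame(chrom = "chr1", start = 60000L,
                                    end = 70000L, strand = "+", id = "gB"))
  got2 <- assign_peaks_to_genes(near, only_far)
  expect_true(is.na(got2$gene_id))

  inside <- peak_set(data.frame(chrom = "chr1", start = 12000L,
                                end = 12200L), "p")
  got3 <- assign_peaks_to_genes(inside, genes)
  expect_identical(got3$distance, 0L)
})

test_that("peak-to-gene assignment matches the brute-force oracle and ties
          break by smallest gene id", {
  set.seed(11)
  for (rep in 1:60) {
    k <- sample(2:12, 1)
    gs <- sample.int(8000L, k)
    genes <- gene_table(data.frame(
      chrom = sample(c("chr1", "chr2"), k, replace = TRUE),
      start = gs, end = gs + sample.int(400L, k, replace = TRUE),
      strand = "+", id = sprintf("g%02d", sample.int(99L, k))))
    peaks <- peak_set(rand_peaks(sample.int(20, 1)), "p")
    got <- assign_peaks_to_genes(peaks, genes, max_dist = 2000L)
    want <- bf_nearest_gene(as.data.frame(peaks), as.data.frame(genes),
                            max_dist = 2000L)
    expect_identical(got$gene_id, want$gene_id)
    expect_identical(got$distance, want$distance)
  }
  # explicit equidistant tie
  genes <- gene_table(data.frame(
    chrom = "chr1", start = c(0L, 2000L), end = c(500L, 2500L),
    strand = "+", id = c("zz", "aa")))
  peak <- peak_set(data.frame(chrom = "chr1", start = 1000L, end = 1500L),
                   "p")
  expect_identical(assign_peaks_to_genes(peak, genes)$gene_id, "aa")
})

test_that("assignment distances are invariant under coordinate translation", {
  set.seed(3)
  gs <- sample.int(5000L, 6)
  genes <- data.frame(chrom = "chr1", start = gs, end = gs + 300L,
                      strand = "+", id = sprintf("g%d", 1:6))
  peaks <- rand_peaks(10, chroms = "chr1")
  base <- assign_peaks_to_genes(peak_set(peaks, "p"), gene_table(genes))
  shift <- 12345L
  peaks2 <- transform(peaks, start = start + shift, end = end + shift)
  genes2 <- transform(genes, start = start + shift, end = end + shift)
  moved <- assign_peaks_to_genes(peak_set(peaks2, "p"), gene_table(genes2))
  expect_identical(base$gene_id, moved$gene_id)
  expect_identical(base$distance, moved$distance)
})

test_that("cell QC applies strict thresholds and boundary cases fail", {
  rec <- data.frame(
    barcode = c("a", "b", "c", "d"),
    n_fragments = c(1500L, 1000L, 5000L, 1001L),
    promoter_ratio = c(0.25, 0.50, 0.20, 0.21))
  got <- atac_cell_qc(rec)
  expect_identical(got$pass, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(atac_cell_qc(transform(rec, promoter_ratio = 1.5)),
               "\\[0, 1\\]")
})

test_that("raising either QC threshold never adds a passing cell", {
  set.seed(5)
  rec <- data.frame(barcode = sprintf("c%03d", 1:200),
                    n_fragments = rnbinom(200, size = 1.2, mu = 2500),
                    promoter_ratio = rbeta(200, 2.5, 6))
  base <- atac_cell_qc(rec)$pass
  for (mf in c(1200, 2000)) {
    expect_true(all(atac_cell_qc(rec, min_fragments = mf)$pass <= base))
  }
  for (mr in c(0.25, 0.4)) {
    expect_true(all(atac_cell_qc(rec, min_promoter_ratio = mr)$pass <= base))
  }
})
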