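small_cfg <- function(...) {
  sim_config(seed = 11, n_chroms = 2, genes_per_chrom = 60, n_loops = 8,
             genes_per_loop = 3, n_effect_loops = 3,
             n_cells_per_condition = 40, mean_depth = 600,
             n_fragments = 3000, background_peaks_per_chrom = 10, ...)
}

test_that("genome construction places exactly the requested loop members", {
  cfg <- sim_config(seed = 1, n_chroms = 1, genes_per_chrom = 20,
                    n_loops = 2, genes_per_loop = 3, n_effect_loops = 1,
                    n_cells_per_condition = 5, mean_depth = 100)
  s <- simulate_genome_and_loops(cfg)
  members <- genes_in_loop(s$loops, s$genes)
  expect_true(all(lengths(members) == 3L))
  expect_identical(sort(names(members)), sort(s$loops$id))
  # loops pairwise non-overlapping
  for (i in seq_len(nrow(s$loops) - 1L)) {
    expect_lte(s$loops$span_end[i], s$loops$span_start[i + 1L])
  }
  expect_error(sim_config(n_chroms = 1, genes_per_chrom = 5, n_loops = 10,
                          genes_per_loop = 3) |> simulate_genome_and_loops(),
               "capacity")
})

test_that("generators are pure functions of the config", {
  cfg <- small_cfg()
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$loops, s2$loops)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.matrix(s1$counts$counts), as.matrix(s2$counts$counts))
  expect_identical(s1$fragments, s2$fragments)
  expect_identical(as.data.frame(s1$peaks$ko), as.data.frame(s2$peaks$ko))
})

test_that("null simulation is exchangeable across conditions", {
  cfg <- sim_config(seed = 3, n_chroms = 1, genes_per_chrom = 50,
                    n_loops = 4, genes_per_loop = 3, n_effect_loops = 0,
                    fold_change = 1, n_cells_per_condition = 200,
                    mean_depth = 500)
  s <- simulate_genome_and_loops(cfg)
  m <- simulate_counts(cfg, s$genes, s$truth)
  lfc <- cell_averaged_logfc(m, "KO", "WT", "neoplastic")
  expect_lt(mean(abs(lfc$logfc)), 0.2)
})

test_that("counts follow the negative-binomial mean-variance relationship", {
  cfg <- sim_config(seed = 5, n_chroms = 1, genes_per_chrom = 30,
                    n_loops = 2, genes_per_loop = 3, n_effect_loops = 0,
                    n_cells_per_condition = 2000, mean_depth = 600,
                    dispersion = 0.5, mean_sdlog = 0.3,
                    cell_depth_sdlog = 0)
  s <- simulate_genome_and_loops(cfg)
  m <- simulate_counts(cfg, s$genes, s$truth)
  wt <- m$counts[, m$cell_meta$condition == "WT"]
  mu <- Matrix::rowMeans(wt)
  v <- apply(as.matrix(wt), 1, var)
  keep <- mu >= 5
  expect_gt(sum(keep), 5)
  expected <- mu[keep] + mu[keep]^2 / cfg$dispersion
  expect_true(all(abs(v[keep] / expected - 1) < 0.2))
})

test_that("an effect gene's estimated logfc converges to log2(f)", {
  est <- numeric(20)
  for (r in seq_len(20)) {
    cfg <- sim_config(seed = 100 + r, n_chroms = 1, genes_per_chrom = 40,
                      n_loops = 2, genes_per_loop = 3, n_effect_loops = 1,
                      fold_change = 2, n_cells_per_condition = 200,
                      mean_depth = 400)
    s <- simulate_genome_and_loops(cfg)
    m <- simulate_counts(cfg, s$genes, s$truth)
    lfc <- cell_averaged_logfc(m, "KO", "WT", "neoplastic")
    eff_genes <- names(s$truth$gene_fold_change)[
      s$truth$gene_fold_change > 1]
    est[r] <- mean(lfc$logfc[lfc$gene_id %in% eff_genes])
  }
  expect_lt(abs(mean(est) - 1), 0.3)
})

test_that("peak simulation encodes anchor loss and classifies effect loops
          direct", {
  cfg <- small_cfg()
  s <- simulate_genome_and_loops(cfg)
  pk <- simulate_peak_sets(cfg, s$loops, s$truth)
  dpk <- differential_peaks(pk$wt, pk$ko)
  # every effect-loop anchor peak is WT-specific
  eff_anchors <- c(paste0(s$truth$effect_loops, "_A"),
                   paste0(s$truth$effect_loops, "_B"))
  expect_true(all(eff_anchors %in% dpk$name))
  expect_true(all(!pk$retention[eff_anchors]))
  cls <- classify_loops(s$loops, dpk)
  lab <- setNames(cls$labels$label, cls$labels$loop_id)
  expect_true(all(lab[s$truth$effect_loops] == "direct"))

  # no loss, no effect loops -> no differential peaks at all
  cfg0 <- sim_config(seed = 2, n_chroms = 1, genes_per_chrom = 40,
                     n_loops = 4, genes_per_loop = 3, n_effect_loops = 0,
                     anchor_peak_loss_frac = 0,
                     n_cells_per_condition = 5, mean_depth = 100)
  s0 <- simulate_genome_and_loops(cfg0)
  pk0 <- simulate_peak_sets(cfg0, s0$loops, s0$truth)
  expect_identical(nrow(differential_peaks(pk0$wt, pk0$ko)), 0L)

  # total loss -> every anchor peak WT-specific
  cfg1 <- sim_config(seed = 2, n_chroms = 1, genes_per_chrom = 40,
                     n_loops = 4, genes_per_loop = 3, n_effect_loops = 0,
                     anchor_peak_loss_frac = 1,
                     n_cells_per_condition = 5, mean_depth = 100)
  s1 <- simulate_genome_and_loops(cfg1)
  pk1 <- simulate_peak_sets(cfg1, s1$loops, s1$truth)
  expect_identical(nrow(differential_peaks(pk1$wt, pk1$ko)), 8L)
})

test_that("fragment enrichment raises the center of the meta-profile", {
  cfg_flat <- small_cfg(fragment_enrichment = 1)
  cfg_enr <- small_cfg(fragment_enrichment = 10)
  s <- simulate_genome_and_loops(cfg_flat)
  pk <- simulate_peak_sets(cfg_flat, s$loops, s$truth)
  anchors <- peak_set(as.data.frame(
    pk$wt[grepl("^loop_", pk$wt$name), ]), "sites")
  prof_of <- function(cfg) {
    profile_means(profile_matrix(simulate_fragments(cfg, anchors), anchors))
  }
  p_enr <- prof_of(cfg_enr)
  n <- length(p_enr)
  center <- mean(p_enr[(n / 2 - 5):(n / 2 + 5)])
  edge <- mean(c(p_enr[1:10], p_enr[(n - 9):n]))
  expect_gt(center, 2 * edge)
  p_flat <- prof_of(cfg_flat)
  center_f <- mean(p_flat[(n / 2 - 5):(n / 2 + 5)])
  edge_f <- mean(c(p_flat[1:10], p_flat[(n - 9):n]))
  expect_lt(abs(center_f - edge_f),
            5 * stats::sd(p_flat) / sqrt(10) + 0.05)
})

test_that("written files round-trip through the module readers", {
  cfg <- small_cfg()
  dir <- withr::local_tempdir()
  s <- write_simulation(cfg, dir)
  expect_identical(read_gene_table(file.path(dir, "genes.tsv")), s$genes)
  expect_identical(read_loops_bedpe(file.path(dir, "loops.bedpe")),
                   s$loops)
  wt <- read_peaks_bed(file.path(dir, "peaks_WT.bed"), "WT")
  cols <- c("chrom", "start", "end", "name")
  expect_identical(as.data.frame(wt)[, cols],
                   as.data.frame(s$peaks$wt)[, cols])
  m <- read_cell_matrix(file.path(dir, "counts"))
  expect_identical(as.matrix(m$counts), as.matrix(s$counts$counts))
  expect_identical(m$cell_meta, s$counts$cell_meta)
  expect_identical(read_fragments(file.path(dir, "fragments.tsv")),
                   s$fragments)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_identical(unlist(gt$effect_loops), s$truth$effect_loops)
})
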