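#' Configuration for the synthetic-study generator
#'
#' Collects every knob of the generator in one validated object. The defaults
#' describe a small two-condition study: four chromosomes of evenly spaced
#' genes, non-overlapping 5-gene loops with CTCF-bearing anchors, log-normal
#' gene abundances with negative-binomial cell counts (variance
#' \code{mu + mu^2/dispersion}), a coordinated multiplicative fold-change on
#' the member genes of designated effect loops in the second condition, loss
#' of anchor peaks in that condition, and fragment pile-ups around sites.
#'
#' @param seed integer seed; every generator is a pure function of the
#'   config, so equal configs give byte-identical outputs.
#' @param n_chroms number of chromosomes.
#' @param genes_per_chrom genes per chromosome.
#' @param gene_spacing distance between consecutive gene starts (bp).
#' @param gene_length gene-body length (bp).
#' @param n_loops total loops; placed on a grid of non-overlapping blocks of
#'   \code{genes_per_loop} consecutive genes with one spacer gene between
#'   blocks.
#' @param genes_per_loop member genes per loop.
#' @param n_effect_loops loops whose member genes carry \code{fold_change}.
#' @param fold_change multiplicative effect (>= 0) applied in the second
#'   condition to member genes of effect loops.
#' @param n_cells_per_condition cells simulated per condition.
#' @param mean_depth expected total counts per cell before per-cell depth
#'   variation.
#' @param dispersion negative-binomial size parameter theta.
#' @param mean_sdlog sdlog of the log-normal per-gene abundance weights.
#' @param cell_depth_sdlog sdlog of per-cell depth factors.
#' @param anchor_width width of each boundary anchor (bp).
#' @param anchor_peak_loss_frac probability a non-effect anchor peak is lost
#'   in the second condition (effect-loop anchors are always lost).
#' @param background_peaks_per_chrom shared (non-differential) peaks.
#' @param fragment_enrichment site enrichment e >= 1; fragments are a mixture
#'   of uniform background and Gaussian (sd 50 bp) pile-ups at sites with
#'   site-component weight \code{(e - 1)/e}, so e = 1 is flat.
#' @param n_fragments fragments to simulate.
#' @param fragment_length fragment length (bp, default 100).
#' @param conditions two condition labels, denominator first (default
#'   \code{c("WT", "KO")}).
#' @param cell_type cell-type label given to all simulated cells.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L, n_chroms = 4L, genes_per_chrom = 300L,
                       gene_spacing = 30000L, gene_length = 2000L,
                       n_loops = 60L, genes_per_loop = 5L,
                       n_effect_loops = 10L, fold_change = 2,
                       n_cells_per_condition = 200L, mean_depth = 7200,
                       dispersion = 0.5, mean_sdlog = 0.5,
                       cell_depth_sdlog = 0.2, anchor_width = 2000L,
                       anchor_peak_loss_frac = 0.1,
                       background_peaks_per_chrom = 40L,
                       fragment_enrichment = 8, n_fragments = 20000L,
                       fragment_length = 100L,
                       conditions = c("WT", "KO"),
                       cell_type = "neoplastic") {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              genes_per_chrom = as.integer(genes_per_chrom),
              gene_spacing = as.integer(gene_spacing),
              gene_length = as.integer(gene_length),
              n_loops = as.integer(n_loops),
              genes_per_loop = as.integer(genes_per_loop),
              n_effect_loops = as.integer(n_effect_loops),
              fold_change = fold_change,
              n_cells_per_condition = as.integer(n_cells_per_condition),
              mean_depth = mean_depth, dispersion = dispersion,
              mean_sdlog = mean_sdlog, cell_depth_sdlog = cell_depth_sdlog,
              anchor_width = as.integer(anchor_width),
              anchor_peak_loss_frac = anchor_peak_loss_frac,
              background_peaks_per_chrom =
                as.integer(background_peaks_per_chrom),
              fragment_enrichment = fragment_enrichment,
              n_fragments = as.integer(n_fragments),
              fragment_length = as.integer(fragment_length),
              conditions = as.character(conditions),
              cell_type = cell_type)
  with(cfg, {
    stopifnot(n_chroms >= 1, genes_per_chrom >= 1, gene_spacing > gene_length,
              gene_length >= 1, n_loops >= 0, genes_per_loop >= 1,
              n_cells_per_condition >= 1, mean_depth > 0,
              fold_change >= 0, mean_sdlog >= 0, cell_depth_sdlog >= 0,
              anchor_width >= 1, background_peaks_per_chrom >= 0,
              fragment_enrichment >= 1, n_fragments >= 0,
              fragment_length >= 2, length(conditions) == 2)
    if (dispersion <= 0) stop("dispersion (NB size theta) must be positive")
    if (anchor_peak_loss_frac < 0 || anchor_peak_loss_frac > 1) {
      stop("anchor_peak_loss_frac must lie in [0, 1]")
    }
    if (n_effect_loops > n_loops) stop("n_effect_loops must be <= n_loops")
  })
  structure(cfg, class = c("sim_config", "list"))
}

.chrom_length <- function(cfg) {
  10000L + cfg$genes_per_chrom * cfg$gene_spacing
}

#' Simulate the gene annotation and loop calls
#'
#' Genes are evenly spaced along each chromosome with random strands; loops
#' occupy non-overlapping blocks of \code{genes_per_loop} consecutive genes
#' (at least one spacer gene between blocks), with anchors of
#' \code{anchor_width} bp flanking the first and last member gene. Effect
#' loops are sampled uniformly.
#'
#' @param cfg a [sim_config()].
#' @return list with \code{genes} ([gene_table()]), \code{loops}
#'   ([loop_set()]), and \code{truth} (effect loop ids, per-gene true fold
#'   change, loop membership).
#' @export
simulate_genome_and_loops <- function(cfg) {
  set.seed(cfg$seed)
  offset <- 10000L
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  genes <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    j <- seq_len(cfg$genes_per_chrom)
    start <- offset + (j - 1L) * cfg$gene_spacing
    data.frame(chrom = chroms[ci], start = start,
               end = start + cfg$gene_length,
               strand = sample(c("+", "-"), cfg$genes_per_chrom,
                               replace = TRUE),
               id = sprintf("gene_%02d_%04d", ci, j),
               symbol = sprintf("Sym%02d%04d", ci, j),
               stringsAsFactors = FALSE)
  }))
  genes <- gene_table(genes)

  block <- cfg$genes_per_loop + 1L
  per_chrom_cap <- cfg$genes_per_chrom %/% block
  if (cfg$n_loops > per_chrom_cap * cfg$n_chroms) {
    stop("cannot place ", cfg$n_loops, " non-overlapping loops of ",
         cfg$genes_per_loop, " genes: capacity is ",
         per_chrom_cap * cfg$n_chroms)
  }
  base <- cfg$n_loops %/% cfg$n_chroms
  alloc <- rep(base, cfg$n_chroms)
  extra <- cfg$n_loops - base * cfg$n_chroms
  if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L
  loops <- list()
  members <- list()
  k <- 0L
  for (ci in seq_along(chroms)) {
    if (alloc[ci] == 0) next
    blocks <- sort(sample.int(per_chrom_cap, alloc[ci]))
    for (b in blocks) {
      k <- k + 1L
      first <- (b - 1L) * block + 1L
      idx <- first:(first + cfg$genes_per_loop - 1L)
      gsub <- genes[genes$chrom == chroms[ci], , drop = FALSE]
      gsub <- gsub[order(gsub$start), , drop = FALSE]
      g1 <- gsub[idx[1], ]
      gn <- gsub[idx[length(idx)], ]
      id <- sprintf("loop_%04d", k)
      loops[[k]] <- data.frame(
        id = id, chrom = chroms[ci],
        a_start = g1$start - cfg$anchor_width, a_end = g1$start,
        b_start = gn$end, b_end = gn$end + cfg$anchor_width,
        stringsAsFactors = FALSE)
      members[[id]] <- gsub$id[idx]
    }
  }
  loops <- loop_set(do.call(rbind, loops))
  effect <- if (cfg$n_effect_loops > 0) {
    sort(sample(loops$id, cfg$n_effect_loops))
  } else character(0)
  fc <- setNames(rep(1, nrow(genes)), genes$id)
  for (id in effect) fc[members[[id]]] <- cfg$fold_change
  truth <- list(effect_loops = effect, gene_fold_change = fc,
                loop_members = members)
  list(genes = genes, loops = loops, truth = truth)
}

#' Simulate the two-condition cell-by-gene count matrix
#'
#' Per-gene base means are log-normal weights scaled so a cell's expected
#' total is \code{mean_depth}; the second condition multiplies effect-loop
#' member genes by \code{fold_change}; per-cell depth factors are log-normal;
#' counts are negative binomial with size \code{dispersion}.
#'
#' @param cfg a [sim_config()].
#' @param genes the [gene_table()] from [simulate_genome_and_loops()].
#' @param truth the matching ground truth.
#' @return A [cell_gene_matrix()].
#' @export
simulate_counts <- function(cfg, genes, truth) {
  set.seed(cfg$seed + 1L)
  n_genes <- nrow(genes)
  w <- rlnorm(n_genes, meanlog = 0, sdlog = cfg$mean_sdlog)
  base <- w / sum(w) * cfg$mean_depth
  fc <- truth$gene_fold_change[genes$id]
  n <- cfg$n_cells_per_condition
  sim_cond <- function(mu_gene, cond) {
    d <- rlnorm(n, meanlog = 0, sdlog = cfg$cell_depth_sdlog)
    counts <- vapply(seq_len(n), function(j) {
      rnbinom(n_genes, size = cfg$dispersion, mu = mu_gene * d[j])
    }, numeric(n_genes))
    colnames(counts) <- sprintf("cell_%s_%04d", cond, seq_len(n))
    counts
  }
  c1 <- sim_cond(base, cfg$conditions[1])
  c2 <- sim_cond(base * fc, cfg$conditions[2])
  counts <- cbind(c1, c2)
  rownames(counts) <- genes$id
  meta <- data.frame(
    barcode = colnames(counts),
    condition = rep(cfg$conditions, each = n),
    cell_type = cfg$cell_type, stringsAsFactors = FALSE)
  cell_gene_matrix(Matrix::Matrix(counts, sparse = TRUE), meta)
}

#' Simulate the per-condition peak sets
#'
#' The first condition carries a peak in every loop anchor plus shared
#' background peaks; the second retains each anchor peak with probability
#' \code{1 - anchor_peak_loss_frac}, and effect loops' anchor peaks are
#' always lost (so differential peaks land exactly where the expression
#' effect is). Background peaks are identical in both conditions.
#'
#' @param cfg a [sim_config()].
#' @param loops the [loop_set()] from [simulate_genome_and_loops()].
#' @param truth the matching ground truth.
#' @return list with [peak_set()]s \code{wt} and \code{ko} (labeled with the
#'   two condition names) and named logical \code{retention} per anchor peak.
#' @export
simulate_peak_sets <- function(cfg, loops, truth) {
  set.seed(cfg$seed + 2L)
  anchors <- data.frame(
    chrom = rep(loops$chrom, 2L),
    start = c(loops$a_start, loops$b_start),
    end = c(loops$a_end, loops$b_end),
    name = c(paste0(loops$id, "_A"), paste0(loops$id, "_B")),
    stringsAsFactors = FALSE)
  retained <- runif(nrow(anchors)) >= cfg$anchor_peak_loss_frac
  effect_anchor <- rep(loops$id, 2L) %in% truth$effect_loops
  retained[effect_anchor] <- FALSE
  retention <- setNames(retained, anchors$name)

  width <- 200L
  clen <- .chrom_length(cfg)
  agr <- .as_granges(anchors)
  bg <- list()
  for (chrom in sprintf("chr%d", seq_len(cfg$n_chroms))) {
    need <- cfg$background_peaks_per_chrom
    got <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    tries <- 0L
    while (nrow(got) < need && tries < 50L) {
      tries <- tries + 1L
      start <- sort(sample.int(clen - width, need))
      cand <- data.frame(chrom = chrom, start = start, end = start + width,
                         stringsAsFactors = FALSE)
      hit <- .find_overlaps(.as_granges(cand), agr)
      cand <- cand[setdiff(seq_len(nrow(cand)),
                           unique(S4Vectors::queryHits(hit))), , drop = FALSE]
      got <- unique(rbind(got, cand))
      got <- utils::head(got, need)
    }
    got$name <- sprintf("bg_%s_%03d", chrom, seq_len(nrow(got)))
    bg[[chrom]] <- got
  }
  bg <- do.call(rbind, bg)
  wt <- peak_set(rbind(anchors, bg[, names(anchors)]), cfg$conditions[1])
  ko <- peak_set(rbind(anchors[retained, , drop = FALSE],
                       bg[, names(anchors)]), cfg$conditions[2])
  list(wt = wt, ko = ko, retention = retention)
}

#' Simulate a fragment table with site-centered pile-ups
#'
#' Fragment midpoints come from a mixture of a uniform background over each
#' chromosome and Gaussian pile-ups (sd 50 bp) centered on the given sites;
#' the site component has mixture weight \code{(e - 1)/e} for enrichment
#' \code{e}, so enrichment 1 gives a flat profile.
#'
#' @param cfg a [sim_config()].
#' @param sites a [peak_set()] of reference sites (e.g. the first-condition
#'   anchor peaks).
#' @return A [fragment_table()].
#' @export
simulate_fragments <- function(cfg, sites) {
  set.seed(cfg$seed + 3L)
  n <- cfg$n_fragments
  flen <- cfg$fragment_length
  clen <- .chrom_length(cfg)
  chroms <- unique(sites$chrom)
  if (length(chroms) == 0) chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  centers <- (sites$start + sites$end) %/% 2L
  q <- (cfg$fragment_enrichment - 1) / cfg$fragment_enrichment
  enriched <- nrow(sites) > 0 & runif(n) < q
  mid <- integer(n)
  chrom <- character(n)
  ne <- sum(enriched)
  if (ne > 0) {
    si <- sample.int(nrow(sites), ne, replace = TRUE)
    mid[enriched] <- as.integer(round(rnorm(ne, mean = centers[si], sd = 50)))
    chrom[enriched] <- sites$chrom[si]
  }
  nb <- n - ne
  if (nb > 0) {
    chrom[!enriched] <- sample(chroms, nb, replace = TRUE)
    mid[!enriched] <- as.integer(floor(runif(nb, flen / 2, clen - flen / 2)))
  }
  start <- pmax(0L, mid - flen %/% 2L)
  fragment_table(data.frame(
    chrom = chrom, start = start, end = start + flen,
    barcode = sprintf("bc%04d", sample.int(96L, n, replace = TRUE)),
    stringsAsFactors = FALSE))
}

#' Simulate a cell QC table
#'
#' Per-barcode fragment counts (negative binomial around 2500) and promoter
#' ratios (Beta(2.5, 6)), producing a realistic mix of passing and failing
#' cells for the QC stage.
#'
#' @param cfg a [sim_config()].
#' @param n number of barcodes (default twice the cells per condition).
#' @return data frame with \code{barcode}, \code{n_fragments},
#'   \code{promoter_ratio}.
#' @export
simulate_qc_table <- function(cfg, n = 2L * cfg$n_cells_per_condition) {
  set.seed(cfg$seed + 4L)
  data.frame(
    barcode = sprintf("qc_cell_%04d", seq_len(n)),
    n_fragments = rnbinom(n, size = 1.2, mu = 2500),
    promoter_ratio = round(rbeta(n, 2.5, 6), 6),
    stringsAsFactors = FALSE)
}

#' Simulate a ligand-receptor pair table over simulated genes
#'
#' @param cfg a [sim_config()].
#' @param genes the simulated [gene_table()].
#' @param n_pairs number of pairs (default 20).
#' @return data frame with \code{ligand}, \code{receptor}.
#' @export
simulate_pair_table <- function(cfg, genes, n_pairs = 20L) {
  set.seed(cfg$seed + 5L)
  picked <- sample(genes$id, 2L * n_pairs)
  data.frame(ligand = picked[seq_len(n_pairs)],
             receptor = picked[n_pairs + seq_len(n_pairs)],
             stringsAsFactors = FALSE)
}

#' Run every generator for one config
#'
#' @param cfg a [sim_config()].
#' @return list with \code{genes}, \code{loops}, \code{truth} (including
#'   anchor-peak retention), \code{counts}, \code{peaks} (list wt/ko),
#'   \code{fragments}, \code{qc}, \code{pairs}.
#' @export
simulate_study <- function(cfg) {
  gl <- simulate_genome_and_loops(cfg)
  counts <- simulate_counts(cfg, gl$genes, gl$truth)
  pk <- simulate_peak_sets(cfg, gl$loops, gl$truth)
  gl$truth$peak_retention <- pk$retention
  anchor_sites <- pk$wt[grepl("^loop_", pk$wt$name %||% ""), , drop = FALSE]
  frags <- simulate_fragments(cfg, peak_set(as.data.frame(anchor_sites),
                                            "sites"))
  list(genes = gl$genes, loops = gl$loops, truth = gl$truth,
       counts = counts, peaks = list(wt = pk$wt, ko = pk$ko),
       fragments = frags, qc = simulate_qc_table(cfg),
       pairs = simulate_pair_table(cfg, gl$genes))
}

#' Write a complete simulated study to disk
#'
#' Emits exactly the formats the pipeline reads: \code{genes.tsv},
#' \code{loops.bedpe}, \code{peaks_<cond>.bed} for both conditions,
#' \code{counts/} (MTX + sidecars + cell metadata), \code{fragments.tsv},
#' \code{sites.bed} (the first-condition anchor peaks, the fragment pile-up
#' centers), \code{qc.tsv}, \code{pairs.tsv}, and \code{ground_truth.json}.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created).
#' @return invisibly, the in-memory [simulate_study()] result.
#' @export
write_simulation <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- simulate_study(cfg)
  write_gene_table(s$genes, file.path(dir, "genes.tsv"))
  write_loops_bedpe(s$loops, file.path(dir, "loops.bedpe"))
  write_peaks_bed(s$peaks$wt,
                  file.path(dir, sprintf("peaks_%s.bed", cfg$conditions[1])))
  write_peaks_bed(s$peaks$ko,
                  file.path(dir, sprintf("peaks_%s.bed", cfg$conditions[2])))
  write_cell_matrix(s$counts, file.path(dir, "counts"))
  write_fragments(s$fragments, file.path(dir, "fragments.tsv"))
  sites <- s$peaks$wt[grepl("^loop_", s$peaks$wt$name), , drop = FALSE]
  write_peaks_bed(peak_set(as.data.frame(sites), "sites"),
                  file.path(dir, "sites.bed"))
  .write_tsv(s$qc, file.path(dir, "qc.tsv"))
  .write_tsv(s$pairs, file.path(dir, "pairs.tsv"))
  jsonlite::write_json(
    list(effect_loops = s$truth$effect_loops,
         gene_fold_change = as.list(s$truth$gene_fold_change),
         peak_retention = as.list(s$truth$peak_retention),
         config = unclass(cfg)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(s)
}
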