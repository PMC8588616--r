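#' Default pipeline configuration
#'
#' Every stage parameter in one declarative list; unknown names in
#' \code{...} are rejected. Input paths default to the layout written by
#' [write_simulation()] under \code{input_dir}.
#'
#' @param input_dir directory holding the stage inputs.
#' @param outdir run directory for stage outputs (created).
#' @param ... overrides for any default listed below.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(input_dir, outdir, ...) {
  cfg <- list(
    input_dir = input_dir, outdir = outdir,
    stages = c("qc", "logfc", "diffpeaks", "classify", "score", "qq",
               "pairs", "profile"),
    cond_num = "KO", cond_den = "WT", population = "neoplastic",
    pseudocount = 1, target_sum = 1e4,
    min_fragments = 1000, min_promoter_ratio = 0.2,
    min_overlap = 1L, boundary_flank = 0L,
    min_genes = 2L, include_own_window = TRUE, compute_p = FALSE,
    min_frac = 0.10, window = 1000L, bin_width = 10L,
    profile_mode = "cutsite",
    genes_path = NULL, loops_path = NULL, peaks_num_path = NULL,
    peaks_den_path = NULL, counts_dir = NULL, qc_path = NULL,
    fragments_path = NULL, sites_path = NULL, pairs_path = NULL
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown pipeline parameter(s): ",
                        paste(bad, collapse = ", "))
  cfg <- utils::modifyList(cfg, dots)
  d <- cfg$input_dir
  cfg$genes_path <- cfg$genes_path %||% file.path(d, "genes.tsv")
  cfg$loops_path <- cfg$loops_path %||% file.path(d, "loops.bedpe")
  cfg$peaks_den_path <- cfg$peaks_den_path %||%
    file.path(d, sprintf("peaks_%s.bed", cfg$cond_den))
  cfg$peaks_num_path <- cfg$peaks_num_path %||%
    file.path(d, sprintf("peaks_%s.bed", cfg$cond_num))
  cfg$counts_dir <- cfg$counts_dir %||% file.path(d, "counts")
  cfg$qc_path <- cfg$qc_path %||% file.path(d, "qc.tsv")
  cfg$fragments_path <- cfg$fragments_path %||% file.path(d, "fragments.tsv")
  cfg$sites_path <- cfg$sites_path %||% file.path(d, "sites.bed")
  cfg$pairs_path <- cfg$pairs_path %||% file.path(d, "pairs.tsv")
  structure(cfg, class = c("pipeline_config", "list"))
}

# config hash for provenance: md5 of the canonical JSON serialization
.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.log_lines <- function(log, lines) {
  message(paste(format(Sys.time(), "%H:%M:%S"), lines, collapse = "\n"))
  cat(lines, file = log, sep = "\n", append = TRUE)
}

#' Run the loop-dysregulation pipeline end to end
#'
#' Stage order: cell QC, per-gene fold-change, differential peaks, loop
#' classification, loop scoring against the sliding-window null, Beta/Q-Q
#' diagnostics, ligand-receptor pairing, and cut-site profiles. Each stage
#' writes its table into the run directory; a \code{summary.json} records
#' per-stage counts, the Beta parameters, the echoed config, its md5 hash and
#' the package version. Rerunning an identical config reproduces identical
#' files (the run log carries no timestamps; timestamped progress goes to
#' stderr only).
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(cfg$outdir, "run.log")
  cat("", file = log)
  summary <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .log_lines(log, sprintf("stage %s FAILED: %s", name,
                              conditionMessage(e)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  run <- function(name) name %in% cfg$stages

  if (run("qc") && file.exists(cfg$qc_path)) {
    stage("qc", {
      qc <- atac_cell_qc(read_qc_table(cfg$qc_path),
                         cfg$min_fragments, cfg$min_promoter_ratio)
      .write_tsv(qc, file.path(cfg$outdir, "qc_pass.tsv"))
      summary$qc <- list(n_cells = nrow(qc), n_pass = sum(qc$pass))
      .log_lines(log, sprintf("stage qc: %d/%d barcodes pass",
                              sum(qc$pass), nrow(qc)))
    })
  }

  genes <- stage("inputs", {
    if (!file.exists(cfg$genes_path)) {
      stop("gene table not found: ", cfg$genes_path)
    }
    read_gene_table(cfg$genes_path)
  })
  loops <- stage("inputs", {
    if (!file.exists(cfg$loops_path)) {
      stop("loop BEDPE not found: ", cfg$loops_path)
    }
    read_loops_bedpe(cfg$loops_path)
  })

  lfc <- NULL
  if (run("logfc") || run("score") || run("qq")) {
    stage("logfc", {
      m <- read_cell_matrix(cfg$counts_dir)
      lfc <- cell_averaged_logfc(m, cfg$cond_num, cfg$cond_den,
                                  cfg$population, cfg$pseudocount,
                                  cfg$target_sum)
      write_gene_logfc(lfc, file.path(cfg$outdir, "gene_logfc.tsv"))
      summary$logfc <- list(n_genes = nrow(lfc),
                             numerator = cfg$cond_num,
                             denominator = cfg$cond_den)
      .log_lines(log, sprintf("stage logfc: %d genes (%s vs %s)",
                              nrow(lfc), cfg$cond_num, cfg$cond_den))
    })
  }

  dpk <- NULL
  labels <- NULL
  if (run("diffpeaks") || run("classify") || run("score")) {
    stage("diffpeaks", {
      den <- read_peaks_bed(cfg$peaks_den_path, cfg$cond_den)
      num <- read_peaks_bed(cfg$peaks_num_path, cfg$cond_num)
      dpk <- differential_peaks(den, num, cfg$min_overlap)
      write_peaks_bed(dpk, file.path(cfg$outdir, "differential_peaks.bed"))
      summary$diffpeaks <- list(
        n_den = nrow(den), n_num = nrow(num), n_differential = nrow(dpk))
      .log_lines(log, sprintf("stage diffpeaks: %d %s-specific peaks",
                              nrow(dpk), cfg$cond_den))
    })
    stage("classify", {
      cls <- classify_loops(loops, dpk, cfg$boundary_flank)
      labels <- cls$labels
      .write_tsv(labels, file.path(cfg$outdir, "loop_classes.tsv"))
      jsonlite::write_json(cls$summary,
                           file.path(cfg$outdir, "class_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      summary$classify <- cls$summary
      .log_lines(log, sprintf(
        "stage classify: %d direct / %d indirect / %d unaffected",
        cls$summary$counts$direct, cls$summary$counts$indirect,
        cls$summary$counts$unaffected))
    })
  }

  scores <- NULL
  if (run("score")) {
    stage("score", {
      scores <- withCallingHandlers(
        score_all_loops(loops, genes, lfc, labels = labels,
                        min_genes = cfg$min_genes,
                        include_own_window = cfg$include_own_window,
                        compute_p = cfg$compute_p),
        warning = function(w) {
          .log_lines(log, paste("stage score:", conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      write_loop_scores(scores, file.path(cfg$outdir, "loop_scores.tsv"))
      sk <- attr(scores, "skipped")
      summary$score <- list(
        n_scored = nrow(scores), n_skipped = nrow(sk),
        mean_percentile = if (nrow(scores)) mean(scores$percentile) else
          NA_real_,
        frac_percentile_ge_95 = if (nrow(scores))
          mean(scores$percentile >= 95) else NA_real_,
        include_own_window = cfg$include_own_window)
      .log_lines(log, sprintf("stage score: %d loops scored, %d skipped",
                              nrow(scores), nrow(sk)))
    })
  }

  if (run("qq") && !is.null(scores)) {
    stage("qq", {
      if (nrow(scores) > 0 && length(unique(scores$percentile)) >= 8) {
        bq <- fit_beta_iqr(scores$percentile)
        .write_tsv(bq$qq_points, file.path(cfg$outdir, "beta_qq.tsv"))
        summary$qq <- list(alpha = bq$alpha, beta = bq$beta)
        .log_lines(log, sprintf("stage qq: Beta(%.4f, %.4f)",
                                bq$alpha, bq$beta))
      } else {
        .log_lines(log, "stage qq: skipped (fewer than 8 distinct percentiles)")
        summary$qq <- list(skipped = TRUE)
      }
    })
  }

  if (run("pairs") && file.exists(cfg$pairs_path)) {
    stage("pairs", {
      m <- read_cell_matrix(cfg$counts_dir)
      pr <- detect_pairs(m, cfg$population, cfg$population,
                         read_pair_table(cfg$pairs_path),
                         cfg$min_frac, cfg$target_sum)
      .write_tsv(pr, file.path(cfg$outdir, "pair_results.tsv"))
      summary$pairs <- list(n_pairs = nrow(pr),
                             n_expressed_in_both = sum(pr$expressed_in_both),
                             n_skipped = nrow(attr(pr, "skipped")))
      .log_lines(log, sprintf("stage pairs: %d/%d pairs expressed in both",
                              sum(pr$expressed_in_both), nrow(pr)))
    })
  }

  if (run("profile") && file.exists(cfg$fragments_path) &&
      file.exists(cfg$sites_path)) {
    stage("profile", {
      frags <- read_fragments(cfg$fragments_path)
      sites <- read_peaks_bed(cfg$sites_path, "sites")
      mat <- profile_matrix(frags, sites, cfg$window, cfg$bin_width,
                            mode = cfg$profile_mode)
      write_profile_matrix(mat, file.path(cfg$outdir, "profile_matrix.tsv"))
      mm <- profile_means(mat)
      .write_tsv(data.frame(bin = seq_along(mm) - 1L,
                            mean = mm, smoothed = moving_average(mm, 5L)),
                 file.path(cfg$outdir, "profile_means.tsv"))
      summary$profile <- list(n_sites = nrow(mat), n_bins = ncol(mat),
                               total_cuts = sum(mat))
      .log_lines(log, sprintf("stage profile: %d sites x %d bins",
                              nrow(mat), ncol(mat)))
    })
  }

  summary$config <- unclass(cfg)
  summary$config_hash <- .config_hash(cfg)
  summary$package_version <- as.character(utils::packageVersion("loopwise"))
  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_lines(log, "pipeline complete")
  invisible(summary)
}
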