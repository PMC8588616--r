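#' Population mean of depth-normalized expression
#'
#' Each selected cell is scaled to a fixed library size (default 10,000
#' counts), then gene means are taken over cells. This is the population-level
#' summary feeding both the fold-change estimator and ligand-receptor pairing.
#'
#' @param m a [cell_gene_matrix()].
#' @param population cell-type label selecting cells.
#' @param condition condition label selecting cells.
#' @param target_sum library size each cell is scaled to (default 1e4).
#' @return named numeric vector, one mean per gene.
#' @export
population_mean_expression <- function(m, population, condition,
                                       target_sum = 1e4) {
  idx <- .select_cells(m, population, condition)
  if (length(idx) == 0) {
    stop("no cells with cell_type '", population,
         "' and condition '", condition, "'")
  }
  norm <- .normalize_depth(m$counts[, idx, drop = FALSE], target_sum)
  setNames(Matrix::rowMeans(norm), rownames(m$counts))
}

#' Cell-averaged log2 fold-change between two conditions
#'
#' For every gene, \code{log2((mean_num + pseudocount) / (mean_den +
#' pseudocount))} where the means are depth-normalized population means from
#' [population_mean_expression()]. The pseudocount (on the normalized scale)
#' keeps the statistic finite for dropout genes; the result is exactly
#' antisymmetric under swapping the condition pair.
#'
#' @param m a [cell_gene_matrix()].
#' @param cond_num numerator condition label (e.g. \code{"KO"}).
#' @param cond_den denominator condition label (e.g. \code{"WT"}).
#' @param population cell-type label both condition means are computed in.
#' @param pseudocount positive stabilizer on the normalized scale (default 1).
#' @param target_sum library size for depth normalization (default 1e4).
#' @return A \code{gene_logfc} data frame (\code{gene_id}, \code{logfc}) with
#'   the condition pair, pseudocount and normalization target as attributes.
#' @export
cell_averaged_logfc <- function(m, cond_num, cond_den, population,
                                pseudocount = 1, target_sum = 1e4) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  mn <- population_mean_expression(m, population, cond_num, target_sum)
  md <- population_mean_expression(m, population, cond_den, target_sum)
  lfc <- log2(mn + pseudocount) - log2(md + pseudocount)
  structure(
    data.frame(gene_id = rownames(m$counts), logfc = unname(lfc),
               stringsAsFactors = FALSE),
    numerator = cond_num, denominator = cond_den,
    pseudocount = pseudocount, target_sum = target_sum,
    class = c("gene_logfc", "data.frame")
  )
}
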