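#' Ligand-receptor pairing between two cell populations
#'
#' For every (ligand, receptor) pair, computes the ligand's detection
#' fraction (cells with count > 0) and mean depth-normalized expression in
#' the ligand population, the receptor's in the receptor population, and
#' flags the pair as \code{expressed_in_both} when both detection fractions
#' reach \code{min_frac}. Pairs naming genes absent from the matrix are not
#' fatal; they are returned in the \code{"skipped"} attribute.
#'
#' @param m a [cell_gene_matrix()].
#' @param ligand_pop cell-type label of the ligand-expressing population.
#' @param receptor_pop cell-type label of the receptor-expressing population.
#' @param pairs data frame with columns \code{ligand}, \code{receptor}.
#' @param min_frac minimum detection fraction counted as "expressed"
#'   (default 0.10).
#' @param target_sum library size for depth normalization (default 1e4).
#' @return data frame sorted by descending ligand mean: \code{ligand},
#'   \code{receptor}, \code{ligand_mean}, \code{ligand_frac},
#'   \code{receptor_mean}, \code{receptor_frac}, \code{expressed_in_both};
#'   unresolvable pairs as attribute \code{"skipped"}.
#' @export
detect_pairs <- function(m, ligand_pop, receptor_pop, pairs,
                         min_frac = 0.10, target_sum = 1e4) {
  if (min_frac < 0 || min_frac > 1) stop("min_frac must lie in [0, 1]")
  li <- .select_cells(m, population = ligand_pop)
  ri <- .select_cells(m, population = receptor_pop)
  if (length(li) == 0) stop("no cells with cell_type '", ligand_pop, "'")
  if (length(ri) == 0) stop("no cells with cell_type '", receptor_pop, "'")
  gid <- rownames(m$counts)
  known_l <- pairs$ligand %in% gid
  known_r <- pairs$receptor %in% gid
  ok <- known_l & known_r
  skipped <- pairs[!ok, , drop = FALSE]
  if (nrow(skipped) > 0) {
    skipped$reason <- ifelse(!known_l[!ok], "ligand gene absent",
                             "receptor gene absent")
  } else {
    skipped$reason <- character(0)
  }
  pr <- pairs[ok, , drop = FALSE]
  lc <- m$counts[, li, drop = FALSE]
  rc <- m$counts[, ri, drop = FALSE]
  lmean <- Matrix::rowMeans(.normalize_depth(lc, target_sum))
  rmean <- Matrix::rowMeans(.normalize_depth(rc, target_sum))
  lfrac <- Matrix::rowMeans(lc > 0)
  rfrac <- Matrix::rowMeans(rc > 0)
  out <- data.frame(
    ligand = pr$ligand, receptor = pr$receptor,
    ligand_mean = unname(lmean[pr$ligand]),
    ligand_frac = unname(lfrac[pr$ligand]),
    receptor_mean = unname(rmean[pr$receptor]),
    receptor_frac = unname(rfrac[pr$receptor]),
    stringsAsFactors = FALSE
  )
  out$expressed_in_both <- out$ligand_frac >= min_frac &
    out$receptor_frac >= min_frac
  out <- out[order(-out$ligand_mean, out$ligand, out$receptor,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "min_frac") <- min_frac
  out
}
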