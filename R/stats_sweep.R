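#' Summary statistics of a pham partition
#'
#' Computes the standard descriptive numbers of a pham partition: total
#' genes and phams, orpham count and percentage (1 dp), mean pham size
#' (2 dp), median and maximum size, and the percentage of phams with ten
#' or fewer members (1 dp).
#'
#' @param partition either a vector of pham numbers (one entry per
#'   gene) or the result of [assemble_phams()].
#' @return a list of class `pham_stats`.
#' @export
#' @examples
#' compute_stats(c(1, 2, 3, 3, 4, 4, 4, 4))
compute_stats <- function(partition) {
  if (is.list(partition) && !is.null(partition$assignment))
    partition <- partition$assignment$pham_number
  sizes <- as.integer(table(partition))
  pham_size_stats(sizes)
}

#' Summary statistics from a vector of pham sizes
#'
#' @param sizes integer vector, one entry per pham.
#' @return same structure as [compute_stats()].
#' @export
pham_size_stats <- function(sizes) {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0) {
    out <- list(total_genes = 0L, total_phams = 0L, n_orphams = 0L,
                pct_orphams = 0, mean_pham_size = 0,
                median_pham_size = 0, max_pham_size = 0L,
                pct_phams_le_10 = 0)
    class(out) <- "pham_stats"
    return(out)
  }
  n_phams <- length(sizes)
  out <- list(
    total_genes = sum(sizes),
    total_phams = n_phams,
    n_orphams = sum(sizes == 1L),
    pct_orphams = round(100 * sum(sizes == 1L) / n_phams, 1),
    mean_pham_size = round(sum(sizes) / n_phams, 2),
    median_pham_size = median(sizes),
    max_pham_size = max(sizes),
    pct_phams_le_10 = round(100 * sum(sizes <= 10L) / n_phams, 1))
  class(out) <- "pham_stats"
  out
}

#' @export
print.pham_stats <- function(x, ...) {
  cat(sprintf("%d genes in %d phams; %d orphams (%.1f%%)\n",
              x$total_genes, x$total_phams, x$n_orphams, x$pct_orphams))
  cat(sprintf("pham size: mean %.2f, median %g, max %d; %.1f%% of phams have <= 10 members\n",
              x$mean_pham_size, x$median_pham_size, x$max_pham_size,
              x$pct_phams_le_10))
  invisible(x)
}

#' Pham-partition ratios from plain counts
#'
#' The arithmetic identities of a pham summary, computable straight from
#' published counts: mean pham size (2 dp) and orpham percentage (1 dp).
#'
#' @param total_genes,total_phams,n_orphams non-negative counts.
#' @return list with `mean_pham_size` and `pct_orphams`.
#' @export
#' @examples
#' pham_summary_counts(12298, 2757, 1322)
pham_summary_counts <- function(total_genes, total_phams, n_orphams) {
  stopifnot(total_genes >= 0, total_phams >= 0, n_orphams >= 0)
  list(mean_pham_size = if (total_phams > 0)
         round(total_genes / total_phams, 2) else 0,
       pct_orphams = if (total_phams > 0)
         round(100 * n_orphams / total_phams, 1) else 0)
}

#' Threshold sensitivity sweep
#'
#' Re-thresholds the stored raw pairwise scores over a grid of identity
#' and E-value cutoffs, re-runs component assembly at each grid point,
#' and reports the partition statistics per point. No alignment is ever
#' recomputed and the persisted partition is not touched. Within a
#' sweep, stricter thresholds can never produce fewer phams than looser
#' ones, and the largest pham can only grow as thresholds loosen —
#' single-linkage clustering is monotone in its edge set.
#'
#' Either channel can be disabled for a grid point by using `NA` (an
#' `NA` identity threshold passes no pair on the identity channel, and
#' likewise for the E-value channel).
#'
#' @param db a `pham_db` with raw scores present.
#' @param identity_grid percent-identity cutoffs (may contain `NA`).
#' @param evalue_grid E-value cutoffs (may contain `NA`); crossed with
#'   `identity_grid`.
#' @return data.frame with one row per grid combination: the two
#'   thresholds plus total_phams, n_orphams, pct_orphams,
#'   mean_pham_size, max_pham_size.
#' @export
threshold_sweep <- function(db, identity_grid,
                            evalue_grid = db$config$evalue_threshold) {
  stopifnot(inherits(db, "pham_db"))
  if (length(identity_grid) == 0 || length(evalue_grid) == 0)
    return(data.frame(identity_threshold = numeric(0),
                      evalue_threshold = numeric(0),
                      total_phams = integer(0), n_orphams = integer(0),
                      pct_orphams = numeric(0), mean_pham_size = numeric(0),
                      max_pham_size = integer(0)))
  grid <- expand.grid(identity_threshold = identity_grid,
                      evalue_threshold = evalue_grid,
                      KEEP.OUT.ATTRS = FALSE)
  ids <- db$gene$gene_id
  dbres <- database_residues(db)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    e <- derive_edges(db$scores, dbres, db$config,
                      grid$identity_threshold[k], grid$evalue_threshold[k])
    e <- e[e$passes_identity | e$passes_evalue, , drop = FALSE]
    st <- compute_stats(assemble_phams(ids, e))
    data.frame(identity_threshold = grid$identity_threshold[k],
               evalue_threshold = grid$evalue_threshold[k],
               total_phams = st$total_phams, n_orphams = st$n_orphams,
               pct_orphams = st$pct_orphams,
               mean_pham_size = st$mean_pham_size,
               max_pham_size = st$max_pham_size)
  })
  do.call(rbind, rows)
}
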