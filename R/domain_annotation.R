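#' Import conserved-domain search hits from tabular output
#'
#' Reads RPS-BLAST style tabular results (BLAST outfmt 6: query id,
#' domain accession, percent identity, alignment length, mismatches,
#' gap opens, query start, query end, subject start, subject end,
#' E-value, bit score, with an optional 13th description column) and
#' stores rows passing the E-value cutoff. 1-based inclusive query
#' coordinates are converted to 0-based half-open. Hits whose query id
#' matches no gene in the database are skipped with a warning. Import is
#' idempotent: existing hits for the incoming genes are replaced, never
#' duplicated.
#'
#' @param db a `pham_db`.
#' @param tsv_path path to the tabular results.
#' @param evalue_cutoff keep hits with E-value at or below this
#'   (default 1e-3, the usual reporting cutoff for domain searches).
#' @return number of hits imported, invisibly.
#' @export
import_domain_hits <- function(db, tsv_path, evalue_cutoff = 1e-3) {
  stopifnot(inherits(db, "pham_db"))
  lines <- readLines(tsv_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(invisible(0L))
  rows <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12)
      stop("malformed domain hit row at line ", k, ": expected >= 12 ",
           "tab-separated fields, got ", length(f))
    qstart <- suppressWarnings(as.integer(f[7]))
    qend <- suppressWarnings(as.integer(f[8]))
    ev <- suppressWarnings(as.numeric(f[11]))
    if (is.na(qstart) || is.na(qend) || is.na(ev))
      stop("malformed domain hit row at line ", k,
           ": non-numeric coordinates or E-value")
    rows[[k]] <- data.frame(
      gene_id = f[1], domain_accession = f[2],
      description = if (length(f) >= 13) f[13] else "",
      query_start = qstart - 1L, query_end = qend,
      evalue = ev, stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  unknown <- unique(hits$gene_id[!hits$gene_id %in% db$gene$gene_id])
  if (length(unknown) > 0) {
    warning("skipping ", sum(!hits$gene_id %in% db$gene$gene_id),
            " hit(s) for unknown gene id(s): ",
            paste(head(unknown, 5), collapse = ","))
    hits <- hits[hits$gene_id %in% db$gene$gene_id, , drop = FALSE]
  }
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(hits) > 0) {
    tl <- nchar(db$gene$translation)[match(hits$gene_id, db$gene$gene_id)]
    bad <- hits$query_start < 0 | hits$query_start >= hits$query_end |
      hits$query_end > tl
    if (any(bad))
      stop("domain hit coordinates outside translation for gene ",
           hits$gene_id[bad][1])
  }
  db$domain <- rbind(
    db$domain[!db$domain$gene_id %in% hits$gene_id, , drop = FALSE], hits)
  rownames(db$domain) <- NULL
  invisible(nrow(hits))
}

#' Domain hit summary statistics
#'
#' Counts domain matches across the proteome and derives the headline
#' ratios: mean matches per protein (2 dp), percentage of proteins with
#' at least one match (1 dp), and mean matches among proteins that have
#' any (2 dp).
#'
#' @param db a `pham_db`.
#' @return a list: `total_hits`, `total_proteins`,
#'   `mean_hits_per_protein`, `n_with_hit`, `pct_with_hit`,
#'   `mean_hits_among_hit`, `max_hits_gene`.
#' @export
domain_summary <- function(db) {
  stopifnot(inherits(db, "pham_db"))
  total_proteins <- nrow(db$gene)
  total_hits <- nrow(db$domain)
  per_gene <- table(db$domain$gene_id)
  n_with_hit <- length(per_gene)
  base <- domain_summary_counts(total_hits, total_proteins, n_with_hit)
  base$max_hits_gene <- if (n_with_hit > 0)
    names(per_gene)[which.max(per_gene)] else NA_character_
  base
}

#' Domain-distribution ratios from plain counts
#'
#' The pure arithmetic behind [domain_summary()], usable directly on
#' published counts: `mean_hits_per_protein = total_hits /
#' total_proteins` (2 dp), `pct_with_hit = 100 * n_with_hit /
#' total_proteins` (1 dp), `mean_hits_among_hit = total_hits /
#' n_with_hit` (2 dp). Zero denominators give zeros, never errors.
#'
#' @param total_hits,total_proteins,n_with_hit non-negative counts.
#' @return list of the counts plus the three rounded ratios.
#' @export
#' @examples
#' domain_summary_counts(16420, 18901, 2981)
domain_summary_counts <- function(total_hits, total_proteins, n_with_hit) {
  stopifnot(total_hits >= 0, total_proteins >= 0, n_with_hit >= 0)
  list(total_hits = total_hits,
       total_proteins = total_proteins,
       n_with_hit = n_with_hit,
       mean_hits_per_protein = if (total_proteins > 0)
         round(total_hits / total_proteins, 2) else 0,
       pct_with_hit = if (total_proteins > 0)
         round(100 * n_with_hit / total_proteins, 1) else 0,
       mean_hits_among_hit = if (n_with_hit > 0)
         round(total_hits / n_with_hit, 2) else 0)
}

#' Export the domain table as TSV
#'
#' @param db a `pham_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_domains <- function(db, path) {
  write.table(db$domain, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
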