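#' Percent identity of two proteins on a global alignment
#'
#' Aligns the two sequences end to end with the configured substitution
#' matrix and affine gap costs, then returns
#' `100 * identities / min(length_a, length_b)`. Among score-optimal
#' alignments the one with the most identical aligned pairs is used, so
#' the result is a well-defined function of the sequences (no traceback
#' tie dependence) and is symmetric in its arguments. The min-length
#' denominator keeps the value independent of gene length, which is what
#' makes a fixed identity threshold usable across short and long genes.
#'
#' @param seq_a,seq_b non-empty protein strings (20 residues + X).
#' @param config a [comparison_config()].
#' @return percent identity in `[0, 100]`.
#' @export
#' @examples
#' percent_identity("ACDEFGHIK", "ACDEFGHIK")
percent_identity <- function(seq_a, seq_b, config = comparison_config()) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0)
    stop("sequences must be non-empty")
  a <- encode_protein(seq_a)
  b <- encode_protein(seq_b)
  res <- nw_align_c(a, b, protein_submatrix(config),
                    config$gap_open, config$gap_extend)
  100 * res$identities / min(length(a), length(b))
}

#' Local alignment score and E-value of two proteins
#'
#' Computes the Smith-Waterman local alignment score `S` under the
#' configured scoring scheme and converts it to an expectation value
#' with the Karlin-Altschul formula
#' `E = K * m * N * exp(-lambda * S)`, where `m` is the query length
#' (`seq_a`) and `N` the total number of residues in the database being
#' searched. E therefore decreases with score and grows linearly with
#' the database size, which is why pham pass/fail flags must be
#' recomputed when genomes are added or removed.
#'
#' @param seq_a query protein; its length enters the E-value.
#' @param seq_b subject protein.
#' @param config a [comparison_config()].
#' @param database_residues total residue count of the search space;
#'   must be at least `nchar(seq_b)`.
#' @return list with elements `score` and `evalue`.
#' @export
local_alignment_evalue <- function(seq_a, seq_b,
                                   config = comparison_config(),
                                   database_residues = nchar(seq_b)) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0)
    stop("sequences must be non-empty")
  if (database_residues < nchar(seq_b))
    stop("database_residues must be >= length of seq_b")
  a <- encode_protein(seq_a)
  b <- encode_protein(seq_b)
  s <- sw_score_c(a, b, protein_submatrix(config),
                  config$gap_open, config$gap_extend)
  list(score = s,
       evalue = protein_evalue(s, length(a), database_residues, config))
}

protein_evalue <- function(score, query_len, database_residues, config) {
  config$karlin_K * query_len * database_residues *
    exp(-config$karlin_lambda * score)
}

#' Pairwise similarity edge between two genes
#'
#' Computes both comparisons for a gene pair and returns an edge row iff
#' the pair passes the identity threshold OR the E-value threshold (pham
#' membership requires meeting either). The edge is canonicalised so that
#' `gene_a < gene_b` lexicographically; the E-value query is the
#' canonical first gene, making the result independent of argument
#' order.
#'
#' @param gene_a,gene_b lists or one-row data.frames with `gene_id` and
#'   `translation`.
#' @param config a [comparison_config()].
#' @param database_residues search-space size for the E-value.
#' @return a one-row data.frame (gene_a, gene_b, percent_identity,
#'   blast_score, evalue, passes_identity, passes_evalue) or `NULL` when
#'   neither threshold is met.
#' @export
build_edge <- function(gene_a, gene_b, config = comparison_config(),
                       database_residues = NULL) {
  if (gene_b$gene_id < gene_a$gene_id) { tmp <- gene_a; gene_a <- gene_b; gene_b <- tmp }
  if (is.null(database_residues))
    database_residues <- nchar(gene_a$translation) + nchar(gene_b$translation)
  pid <- percent_identity(gene_a$translation, gene_b$translation, config)
  loc <- local_alignment_evalue(gene_a$translation, gene_b$translation,
                                config, database_residues)
  pi_ok <- pid >= config$identity_threshold
  ev_ok <- loc$evalue <= config$evalue_threshold
  if (!pi_ok && !ev_ok) return(NULL)
  data.frame(gene_a = gene_a$gene_id, gene_b = gene_b$gene_id,
             percent_identity = pid, blast_score = loc$score,
             evalue = loc$evalue, passes_identity = pi_ok,
             passes_evalue = ev_ok, stringsAsFactors = FALSE)
}

# Raw scores for a set of unordered gene pairs: identity, local score and
# the canonical query length. E-values and pass flags are derived later
# from the database size of the moment, never re-aligned.
score_gene_pairs <- function(genes_a, genes_b, config) {
  n <- nrow(genes_a)
  out <- vector("list", n)
  mat <- protein_submatrix(config)
  for (k in seq_len(n)) {
    ga <- genes_a[k, ]; gb <- genes_b[k, ]
    if (gb$gene_id < ga$gene_id) { tmp <- ga; ga <- gb; gb <- tmp }
    ea <- encode_protein(ga$translation)
    eb <- encode_protein(gb$translation)
    nw <- nw_align_c(ea, eb, mat, config$gap_open, config$gap_extend)
    sw <- sw_score_c(ea, eb, mat, config$gap_open, config$gap_extend)
    out[[k]] <- data.frame(
      gene_a = ga$gene_id, gene_b = gb$gene_id,
      percent_identity = 100 * nw$identities / min(length(ea), length(eb)),
      blast_score = sw, query_len = length(ea), stringsAsFactors = FALSE)
  }
  if (n == 0) return(empty_scores_table())
  do.call(rbind, out)
}

empty_scores_table <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             percent_identity = numeric(0), blast_score = numeric(0),
             query_len = integer(0), stringsAsFactors = FALSE)
}

#' Whole-genome nucleotide local alignments
#'
#' Seed-and-extend comparison of two genome sequences: exact 11-mer
#' seeds, ungapped X-drop extension with +1/-2 scoring, and ungapped
#' Karlin-Altschul E-values over the m-by-n search space. Matches on the
#' reverse strand are found against the reverse complement and flagged
#' `orientation = "reverse"`. Only matches with
#' `E <= nucleotide_evalue_threshold` (default 1e-4) are returned; these
#' are the spans shaded between adjacent genomes on comparative maps.
#'
#' @param phage_a,phage_b [new_phage()] records with non-empty genomes.
#' @param config a [comparison_config()].
#' @param xdrop terminate extension when the running score falls this
#'   far below its maximum (default 20).
#' @return data.frame with columns phage_a, phage_b, a_start, a_end,
#'   b_start, b_end (0-based half-open), orientation, score, evalue.
#' @export
genome_alignments <- function(phage_a, phage_b,
                              config = comparison_config(), xdrop = 20) {
  stopifnot(inherits(phage_a, "phage"), inherits(phage_b, "phage"))
  sa <- phage_a$genome_sequence
  sb <- phage_b$genome_sequence
  if (nchar(sa) == 0 || nchar(sb) == 0) stop("empty genome sequence")
  fwd <- hsp_search(sa, sb, config, xdrop)
  if (nrow(fwd) > 0) fwd$orientation <- "same"
  rcb <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sb)))
  rev <- hsp_search(sa, rcb, config, xdrop)
  if (nrow(rev) > 0) {
    nb <- nchar(sb)
    b_start <- nb - rev$b_end
    rev$b_end <- nb - rev$b_start
    rev$b_start <- b_start
    rev$orientation <- "reverse"
  }
  out <- rbind(fwd, rev)
  if (nrow(out) == 0) {
    return(data.frame(phage_a = character(0), phage_b = character(0),
                      a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      orientation = character(0), score = numeric(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  }
  out$phage_a <- phage_a$name
  out$phage_b <- phage_b$name
  out <- out[order(out$a_start, out$b_start, out$orientation), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("phage_a", "phage_b", "a_start", "a_end", "b_start", "b_end",
          "orientation", "score", "evalue")]
}

# One strand of the seed-and-extend search. Coordinates 0-based
# half-open on the given sequences.
hsp_search <- function(sa, sb, config, xdrop, word = 11L) {
  na <- nchar(sa); nb <- nchar(sb)
  if (na < word || nb < word) return(empty_hsp_table())
  ka <- substring(sa, 1:(na - word + 1), word:na)
  kb <- substring(sb, 1:(nb - word + 1), word:nb)
  idx_b <- split(seq_along(kb), kb)
  hit_lists <- idx_b[ka]
  n_hits <- lengths(hit_lists)
  keep <- which(n_hits > 0)
  if (length(keep) == 0) return(empty_hsp_table())
  pa <- rep.int(keep, n_hits[keep])
  pb <- unlist(hit_lists[keep], use.names = FALSE)
  # greedy per diagonal: sorted seeds, skip those inside a previous HSP
  dg <- pa - pb
  ord <- order(dg, pa)
  pa <- pa[ord]; pb <- pb[ord]; dg <- dg[ord]
  ra <- charToRaw(sa); rb <- charToRaw(sb)
  lam <- config$nt_lambda; K <- config$nt_K
  thr <- config$nucleotide_evalue_threshold
  res <- list()
  cur_dg <- NA_integer_; covered <- 0L
  for (k in seq_along(pa)) {
    if (is.na(cur_dg) || dg[k] != cur_dg) { cur_dg <- dg[k]; covered <- 0L }
    if (pa[k] + word - 1L <= covered) next
    h <- xdrop_extend(ra, rb, pa[k], pb[k], word, xdrop)
    covered <- h$a_end
    ev <- K * na * nb * exp(-lam * h$score)
    if (ev <= thr)
      res[[length(res) + 1]] <- data.frame(
        a_start = h$a_start - 1L, a_end = h$a_end,
        b_start = h$b_start - 1L, b_end = h$b_end,
        score = h$score, evalue = ev, stringsAsFactors = FALSE)
  }
  if (length(res) == 0) return(empty_hsp_table())
  do.call(rbind, res)
}

empty_hsp_table <- function() {
  data.frame(a_start = integer(0), a_end = integer(0),
             b_start = integer(0), b_end = integer(0),
             score = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

# Ungapped X-drop extension of an exact word match at 1-based (i, j).
# +1/-2 scoring; vectorised along the diagonal with a cumulative-score
# trick: stop at the first point where the running score drops `xdrop`
# below its maximum, keep the prefix maximising the score.
xdrop_extend <- function(ra, rb, i, j, word, xdrop) {
  na <- length(ra); nb <- length(rb)
  extend <- function(ai, bi, dir) {
    len <- if (dir > 0) min(na - ai, nb - bi) else min(ai - 1L, bi - 1L)
    if (len <= 0) return(list(gain = 0, steps = 0L))
    ix <- if (dir > 0) (ai + 1L):(ai + len) else (ai - 1L):(ai - len)
    jx <- if (dir > 0) (bi + 1L):(bi + len) else (bi - 1L):(bi - len)
    sc <- cumsum(ifelse(ra[ix] == rb[jx], 1, -2))
    viol <- which(cummax(sc) - sc >= xdrop)
    lim <- if (length(viol) > 0) viol[1] else len
    best <- which.max(sc[seq_len(lim)])
    if (sc[best] <= 0) return(list(gain = 0, steps = 0L))
    list(gain = sc[best], steps = best)
  }
  fr <- extend(i + word - 1L, j + word - 1L, +1L)
  bk <- extend(i, j, -1L)
  list(a_start = i - bk$steps, a_end = i + word - 1L + fr$steps,
       b_start = j - bk$steps, b_end = j + word - 1L + fr$steps,
       score = word + fr$gain + bk$gain)
}

#' Map an E-value onto the similarity colour spectrum
#'
#' Shading between adjacent genomes is colour-coded by E-value: violet
#' for E = 0 (most similar) through the spectrum to red at the threshold
#' (least similar that still counts). The hue is interpolated linearly
#' from 270 degrees to 0 over
#' `t = clamp((log10(max(E, 1e-180)) + 180) / (log10(threshold) + 180), 0, 1)`.
#'
#' @param evalue E-value in `[0, threshold]`.
#' @param threshold the nucleotide E-value threshold in force.
#' @return hex colour string.
#' @export
#' @examples
#' evalue_to_color(0, 1e-4)      # violet
#' evalue_to_color(1e-4, 1e-4)   # red
evalue_to_color <- function(evalue, threshold = 1e-4) {
  if (evalue < 0) stop("evalue must be >= 0")
  if (evalue > threshold) stop("evalue exceeds threshold; filter first")
  t <- (log10(max(evalue, 1e-180)) + 180) / (log10(threshold) + 180)
  t <- min(max(t, 0), 1)
  hue <- 270 * (1 - t)
  grDevices::hsv(hue / 360, 1, 1)
}

#' Export similarity edges as TSV
#'
#' @param edges an edge data.frame (see [build_edge()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_edges <- function(edges, path) {
  write.table(edges[, c("gene_a", "gene_b", "percent_identity",
                        "blast_score", "evalue")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
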