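PHAM_SCHEMA_VERSION <- 1L

#' Create an empty in-memory pham database
#'
#' The store is an environment holding one data.frame per table, closely
#' mirroring a relational schema: `phage`, `gene`, `scores` (raw pairwise
#' identity and local-alignment score per unordered gene pair), `pham`,
#' `pham_history`, `pham_old` (retired phams) and `domain`. Raw scores
#' are kept permanently; E-values and threshold pass flags are derived
#' from them at the database size of the moment, so re-thresholding and
#' sweeps never re-align. A monotonic pham-number counter guarantees
#' retired numbers are never reused.
#'
#' @param config a [comparison_config()] echoed into the store for
#'   provenance; all subsequent operations default to it.
#' @return an environment of class `pham_db`.
#' @export
pham_db <- function(config = comparison_config()) {
  db <- new.env(parent = emptyenv())
  db$schema_version <- PHAM_SCHEMA_VERSION
  db$config <- config
  db$phage <- data.frame(name = character(0), accession = character(0),
                         length_bp = integer(0), cluster = character(0),
                         subcluster = character(0), sequence = character(0),
                         stringsAsFactors = FALSE)
  db$gene <- cbind(empty_gene_table(),
                   data.frame(phage = character(0), stringsAsFactors = FALSE))
  db$scores <- empty_scores_table()
  db$pham <- data.frame(number = integer(0), size = integer(0),
                        is_orpham = logical(0), stringsAsFactors = FALSE)
  db$pham_history <- data.frame(seq = integer(0), event = character(0),
                                old_numbers = character(0),
                                new_numbers = character(0),
                                trigger = character(0),
                                stringsAsFactors = FALSE)
  db$pham_old <- data.frame(number = integer(0), members = character(0),
                            retired_seq = integer(0),
                            stringsAsFactors = FALSE)
  db$domain <- data.frame(gene_id = character(0),
                          domain_accession = character(0),
                          description = character(0),
                          query_start = integer(0), query_end = integer(0),
                          evalue = numeric(0), stringsAsFactors = FALSE)
  db$next_pham_number <- 1L
  db$event_seq <- 0L
  class(db) <- "pham_db"
  db
}

#' @export
print.pham_db <- function(x, ...) {
  cat(sprintf("pham database: %d phages, %d genes, %d phams (%d orphams)\n",
              nrow(x$phage), nrow(x$gene), nrow(x$pham),
              sum(x$pham$is_orpham)))
  invisible(x)
}

# Total amino-acid residues currently in the database; this is the
# search-space size that enters every protein E-value.
database_residues <- function(db) {
  if (nrow(db$gene) == 0) return(0L)
  sum(nchar(db$gene$translation))
}

#' Open or create a file-backed store
#'
#' Creates an empty store at `path` when the file does not exist
#' (writing it immediately), otherwise loads and validates the existing
#' one. Idempotent on a valid store.
#'
#' @param path store file path (JSON).
#' @param config configuration used when creating a fresh store.
#' @return a `pham_db`.
#' @export
init_store <- function(path, config = comparison_config()) {
  if (file.exists(path)) return(db_load(path))
  db <- pham_db(config)
  db_save(db, path)
  db
}

#' Persist a store to disk as a single JSON file
#'
#' The dump is a faithful, full-precision serialisation of every table
#' plus counters; [db_load()] restores it bit-exactly.
#'
#' @param db a `pham_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
db_save <- function(db, path) {
  stopifnot(inherits(db, "pham_db"))
  cfg <- unclass(db$config)
  payload <- list(schema_version = db$schema_version,
                  next_pham_number = db$next_pham_number,
                  event_seq = db$event_seq,
                  config = cfg,
                  tables = lapply(pham_table_names(),
                                  function(t) db[[t]]))
  names(payload$tables) <- pham_table_names()
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

pham_table_names <- function() {
  c("phage", "gene", "scores", "pham", "pham_history", "pham_old", "domain")
}

#' Restore a store from its JSON dump
#'
#' @param path path written by [db_save()].
#' @return a `pham_db`.
#' @export
db_load <- function(path) {
  if (!file.exists(path)) stop("no such store: ", path)
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(payload$schema_version) ||
      payload$schema_version != PHAM_SCHEMA_VERSION)
    stop("store schema version mismatch: found ",
         payload$schema_version %||% "none", ", expected ",
         PHAM_SCHEMA_VERSION)
  cfg <- payload$config
  config <- comparison_config(
    identity_threshold = cfg$identity_threshold,
    evalue_threshold = cfg$evalue_threshold,
    nucleotide_evalue_threshold = cfg$nucleotide_evalue_threshold,
    protein_matrix = cfg$protein_matrix,
    gap_open = cfg$gap_open, gap_extend = cfg$gap_extend,
    nucleotide_match = cfg$nucleotide_match,
    nucleotide_mismatch = cfg$nucleotide_mismatch,
    karlin_lambda = cfg$karlin_lambda, karlin_K = cfg$karlin_K,
    nt_K = cfg$nt_K)
  db <- pham_db(config)
  db$next_pham_number <- as.integer(payload$next_pham_number)
  db$event_seq <- as.integer(payload$event_seq)
  for (t in pham_table_names()) {
    empty <- db[[t]]
    got <- payload$tables[[t]]
    if (is.null(got) || length(got) == 0 ||
        (is.data.frame(got) && nrow(got) == 0)) next
    got <- as.data.frame(got, stringsAsFactors = FALSE)
    for (col in names(empty)) {
      if (is.null(got[[col]])) stop("store table ", t, " lacks column ", col)
      mode_fun <- switch(class(empty[[col]])[1],
                         integer = as.integer, numeric = as.numeric,
                         logical = as.logical, as.character)
      got[[col]] <- mode_fun(got[[col]])
    }
    got <- got[, names(empty), drop = FALSE]
    rownames(got) <- NULL
    db[[t]] <- got
  }
  db
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Verify referential and partition integrity of a store
#'
#' Checks that every gene references an existing phage, every score row
#' and domain hit references existing genes, pham numbers partition the
#' gene set, sizes agree, and no retired number is in live use.
#'
#' @param db a `pham_db`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
db_integrity_check <- function(db) {
  stopifnot(inherits(db, "pham_db"))
  if (!all(db$gene$phage %in% db$phage$name))
    stop("gene referencing unknown phage")
  if (anyDuplicated(db$gene$gene_id))
    stop("duplicate gene_id")
  gid <- db$gene$gene_id
  if (!all(db$scores$gene_a %in% gid) || !all(db$scores$gene_b %in% gid))
    stop("score row referencing unknown gene")
  if (any(db$scores$gene_a >= db$scores$gene_b))
    stop("score rows must be canonical (gene_a < gene_b)")
  if (anyDuplicated(paste(db$scores$gene_a, db$scores$gene_b)))
    stop("duplicate score row")
  if (!all(db$domain$gene_id %in% gid))
    stop("domain hit referencing unknown gene")
  if (nrow(db$gene) > 0) {
    if (anyNA(db$gene$pham_number)) stop("gene without pham assignment")
    sizes <- table(db$gene$pham_number)
    if (!setequal(names(sizes), as.character(db$pham$number)))
      stop("pham table out of step with gene assignments")
    m <- match(as.character(db$pham$number), names(sizes))
    if (!all(db$pham$size == as.integer(sizes)[m]))
      stop("pham sizes out of step")
    if (!all(db$pham$is_orpham == (db$pham$size == 1L)))
      stop("orpham flags out of step")
  } else if (nrow(db$pham) > 0) {
    stop("phams present without genes")
  }
  if (any(db$pham$number %in% db$pham_old$number))
    stop("retired pham number in live use")
  if (any(db$pham$number >= db$next_pham_number) ||
      any(db$pham_old$number >= db$next_pham_number))
    stop("pham counter behind issued numbers")
  invisible(TRUE)
}

#' Snapshot summary statistics of a store
#'
#' Convenience wrapper computing [compute_stats()] over the current pham
#' partition plus phage/gene totals in one pass.
#'
#' @param db a `pham_db`.
#' @return a list: `n_phages`, `total_genes`, plus all [compute_stats()]
#'   fields.
#' @export
snapshot_stats <- function(db) {
  stopifnot(inherits(db, "pham_db"))
  st <- compute_stats(db$gene$pham_number[!is.na(db$gene$pham_number)])
  c(list(n_phages = nrow(db$phage)), st)
}
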