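# Derived view of the scores table: E-values and pass flags at the
# current database size and thresholds. Raw alignments are never redone;
# only this derivation changes when genomes come and go.
derive_edges <- function(scores, db_residues, config,
                         identity_threshold = config$identity_threshold,
                         evalue_threshold = config$evalue_threshold) {
  if (nrow(scores) == 0) {
    out <- scores
    out$evalue <- numeric(0)
    out$passes_identity <- logical(0)
    out$passes_evalue <- logical(0)
    return(out)
  }
  ev <- protein_evalue(scores$blast_score, scores$query_len,
                       db_residues, config)
  pi_ok <- if (is.na(identity_threshold)) rep(FALSE, nrow(scores))
           else scores$percent_identity >= identity_threshold
  ev_ok <- if (is.na(evalue_threshold)) rep(FALSE, nrow(scores))
           else ev <= evalue_threshold
  cbind(scores, data.frame(evalue = ev, passes_identity = pi_ok,
                           passes_evalue = ev_ok))
}

passing_edges <- function(db, identity_threshold = db$config$identity_threshold,
                          evalue_threshold = db$config$evalue_threshold) {
  e <- derive_edges(db$scores, database_residues(db), db$config,
                    identity_threshold, evalue_threshold)
  e[e$passes_identity | e$passes_evalue, , drop = FALSE]
}

#' Assort genes into phams by connected components
#'
#' Phams are the connected components of the graph whose vertices are
#' genes and whose edges are pairwise relationships passing either
#' threshold. Membership is therefore transitive: a fused gene C related
#' to both A and B pulls the otherwise unrelated A and B into one pham.
#' Genes with no passing edge become orphams. Pham numbers are assigned
#' 1..N in order of the smallest gene_id in each component.
#'
#' @param genes character vector of gene ids (or a data.frame with a
#'   `gene_id` column).
#' @param edges data.frame with columns `gene_a`, `gene_b`; every
#'   endpoint must be in `genes`.
#' @return a list with `assignment` (data.frame gene_id, pham_number)
#'   and `phams` (data.frame number, size, is_orpham).
#' @export
#' @examples
#' assemble_phams(c("A", "B", "C"),
#'                data.frame(gene_a = c("A", "B"), gene_b = c("C", "C")))
assemble_phams <- function(genes, edges = NULL) {
  ids <- if (is.data.frame(genes)) genes$gene_id else genes
  if (anyDuplicated(ids)) stop("duplicate gene ids")
  comp <- gene_components(ids, edges)
  numbers <- seq_along(comp)
  assignment <- data.frame(
    gene_id = unlist(comp, use.names = FALSE),
    pham_number = rep.int(numbers, lengths(comp)),
    stringsAsFactors = FALSE)
  assignment <- assignment[match(ids, assignment$gene_id), , drop = FALSE]
  rownames(assignment) <- NULL
  phams <- data.frame(number = numbers, size = lengths(comp),
                      is_orpham = lengths(comp) == 1L,
                      stringsAsFactors = FALSE)
  list(assignment = assignment, phams = phams)
}

# Connected components over gene ids, returned as a list of member
# vectors (each sorted) ordered by smallest member gene_id.
gene_components <- function(ids, edges) {
  if (length(ids) == 0) return(list())
  if (!is.null(edges) && nrow(edges) > 0) {
    unknown <- setdiff(c(edges$gene_a, edges$gene_b), ids)
    if (length(unknown) > 0)
      stop("edge referencing unknown gene: ", unknown[1])
    g <- igraph::graph_from_data_frame(
      edges[, c("gene_a", "gene_b")], directed = FALSE,
      vertices = data.frame(name = ids, stringsAsFactors = FALSE))
    memb <- igraph::components(g)$membership
    comp <- split(names(memb), memb)
  } else {
    comp <- as.list(ids)
  }
  comp <- lapply(comp, function(x) sort(as.character(x)))
  comp[order(vapply(comp, `[`, character(1), 1))]
}

#' Add a genome to the database and update pham assignments
#'
#' Appends the phage and its genes, computes raw pairwise scores for the
#' new genes against everything (including new-vs-new), derives pass
#' flags at the enlarged database size, and re-forms connected
#' components. A component keeps a prior pham number iff it contains
#' every surviving member of exactly one prior pham and no member of any
#' other; otherwise all touched numbers are retired and a fresh number
#' is issued. When a new protein bridges two existing phams the phams
#' are merged, their numbers retired, and a new pham created containing
#' all their members plus the new protein. Because E-values grow with
#' database size, an addition can also knock borderline pairs below
#' threshold and split phams or demote proteins to orphams.
#'
#' @param db a `pham_db`.
#' @param phage a [new_phage()] record not yet in the database.
#' @param config comparison configuration (defaults to the store's).
#' @return a pham update report: lists of phams `created`, `retired`,
#'   `merged`, `split`, and `new_orphams`.
#' @export
add_genome <- function(db, phage, config = db$config) {
  stopifnot(inherits(db, "pham_db"), inherits(phage, "phage"))
  if (phage$name %in% db$phage$name)
    stop("phage already in database: ", phage$name)
  if (any(phage$genes$gene_id %in% db$gene$gene_id))
    stop("gene_id collision adding phage ", phage$name)
  db$config <- config
  db$phage <- rbind(db$phage, data.frame(
    name = phage$name, accession = phage$accession,
    length_bp = phage$length_bp, cluster = phage$cluster,
    subcluster = if (is.na(phage$subcluster)) NA_character_ else phage$subcluster,
    sequence = phage$genome_sequence, stringsAsFactors = FALSE))
  new_genes <- phage$genes
  new_genes$phage <- phage$name
  new_genes$pham_number <- NA_integer_
  old_genes <- db$gene
  db$gene <- rbind(old_genes, new_genes[, names(db$gene), drop = FALSE])
  # raw scores: new-vs-existing and new-vs-new, one row per unordered pair
  pairs_a <- list(); pairs_b <- list()
  n_new <- nrow(new_genes)
  if (n_new > 0 && nrow(old_genes) > 0) {
    idx <- expand.grid(i = seq_len(n_new), j = seq_len(nrow(old_genes)))
    pairs_a[[1]] <- new_genes[idx$i, , drop = FALSE]
    pairs_b[[1]] <- old_genes[idx$j, , drop = FALSE]
  }
  if (n_new > 1) {
    idx <- which(upper.tri(matrix(0, n_new, n_new)), arr.ind = TRUE)
    pairs_a[[2]] <- new_genes[idx[, 1], , drop = FALSE]
    pairs_b[[2]] <- new_genes[idx[, 2], , drop = FALSE]
  }
  if (length(pairs_a) > 0) {
    ga <- do.call(rbind, pairs_a)
    gb <- do.call(rbind, pairs_b)
    db$scores <- rbind(db$scores, score_gene_pairs(ga, gb, config))
  }
  reassign_phams(db, trigger = paste0("genome added: ", phage$name))
}

#' Remove a genome and update pham assignments
#'
#' Deletes the phage, its genes, incident score rows and domain hits,
#' then recomputes pass flags at the reduced database size and re-forms
#' components. A pham whose members are split across components has its
#' number retired and fresh numbers issued for the fragments (a split
#' event); a member left alone is demoted to an orpham.
#'
#' @param db a `pham_db`.
#' @param phage_name name of a phage present in the database.
#' @return a pham update report (see [add_genome()]).
#' @export
remove_genome <- function(db, phage_name) {
  stopifnot(inherits(db, "pham_db"))
  if (!phage_name %in% db$phage$name)
    stop("phage not in database: ", phage_name)
  gone <- db$gene$gene_id[db$gene$phage == phage_name]
  db$phage <- db$phage[db$phage$name != phage_name, , drop = FALSE]
  db$gene <- db$gene[db$gene$phage != phage_name, , drop = FALSE]
  db$scores <- db$scores[!(db$scores$gene_a %in% gone |
                           db$scores$gene_b %in% gone), , drop = FALSE]
  db$domain <- db$domain[!db$domain$gene_id %in% gone, , drop = FALSE]
  reassign_phams(db, trigger = paste0("genome removed: ", phage_name))
}

# Re-form components, apply the number-retention rule, and record
# history events. This is the single path through which pham identity
# ever changes.
reassign_phams <- function(db, trigger) {
  prior <- split(db$gene$gene_id[!is.na(db$gene$pham_number)],
                 db$gene$pham_number[!is.na(db$gene$pham_number)])
  prior_numbers <- as.integer(names(prior))
  edges <- passing_edges(db)
  comp <- gene_components(db$gene$gene_id, edges)

  # map prior phams onto new components
  comp_of_gene <- setNames(rep.int(seq_along(comp), lengths(comp)),
                           unlist(comp, use.names = FALSE))
  priors_in_comp <- vector("list", length(comp))
  comps_of_prior <- vector("list", length(prior))
  for (p in seq_along(prior)) {
    cs <- sort(unique(comp_of_gene[prior[[p]]]))
    comps_of_prior[[p]] <- cs
    for (ci in cs)
      priors_in_comp[[ci]] <- c(priors_in_comp[[ci]], p)
  }

  numbers <- integer(length(comp))
  kept <- logical(length(prior))
  for (ci in seq_along(comp)) {
    ps <- priors_in_comp[[ci]]
    if (length(ps) == 1 && length(comps_of_prior[[ps]]) == 1) {
      numbers[ci] <- prior_numbers[ps]   # superset of exactly one prior
      kept[ps] <- TRUE
    }
  }
  fresh <- which(numbers == 0L)
  if (length(fresh) > 0) {
    issue <- seq.int(db$next_pham_number, length.out = length(fresh))
    numbers[fresh] <- issue
    db$next_pham_number <- db$next_pham_number + length(fresh)
  }

  # events
  report <- list(created = integer(0), retired = integer(0),
                 merged = list(), split = list(), new_orphams = integer(0))
  add_event <- function(event, old, new) {
    db$event_seq <- db$event_seq + 1L
    db$pham_history <- rbind(db$pham_history, data.frame(
      seq = db$event_seq, event = event,
      old_numbers = paste(old, collapse = ","),
      new_numbers = paste(new, collapse = ","),
      trigger = trigger, stringsAsFactors = FALSE))
  }
  for (ci in seq_along(comp)) {
    ps <- priors_in_comp[[ci]]
    if (length(ps) == 0) {
      add_event("create", integer(0), numbers[ci])
      report$created <- c(report$created, numbers[ci])
      if (length(comp[[ci]]) == 1)
        report$new_orphams <- c(report$new_orphams, numbers[ci])
    } else if (length(ps) >= 2) {
      olds <- sort(prior_numbers[ps])
      add_event("merge", olds, numbers[ci])
      report$merged <- c(report$merged, list(list(old = olds,
                                                  new = numbers[ci])))
    }
  }
  for (p in seq_along(prior)) {
    cs <- comps_of_prior[[p]]
    if (length(cs) >= 2) {
      news <- sort(numbers[cs])
      add_event("split", prior_numbers[p], news)
      report$split <- c(report$split, list(list(old = prior_numbers[p],
                                                new = news)))
      for (ci in cs)
        if (length(comp[[ci]]) == 1 && length(prior[[p]]) > 1)
          add_event("demote_to_orpham", prior_numbers[p], numbers[ci])
    }
  }
  retired <- prior_numbers[!kept]
  for (i in which(!kept)) {
    add_event("retire", prior_numbers[i], integer(0))
    db$pham_old <- rbind(db$pham_old, data.frame(
      number = prior_numbers[i],
      members = paste(sort(prior[[i]]), collapse = ";"),
      retired_seq = db$event_seq, stringsAsFactors = FALSE))
  }
  report$retired <- sort(retired)

  # apply assignments
  db$gene$pham_number <- unname(numbers[comp_of_gene[db$gene$gene_id]])
  if (length(comp) > 0) {
    ord <- order(numbers)
    db$pham <- data.frame(number = numbers[ord],
                          size = lengths(comp)[ord],
                          is_orpham = lengths(comp)[ord] == 1L,
                          stringsAsFactors = FALSE)
  } else {
    db$pham <- db$pham[0, , drop = FALSE]
  }
  for (t in pham_table_names()) rownames(db[[t]]) <- NULL
  invisible(report)
}

#' Pairwise values of pham members relative to a reference gene
#'
#' For every other member of the pham, reports the stored percent
#' identity and the E-value at the current database size against the
#' chosen reference gene, flagging rows that fall below both thresholds:
#' sub-threshold pairs legitimately occur inside a pham because
#' membership is transitive.
#'
#' @param db a `pham_db`.
#' @param pham_number an existing pham number.
#' @param reference_gene gene_id of a member of that pham.
#' @return data.frame with columns gene_id, percent_identity, evalue,
#'   below_threshold; zero rows for an orpham.
#' @export
pham_detail <- function(db, pham_number, reference_gene) {
  stopifnot(inherits(db, "pham_db"))
  if (!pham_number %in% db$pham$number)
    stop("no such pham: ", pham_number)
  members <- db$gene$gene_id[db$gene$pham_number == pham_number]
  if (!reference_gene %in% members)
    stop(reference_gene, " is not a member of pham ", pham_number)
  others <- setdiff(members, reference_gene)
  e <- derive_edges(db$scores, database_residues(db), db$config)
  out <- lapply(others, function(g) {
    a <- min(reference_gene, g); b <- max(reference_gene, g)
    row <- e[e$gene_a == a & e$gene_b == b, , drop = FALSE]
    if (nrow(row) == 0)
      data.frame(gene_id = g, percent_identity = 0, evalue = Inf,
                 below_threshold = TRUE, stringsAsFactors = FALSE)
    else
      data.frame(gene_id = g, percent_identity = row$percent_identity,
                 evalue = row$evalue,
                 below_threshold = !(row$passes_identity | row$passes_evalue),
                 stringsAsFactors = FALSE)
  })
  if (length(out) == 0)
    return(data.frame(gene_id = character(0), percent_identity = numeric(0),
                      evalue = numeric(0), below_threshold = logical(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$gene_id), , drop = FALSE]
}

#' Export the pham table as TSV
#'
#' One row per pham: number, size, semicolon-joined member gene ids.
#'
#' @param db a `pham_db`.
#' @param path output path; `NULL` returns the data.frame.
#' @return the table, invisibly when written.
#' @export
export_phams <- function(db, path = NULL) {
  stopifnot(inherits(db, "pham_db"))
  members <- split(db$gene$gene_id, db$gene$pham_number)
  tab <- data.frame(
    pham_number = as.integer(names(members)),
    size = lengths(members),
    members = vapply(members, function(x) paste(sort(x), collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$pham_number), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
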