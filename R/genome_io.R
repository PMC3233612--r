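#' Construct a phage genome record
#'
#' A `phage` is the unit record of the database: a genome sequence plus
#' its ordered table of protein-coding genes. Coordinates are stored
#' 0-based half-open on the forward strand; `strand` is `"forward"` or
#' `"reverse"`. Gene display names follow the annotation's `/gene`
#' qualifier, falling back to `/locus_tag` and finally to the ordinal
#' position.
#'
#' @param name phage identifier (unique within a database).
#' @param sequence genome DNA string over A/C/G/T/N. Other IUPAC
#'   ambiguity codes are normalised to N with a warning.
#' @param genes data.frame with columns `name`, `start`, `stop`,
#'   `strand`, `translation` (and optionally `gene_id`, `pham_number`).
#' @param accession GenBank accession, may be "".
#' @param cluster,subcluster nucleotide-similarity grouping labels;
#'   `cluster` defaults to `"singleton"`.
#' @return an object of class `phage`.
#' @export
new_phage <- function(name, sequence, genes = empty_gene_table(),
                      accession = "", cluster = "singleton",
                      subcluster = NA_character_) {
  stopifnot(is.character(name), nchar(name) > 0)
  sequence <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0) {
    warning("normalising ambiguity codes to N in ", name, ": ",
            paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes) > 0) {
    if (is.null(genes$gene_id))
      genes$gene_id <- paste(name, genes$name, sep = "_")
    if (is.null(genes$pham_number)) genes$pham_number <- NA_integer_
    genes <- genes[order(genes$start, genes$stop, genes$name), , drop = FALSE]
    rownames(genes) <- NULL
    validate_genes(genes, nchar(sequence), name)
  } else {
    genes <- empty_gene_table()
  }
  structure(list(name = name, accession = accession,
                 genome_sequence = sequence, length_bp = nchar(sequence),
                 genes = genes, cluster = cluster, subcluster = subcluster),
            class = "phage")
}

#' @export
print.phage <- function(x, ...) {
  cat(sprintf("phage %s: %d bp, %d genes, cluster %s%s\n", x$name,
              x$length_bp, nrow(x$genes), x$cluster,
              if (is.na(x$subcluster)) "" else paste0("/", x$subcluster)))
  invisible(x)
}

empty_gene_table <- function() {
  data.frame(gene_id = character(0), name = character(0),
             start = integer(0), stop = integer(0), strand = character(0),
             translation = character(0), pham_number = integer(0),
             stringsAsFactors = FALSE)
}

validate_genes <- function(genes, length_bp, phage_name) {
  if (anyDuplicated(genes$name))
    stop("duplicate gene names in phage ", phage_name)
  if (any(genes$start >= genes$stop))
    stop("gene with start >= stop in phage ", phage_name)
  if (any(genes$start < 0) || any(genes$stop > length_bp))
    stop("gene coordinates outside genome in phage ", phage_name)
  if (!all(genes$strand %in% c("forward", "reverse")))
    stop("strand must be 'forward' or 'reverse' in phage ", phage_name)
  if (any(nchar(genes$translation) == 0))
    stop("empty translation in phage ", phage_name)
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
               genes$translation)
  if (any(bad))
    stop("translation with invalid residues in phage ", phage_name,
         " gene ", genes$name[bad][1])
  if (any(genes$stop - genes$start < 3 * nchar(genes$translation)))
    stop("gene span shorter than 3x translation length in phage ",
         phage_name)
  invisible(TRUE)
}

#' Read an annotated phage genome from a GenBank flat file
#'
#' Parses a single-record GenBank flat file: the LOCUS name, ACCESSION,
#' ORIGIN sequence, and every CDS feature carrying coordinates and
#' (usually) a `/translation` qualifier. GenBank 1-based inclusive spans
#' become 0-based half-open coordinates; `complement(...)` features get
#' `strand = "reverse"`. A CDS without `/translation` is translated from
#' the genome with translation table 11 (with a warning); a joined
#' multi-interval CDS is reduced to its outermost span (with a warning).
#'
#' @param path path to a GenBank flat file.
#' @return a [new_phage()] record with genes ordered by start coordinate.
#' @export
parse_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) stop("not a GenBank flat file (no LOCUS): ", path)
  name <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "[[:space:]]+")[[1]][1]
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line) > 0) {
    a <- trimws(sub("^ACCESSION", "", acc_line[1]))
    if (identical(a, "") || identical(a, ".")) "" else strsplit(a, "[[:space:]]+")[[1]][1]
  } else ""

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0) stop("GenBank file has no ORIGIN sequence: ", path)
  endrec <- grep("^//", lines)
  endrec <- endrec[endrec > ori[1]]
  if (length(endrec) == 0) endrec <- length(lines) + 1
  seq_lines <- lines[(ori[1] + 1):(endrec[1] - 1)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0) stop("GenBank file has empty sequence: ", path)

  feat_start <- grep("^FEATURES", lines)
  genes <- empty_gene_table()
  if (length(feat_start) > 0) {
    feat_lines <- lines[(feat_start[1] + 1):(ori[1] - 1)]
    genes <- parse_cds_features(feat_lines, name, sequence)
  }
  new_phage(name, sequence, genes, accession = accession)
}

# Split the FEATURES block into individual features (key starts in col 6)
# and extract every CDS into a gene-table row.
parse_cds_features <- function(feat_lines, phage_name, sequence) {
  is_key <- grepl("^ {5}\\S", feat_lines)
  if (!any(is_key)) return(empty_gene_table())
  grp <- cumsum(is_key)
  feats <- split(feat_lines[grp > 0], grp[grp > 0])
  rows <- list()
  ordinal <- 0L
  for (fl in feats) {
    key <- strsplit(trimws(fl[1]), "[[:space:]]+")[[1]][1]
    if (!identical(key, "CDS")) next
    ordinal <- ordinal + 1L
    # location may continue until the first qualifier line
    qual_start <- grep("^ {10,}/", fl)
    loc_end <- if (length(qual_start) > 0) qual_start[1] - 1 else length(fl)
    loc <- paste(trimws(sub("^ {5}\\S+", "", fl[1])),
                 paste(trimws(fl[seq_len(loc_end)][-1]), collapse = ""),
                 sep = "")
    loc <- gsub("[[:space:]]", "", loc)
    strand <- if (grepl("complement", loc)) "reverse" else "forward"
    if (grepl("join|order", loc))
      warning("multi-interval CDS reduced to outermost span in ",
              phage_name, ": ", loc)
    pos <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
    if (length(pos) < 2) stop("unparseable CDS location: ", loc)
    start1 <- min(pos); stop1 <- max(pos)

    quals <- parse_qualifiers(fl[seq.int(loc_end + 1, length.out = max(0, length(fl) - loc_end))])
    gname <- quals[["gene"]]
    if (is.null(gname)) gname <- quals[["locus_tag"]]
    if (is.null(gname)) gname <- as.character(ordinal)
    translation <- quals[["translation"]]
    if (is.null(translation)) {
      warning("CDS without /translation in ", phage_name,
              " (", gname, "); translating with table 11")
      translation <- translate_cds(sequence, start1 - 1L, stop1, strand)
    }
    rows[[length(rows) + 1]] <- data.frame(
      name = gname, start = start1 - 1L, stop = stop1, strand = strand,
      translation = toupper(gsub("\\*$", "", translation)),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_gene_table())
  do.call(rbind, rows)
}

# Qualifier lines: /name="value" with values possibly wrapped over lines.
parse_qualifiers <- function(qlines) {
  if (length(qlines) == 0) return(list())
  qlines <- trimws(qlines)
  starts <- grepl("^/", qlines)
  grp <- cumsum(starts)
  out <- list()
  for (q in split(qlines[grp > 0], grp[grp > 0])) {
    txt <- paste(q, collapse = if (grepl("^/translation", q[1])) "" else " ")
    m <- regmatches(txt, regexec("^/([A-Za-z_]+)(=(.*))?$", txt))[[1]]
    if (length(m) == 0) next
    out[[m[2]]] <- gsub('"', "", m[4])
  }
  out
}

# Translate a forward-strand [start0, stop) span (reverse-complemented
# first when strand = "reverse") with genetic code table 11.
translate_cds <- function(sequence, start0, stop, strand) {
  dna <- substr(sequence, start0 + 1, stop)
  if (identical(strand, "reverse"))
    dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  usable <- 3L * (nchar(dna) %/% 3L)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1, usable)),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  sub("\\*.*$", "", aa)
}

#' Export a phage proteome as FASTA text
#'
#' One record per gene in start-coordinate order; headers are the
#' `gene_id` (phage name + gene name), sequences are the translations.
#'
#' @param phage a [new_phage()] record.
#' @param width line-wrap width for sequences.
#' @return a single FASTA string ("" for a phage without genes).
#' @export
export_proteome <- function(phage, width = 60) {
  stopifnot(inherits(phage, "phage"))
  g <- phage$genes
  if (nrow(g) == 0) return("")
  recs <- vapply(seq_len(nrow(g)), function(i) {
    s <- g$translation[i]
    chunks <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
    paste0(">", g$gene_id[i], "\n", paste(chunks, collapse = "\n"))
  }, character(1))
  paste0(paste(recs, collapse = "\n"), "\n")
}

#' Export the gene table of a phage or database as TSV
#'
#' Columns: phage, gene, start, stop, strand, pham, translation_length.
#'
#' @param x a `phage` or a `pham_db` store.
#' @param path output path; when `NULL` the data.frame is returned.
#' @return the gene table data.frame, invisibly when written to a file.
#' @export
export_gene_table <- function(x, path = NULL) {
  tab <- if (inherits(x, "phage")) {
    data.frame(phage = rep(x$name, nrow(x$genes)), gene = x$genes$name,
               start = x$genes$start, stop = x$genes$stop,
               strand = x$genes$strand, pham = x$genes$pham_number,
               translation_length = nchar(x$genes$translation),
               stringsAsFactors = FALSE)
  } else if (inherits(x, "pham_db")) {
    g <- x$gene
    data.frame(phage = g$phage, gene = g$name, start = g$start,
               stop = g$stop, strand = g$strand, pham = g$pham_number,
               translation_length = nchar(g$translation),
               stringsAsFactors = FALSE)
  } else stop("x must be a phage or a pham_db")
  if (!is.null(path)) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Write a phage record as a GenBank flat file
#'
#' Emits a minimal single-record GenBank flat file (LOCUS, ACCESSION,
#' FEATURES with one CDS per gene carrying `/gene`, `/locus_tag` and
#' `/translation`, and the ORIGIN sequence). Output is deterministic:
#' the LOCUS date is fixed, so identical records give identical bytes.
#' Files written here parse back losslessly with [parse_genbank()].
#'
#' @param phage a [new_phage()] record.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(phage, path) {
  stopifnot(inherits(phage, "phage"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf("LOCUS       %-17s %d bp    DNA     linear   PHG 01-JAN-2000",
            phage$name, phage$length_bp))
  w(sprintf("DEFINITION  %s, synthetic phage genome.", phage$name))
  w(sprintf("ACCESSION   %s",
            if (nchar(phage$accession) > 0) phage$accession else "."))
  w("FEATURES             Location/Qualifiers")
  w(sprintf("     source          1..%d", phage$length_bp))
  g <- phage$genes
  for (i in seq_len(nrow(g))) {
    span <- sprintf("%d..%d", g$start[i] + 1L, g$stop[i])
    if (g$strand[i] == "reverse") span <- sprintf("complement(%s)", span)
    w(sprintf("     CDS             %s", span))
    w(sprintf('                     /gene="%s"', g$name[i]))
    w(sprintf('                     /locus_tag="%s"', g$gene_id[i]))
    tr <- paste0('/translation="', g$translation[i], '"')
    pos <- seq(1, nchar(tr), 58)
    for (chunk in substring(tr, pos, pmin(pos + 57, nchar(tr))))
      w(paste0(strrep(" ", 21), chunk))
  }
  w("ORIGIN")
  s <- tolower(phage$genome_sequence)
  starts <- seq(1, nchar(s), 60)
  for (st in starts) {
    blocks <- substring(s, seq(st, min(st + 59, nchar(s)), 10),
                        pmin(seq(st, min(st + 59, nchar(s)), 10) + 9, nchar(s)))
    w(sprintf("%9d %s", st, paste(blocks, collapse = " ")))
  }
  w("//")
  invisible(path)
}

#' Attach cluster/subcluster labels from a TSV table
#'
#' The table must have columns `phage`, `cluster` and optionally
#' `subcluster`. Phages absent from the table keep their current labels.
#'
#' @param db a `pham_db` store.
#' @param path TSV path.
#' @return number of phages relabelled, invisibly.
#' @export
assign_clusters <- function(db, path) {
  stopifnot(inherits(db, "pham_db"))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("phage", "cluster") %in% names(tab)))
    stop("cluster table needs columns phage, cluster")
  hit <- match(db$phage$name, tab$phage)
  sel <- !is.na(hit)
  db$phage$cluster[sel] <- tab$cluster[hit[sel]]
  if ("subcluster" %in% names(tab))
    db$phage$subcluster[sel] <- tab$subcluster[hit[sel]]
  invisible(sum(sel))
}
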