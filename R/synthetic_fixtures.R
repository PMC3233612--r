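#' Specification for a synthetic phage cohort
#'
#' Describes a cohort of artificial phage genomes with planted ground
#' truth: protein families at controlled pairwise divergence, a
#' configurable fraction of orphan (family-less) genes, optional
#' fused-gene events (a protein concatenating two family ancestors,
#' which transitively joins the two families into one pham), shared
#' nucleotide blocks planted into otherwise unrelated backgrounds, and
#' random background padding. Members of a family are produced by
#' per-site substitution of a common ancestor, calibrated so realised
#' pairwise identity lands within +/-5 points of the target (verified
#' with the package's own aligner, resampling on miss). The same seed
#' always yields byte-identical GenBank output.
#'
#' @param n_phages number of genomes.
#' @param genes_per_phage genes per genome (family slots + orphans).
#' @param n_families number of planted protein families.
#' @param family_identity target pairwise percent identity within each
#'   family; scalar or one value per family.
#' @param orphan_fraction fraction of each genome's genes that are
#'   unrelated singletons.
#' @param fused_gene_events number of fused-gene constructs to plant.
#' @param shared_blocks list of `list(length_bp =, participants =)`
#'   describing exact nucleotide blocks copied into the named genomes
#'   (participants are phage indices).
#' @param background_bp random background sequence appended to each
#'   genome (blocks are planted inside it when present).
#' @param protein_length `c(min, max)` ancestor protein length range.
#' @param seed RNG seed; all cohort randomness flows from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_phages = 5, genes_per_phage = 8, n_families = 6,
                        family_identity = 90, orphan_fraction = 0.15,
                        fused_gene_events = 0, shared_blocks = list(),
                        background_bp = 0, protein_length = c(60, 120),
                        seed = 1) {
  stopifnot(n_phages >= 1, genes_per_phage >= 0, n_families >= 0,
            all(family_identity > 0), all(family_identity <= 100),
            orphan_fraction >= 0, orphan_fraction <= 1,
            fused_gene_events >= 0, background_bp >= 0,
            length(protein_length) == 2,
            protein_length[1] >= 10, protein_length[2] >= protein_length[1])
  if (fused_gene_events > 0 && n_families < 2)
    stop("fused-gene events need at least two families")
  if (length(family_identity) == 1)
    family_identity <- rep(family_identity, max(n_families, 1))
  if (n_families > 0 && length(family_identity) != n_families)
    stop("family_identity must be scalar or one value per family")
  for (b in shared_blocks) {
    stopifnot(is.list(b), !is.null(b$length_bp), !is.null(b$participants))
    if (b$length_bp < 20) stop("shared blocks must be >= 20 bp")
    if (any(b$participants < 1) || any(b$participants > n_phages))
      stop("block participant index out of range")
  }
  structure(list(n_phages = n_phages, genes_per_phage = genes_per_phage,
                 n_families = n_families, family_identity = family_identity,
                 orphan_fraction = orphan_fraction,
                 fused_gene_events = fused_gene_events,
                 shared_blocks = shared_blocks,
                 background_bp = background_bp,
                 protein_length = protein_length, seed = seed),
            class = "cohort_spec")
}

AA20 <- setdiff(AA_ALPHABET, "X")

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  if (len == 0) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Substitute a fraction q of sites to a different residue.
mutate_protein <- function(seq, q) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- round(q * length(ch))
  if (k > 0) {
    pos <- sample(length(ch), k)
    ch[pos] <- vapply(ch[pos],
                      function(r) sample(setdiff(AA20, r), 1), character(1))
  }
  paste(ch, collapse = "")
}

# Back-translate with genetic code table 11, random synonymous codons.
back_translate <- function(protein) {
  codons <- .codon_choices()
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(a) {
    cs <- codons[[a]]
    if (is.null(cs)) stop("cannot back-translate residue ", a)
    if (length(cs) == 1) cs else sample(cs, 1)
  }, character(1)), collapse = "")
}

.codon_choices <- function() {
  if (!is.null(.pham_env$codon_choices)) return(.pham_env$codon_choices)
  gc11 <- Biostrings::getGeneticCode("11")
  out <- split(names(gc11), gc11)
  out <- out[names(out) != "*"]
  .pham_env$codon_choices <- out
  out
}

#' Generate a synthetic phage cohort with planted truth
#'
#' Realises a [cohort_spec()]: builds the family ancestors, diverged
#' members, orphans, fused genes and genomes, optionally writes one
#' GenBank flat file per phage plus truth tables into `dir`, and returns
#' everything in memory. Family divergence is verified against the first
#' realised member with the package aligner and resampled (up to 25
#' tries) until pairwise identity is within +/-5 points of target;
#' persistent failure is an infeasible-spec error.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory for GenBank files and truth tables;
#'   `NULL` keeps everything in memory.
#' @return list with `phages` (list of [new_phage()] records),
#'   `truth_genes` (data.frame gene_id, phage, gene, family),
#'   `truth_blocks` (data.frame block, phage, start, end), and `files`
#'   (GenBank paths, `NULL` when `dir` is `NULL`).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  n_orphans <- round(spec$orphan_fraction * spec$genes_per_phage)
  n_slots <- spec$genes_per_phage - n_orphans
  if (n_slots > 0 && spec$n_families == 0)
    stop("family slots requested but n_families is 0")

  anc_len <- if (spec$n_families > 0)
    sample(seq(spec$protein_length[1], spec$protein_length[2]),
           spec$n_families, replace = TRUE) else integer(0)
  ancestors <- vapply(anc_len, random_protein, character(1))
  q <- 1 - sqrt(spec$family_identity / 100)
  first_member <- rep(NA_character_, spec$n_families)

  make_member <- function(f) {
    for (try in 1:25) {
      cand <- mutate_protein(ancestors[f], q[f])
      if (is.na(first_member[f])) {
        first_member[f] <<- cand
        return(cand)
      }
      pid <- percent_identity(cand, first_member[f])
      if (abs(pid - spec$family_identity[f]) <= 5) return(cand)
    }
    stop("infeasible spec: cannot realise family ", f, " at ",
         spec$family_identity[f], "% identity")
  }

  phage_names <- sprintf("SynPhage%02d", seq_len(spec$n_phages))
  phages <- vector("list", spec$n_phages)
  truth_genes <- list()
  truth_blocks <- list()

  # pre-generate shared blocks
  block_seqs <- lapply(spec$shared_blocks, function(b) random_dna(b$length_bp))

  for (p in seq_len(spec$n_phages)) {
    prots <- character(0); fams <- character(0)
    if (n_slots > 0) {
      fam_idx <- ((p - 1 + seq_len(n_slots) - 1) %% spec$n_families) + 1
      for (f in fam_idx) {
        prots <- c(prots, make_member(f))
        fams <- c(fams, paste0("F", f))
      }
    }
    if (n_orphans > 0) {
      for (o in seq_len(n_orphans)) {
        prots <- c(prots, random_protein(
          sample(seq(spec$protein_length[1], spec$protein_length[2]), 1)))
        fams <- c(fams, "orphan")
      }
    }
    if (spec$fused_gene_events > 0) {
      for (e in seq_len(spec$fused_gene_events)) {
        if (((e - 1) %% spec$n_phages) + 1 != p) next
        f1 <- ((2 * e - 2) %% spec$n_families) + 1
        f2 <- ((2 * e - 1) %% spec$n_families) + 1
        if (f1 == f2) f2 <- (f2 %% spec$n_families) + 1
        prots <- c(prots, paste0(ancestors[f1], ancestors[f2]))
        fams <- c(fams, paste0("F", f1, "+F", f2))
      }
    }

    # assemble the genome: spacer, CDS, spacer, CDS, ...
    pieces <- character(0)
    starts <- integer(0); stops <- integer(0); strands <- character(0)
    pos <- 0L
    for (gi in seq_along(prots)) {
      spacer <- random_dna(sample(20:80, 1))
      pieces <- c(pieces, spacer)
      pos <- pos + nchar(spacer)
      cds <- paste0(back_translate(prots[gi]), "TAA")
      strand <- if (runif(1) < 0.2) "reverse" else "forward"
      ins <- if (strand == "reverse")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
      else cds
      pieces <- c(pieces, ins)
      starts <- c(starts, pos)
      stops <- c(stops, pos + nchar(ins))
      strands <- c(strands, strand)
      pos <- pos + nchar(ins)
    }
    tail_spacer <- random_dna(sample(20:80, 1))
    pieces <- c(pieces, tail_spacer)
    pos <- pos + nchar(tail_spacer)

    # background padding, with any shared blocks planted inside it
    my_blocks <- which(vapply(spec$shared_blocks,
                              function(b) p %in% b$participants, logical(1)))
    pad <- spec$background_bp
    if (length(my_blocks) > 0 || pad > 0) {
      pad_seq <- random_dna(pad)
      offset_base <- pos
      cursor <- 0L
      for (bi in my_blocks) {
        blk <- block_seqs[[bi]]
        slack <- nchar(pad_seq) - cursor
        at <- if (slack > 0) cursor + sample.int(slack, 1) else cursor
        pad_seq <- paste0(substr(pad_seq, 1, at), blk,
                          substr(pad_seq, at + 1, nchar(pad_seq)))
        truth_blocks[[length(truth_blocks) + 1]] <- data.frame(
          block = bi, phage = phage_names[p],
          start = offset_base + at, end = offset_base + at + nchar(blk),
          stringsAsFactors = FALSE)
        cursor <- at + nchar(blk)
      }
      pieces <- c(pieces, pad_seq)
    }

    genes <- if (length(prots) > 0) data.frame(
      name = as.character(seq_along(prots)), start = starts, stop = stops,
      strand = strands, translation = prots, stringsAsFactors = FALSE)
    else empty_gene_table()
    phg <- new_phage(phage_names[p], paste(pieces, collapse = ""), genes)
    phages[[p]] <- phg
    if (length(prots) > 0)
      truth_genes[[length(truth_genes) + 1]] <- data.frame(
        gene_id = paste(phage_names[p], seq_along(prots), sep = "_"),
        phage = phage_names[p], gene = as.character(seq_along(prots)),
        family = fams, stringsAsFactors = FALSE)
  }

  truth_genes <- if (length(truth_genes) > 0) do.call(rbind, truth_genes)
    else data.frame(gene_id = character(0), phage = character(0),
                    gene = character(0), family = character(0),
                    stringsAsFactors = FALSE)
  truth_blocks <- if (length(truth_blocks) > 0) do.call(rbind, truth_blocks)
    else data.frame(block = integer(0), phage = character(0),
                    start = integer(0), end = integer(0),
                    stringsAsFactors = FALSE)

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- vapply(phages, function(ph) {
      f <- file.path(dir, paste0(ph$name, ".gbk"))
      write_genbank(ph, f)
      f
    }, character(1))
    write.table(truth_genes, file.path(dir, "truth_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(truth_blocks, file.path(dir, "truth_blocks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(spec), file.path(dir, "cohort_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(spec = spec, phages = phages, truth_genes = truth_genes,
       truth_blocks = truth_blocks, files = files)
}
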