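# Independent oracles used to cross-check the package implementation.

AAS <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
         "P","S","T","W","Y","V")

random_protein_str <- function(n) paste(sample(AAS, n, TRUE), collapse = "")

# Mutate a fraction q of sites to a different residue (test-local copy,
# independent of the package generator).
mutate_protein_str <- function(seq, q) {
  ch <- strsplit(seq, "")[[1]]
  k <- round(q * length(ch))
  if (k > 0) {
    pos <- sample(length(ch), k)
    ch[pos] <- vapply(ch[pos], function(r) sample(setdiff(AAS, r), 1),
                      character(1))
  }
  paste(ch, collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Brute-force enumeration of ALL global alignments of two short
# sequences under affine gaps (gap of length L costs open + L * ext).
# Returns the maximum score and, among score-optimal alignments, the
# maximum number of identical aligned pairs. Exponential; lengths <= 6.
oracle_global_enumerate <- function(a, b, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- c(score = -Inf, id = -Inf)
  rec <- function(i, j, sc, id, last) {
    if (i > n && j > m) {
      if (sc > best["score"] ||
          (sc == best["score"] && id > best["id"]))
        best <<- c(score = sc, id = id)
      return(invisible())
    }
    if (i <= n && j <= m)
      rec(i + 1, j + 1, sc + blosum62[av[i], bv[j]],
          id + (av[i] == bv[j]), "M")
    if (i <= n)
      rec(i + 1, j, sc - (if (last == "X") ext else open + ext), id, "X")
    if (j <= m)
      rec(i, j + 1, sc - (if (last == "Y") ext else open + ext), id, "Y")
  }
  rec(1, 1, 0, 0, "start")
  best
}

# BFS connected components over an adjacency list; canonical form is a
# sorted list of sorted member vectors.
oracle_components <- function(ids, edges) {
  adj <- setNames(vector("list", length(ids)), ids)
  for (k in seq_len(NROW(edges))) {
    a <- edges$gene_a[k]; b <- edges$gene_b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(rep(FALSE, length(ids)), ids)
  comps <- list()
  for (s in ids) {
    if (seen[[s]]) next
    queue <- s; seen[[s]] <- TRUE; comp <- character(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (!seen[[w]]) { seen[[w]] <- TRUE; queue <- c(queue, w) }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps[order(vapply(comps, `[`, character(1), 1))]
}

# Canonical form of a pham partition for member-set comparison
# (numbers deliberately ignored).
canonical_partition <- function(db) {
  comps <- split(db$gene$gene_id, db$gene$pham_number)
  comps <- lapply(comps, sort)
  unname(comps[order(vapply(comps, `[`, character(1), 1))])
}
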