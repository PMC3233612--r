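# Deterministic fixture builders: phages assembled from protein lists
# with a test-local (single-codon) back-translation, so coordinates and
# sequences are fully predictable and independent of the package's own
# generator.

codon1 <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
            Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
            L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCG",
            S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

simple_backtranslate <- function(protein) {
  paste(codon1[strsplit(protein, "")[[1]]], collapse = "")
}

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Build a phage whose genes encode the given proteins, separated by
# fixed 40 bp spacers. strands recycles over genes.
make_protein_phage <- function(name, prots, strands = "forward") {
  strands <- rep(strands, length.out = length(prots))
  spacer <- strrep("ACGT", 10)
  pieces <- character(0); starts <- integer(0); stops <- integer(0)
  pos <- 0L
  for (i in seq_along(prots)) {
    pieces <- c(pieces, spacer); pos <- pos + nchar(spacer)
    cds <- paste0(simple_backtranslate(prots[i]), "TAA")
    ins <- if (strands[i] == "reverse") revcomp_str(cds) else cds
    pieces <- c(pieces, ins)
    starts <- c(starts, pos); stops <- c(stops, pos + nchar(ins))
    pos <- pos + nchar(ins)
  }
  pieces <- c(pieces, spacer)
  new_phage(name, paste(pieces, collapse = ""),
            data.frame(name = as.character(seq_along(prots)),
                       start = starts, stop = stops, strand = strands,
                       translation = prots, stringsAsFactors = FALSE))
}

build_db <- function(phages, config = comparison_config()) {
  db <- pham_db(config)
  for (p in phages) add_genome(db, p)
  db
}

# Two-family + bridging-fusion fixture used by the merge/split and
# circle tests: famA and famB are unrelated; the bridge genome carries
# a fusion of both ancestors.
bridge_fixture <- function(seed = 101, member_q = 0.05) {
  set.seed(seed)
  ancA <- random_protein_str(80)
  ancB <- random_protein_str(80)
  list(
    g1 = make_protein_phage("PhgA", c(mutate_protein_str(ancA, member_q))),
    g2 = make_protein_phage("PhgB", c(mutate_protein_str(ancB, member_q))),
    g3 = make_protein_phage("PhgFus", paste0(ancA, ancB)),
    ancA = ancA, ancB = ancB)
}
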