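Package: phamr
Title: Phage Gene Phamily Assembly and Comparative Genome Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assorts annotated bacteriophage protein-coding genes into
    phamilies ("phams") by all-versus-all pairwise comparison under dual
    thresholds (percent amino-acid identity or alignment E-value), and
    maintains pham identity under incremental genome addition and removal
    with merge, split, retirement and orpham-demotion semantics. Reads
    annotated genomes from GenBank flat files into an embedded JSON-backed
    relational store, ingests conserved-domain search results, computes
    whole-genome nucleotide local alignments, and renders comparative
    genome maps with nucleotide-similarity shading and phamily-circle
    gene-sharing diagrams as SVG. Includes a synthetic-cohort generator
    with planted gene families at controlled divergence so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    grDevices,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
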