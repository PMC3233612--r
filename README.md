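# phamr

Comparative bacteriophage genomics: assembling protein **phamilies
("phams")**, maintaining them as genomes come and go, and drawing the two
classic comparative representations — stacked genome maps with
nucleotide-similarity shading, and phamily circles.

## What it does

Phage genomes are mosaics: modules, often single genes, travel between
genomes by horizontal exchange, so genes in one genome have different
evolutionary histories. To analyse a set of phage genomes, `phamr`
compares every predicted protein against every other and groups genes
whose products are related into phams. A pair of genes is *related* when
it meets **either** of two thresholds:

* percent amino-acid identity on a global (end-to-end) alignment,
  `100 · identities / min(len_a, len_b)` ≥ **32.5%** — the min-length
  denominator keeps the cutoff independent of gene length; or
* local-alignment E-value ≤ **1e-50**, with
  `E = K · m · N · exp(−λ·S)` (Karlin–Altschul; `m` query length, `N`
  total residues in the database, `S` the Smith–Waterman score,
  λ = 0.267, K = 0.041 for BLOSUM62 with 11/1 affine gaps).

Phams are the **connected components** of the resulting graph, so
membership is transitive — a fusion protein related to two otherwise
unrelated families legitimately pulls them into one pham. A pham with a
single member is an **orpham**.

Pham identity is maintained incrementally. Adding a genome whose protein
bridges two phams **merges** them: both numbers are retired and a fresh
number is issued. Because E-values scale with database size, additions
can also drop borderline pairs below threshold and **split** phams (or
demote members to orphams); removals are symmetric. Retired numbers are
never reused, and every merge/split/retire/demotion is recorded in a
history table.

Around that core the package provides: GenBank flat-file input and
FASTA/TSV export, an embedded JSON-backed relational store, ingestion of
conserved-domain (RPS-BLAST tabular) hits with summary statistics,
seed-and-extend whole-genome nucleotide alignment (+1/−2 scoring,
E ≤ 1e-4) for the map shading, threshold sensitivity sweeps, SVG
rendering, and a synthetic-cohort generator with planted ground truth so
the whole pipeline is testable offline.

## Worked example

```r
library(phamr)

# a synthetic cohort: 3 genomes, 4 planted families, seeded
co <- generate_cohort(cohort_spec(n_phages = 3, genes_per_phage = 6,
                                  n_families = 4, seed = 7))
db <- pham_db()
for (p in co$phages) add_genome(db, p)
print(db)
#> pham database: 3 phages, 18 genes, 7 phams (3 orphams)

snapshot_stats(db)[c("total_genes", "total_phams", "n_orphams",
                     "mean_pham_size", "max_pham_size")]
#> $total_genes   [1] 18
#> $total_phams   [1] 7
#> $n_orphams     [1] 3
#> $mean_pham_size [1] 2.57
#> $max_pham_size [1] 4
```

18 genes fall into 7 phams: the four planted families (sizes 4, 4, 4, 3
— each genome carries 5 family slots cycling 4 families) plus one orpham
per genome for the planted orphan genes. Member-level detail relative to
a chosen reference gene:

```r
pham_detail(db, 1, "SynPhage01_1")
#>        gene_id percent_identity       evalue below_threshold
#> 1 SynPhage01_5         90.09901 1.343412e-58           FALSE
#> 2 SynPhage02_4         90.09901 1.343412e-58           FALSE
#> 3 SynPhage03_3         91.08911 1.754550e-58           FALSE
```

Sub-threshold rows (possible because membership is transitive) are
flagged by `below_threshold`. Maps and circles:

```r
writeLines(render_map(layout_map(db, db$phage$name)), "maps.svg", sep = "")
writeLines(render_circle(layout_circle(db, 1)), "circle.svg", sep = "")
```

The same workflow is scriptable from a shell via `inst/cli/phamr.R`
(`build`, `add`, `remove`, `stats`, `sweep`, `map`, `circle`,
`import-domains`).

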