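---
title: "Pham assembly: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pham assembly: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phamr)
```

## The model

Phage genomes evolve by horizontal exchange of modules that often
correspond to single genes, so a meaningful comparative unit is the
*gene family*, not the genome. `phamr` builds these families — phams —
from all-versus-all pairwise protein comparison under a **dual
threshold**: a pair of genes is related when its products reach either
32.5% identity on a global alignment or an E-value of 1e-50 on a local
alignment. Identity catches short, well-conserved proteins whose
E-values can never become small (E-values scale with alignment score,
which scales with length); the E-value channel catches long proteins
whose global identity is diluted below the cutoff but whose local
similarity is statistically overwhelming. Phams are the connected
components of the relationship graph.

Transitivity is a modelling decision, not an artefact: a fusion gene C
related to both A and B joins otherwise unrelated A and B into one
pham. That is biologically informative (it flags intragenic mosaicism)
but it also means thresholds must be strict enough that domain-level
promiscuity — e.g. a short shared domain linking a tape-measure family
to a lysin family — does not snowball into giant phams. The defaults
(32.5% / 1e-50) sit deliberately at the stringent end; the package
performs no automatic deconvolution of complex phams, leaving that to
curation.

### Percent identity

`percent_identity()` aligns end-to-end (Needleman–Wunsch, BLOSUM62,
affine gaps costing `11 + L` for a gap of length `L`) and divides the
identity count by the length of the *shorter* sequence. The min-length
denominator makes the value threshold-compatible across gene lengths
and treats a perfect fragment-within-fusion match as 100%. Among
score-optimal alignments the identity count is maximised, so the value
is a well-defined function of the two sequences, independent of
traceback tie-breaking — this is what lets the test suite check the
aligner against independent implementations exactly.

### E-values

`local_alignment_evalue()` converts a Smith–Waterman score `S` into
`E = K · m · N · exp(−λ·S)` with the published gapped BLOSUM62-11/1
parameters λ = 0.267, K = 0.041. `N` is the total residue count of the
proteins currently in the database, so *pass/fail flags depend on
database size*: raw scores are stored once, E-values are re-derived
whenever genomes are added or removed, and never re-aligned. For an
unordered gene pair the query length `m` is taken from the
lexicographically first gene id, which makes the stored edge
independent of comparison order.

### Nucleotide comparison

Whole-genome similarity, used for map shading, is a seed-and-extend
local aligner: exact 11-mer seeds, ungapped X-drop extension (default
drop 20) under +1/−2 scoring, both strands, ungapped Karlin–Altschul
statistics over the m×n search space. λ for +1/−2 at uniform base
composition is solved from `Σ pᵢpⱼ e^{λ·sᵢⱼ} = 1` (λ ≈ 1.3327;
`exp(λ)` is the positive root of `x² − 3x − 3`), K = 0.621, and only
matches with E ≤ 1e-4 are reported. An E-value threshold, rather than a
score threshold, keeps the reported-match rate on unrelated genomes at
the same fixed, low expectation regardless of genome length. Gapped
extension is deliberately out of scope: the shading visualisation needs
conserved spans and their boundaries, not base-perfect alignments, and
diverged neighbouring spans simply appear as separate quadrilaterals.

## Incremental maintenance

Pham numbers are identities, not indices. After any addition or
removal the components are re-formed from the re-thresholded edges and
numbers are assigned by a retention rule: **a component keeps a prior
number iff it contains every surviving member of exactly one prior pham
and no member of any other**. Everything else retires the touched
numbers and issues fresh ones from a monotonic counter. Consequences:

* a new protein bridging two phams merges them — both numbers retired,
  one fresh number, a `merge` event;
* a pham that merely gains members keeps its number (the retention rule
  is deliberately superset-tolerant — the alternative, retiring on
  every growth, would churn numbers without informational gain);
* database growth can push borderline E-values over threshold, so an
  *addition* can split a pham or demote a protein to an orpham; these
  record `split` and `demote_to_orpham` events;
* retired numbers never reappear (`pham_old` keeps the tombstones).

Member sets are insertion-order invariant — only the numbering depends
on history. The test suite asserts this by building the same cohort in
ten shuffled orders. Where the similarity of a new protein to more than
one pham is counted, any passing edge counts, whichever channel passed
it.

## Data store

The store is a set of relational tables (`phage`, `gene`, `scores`,
`pham`, `pham_history`, `pham_old`, `domain`) held in memory and
persisted as a single JSON file with full double precision (17
significant digits), giving bit-exact dump/reload round-trips. Raw
pairwise scores are permanent; thresholds and E-values are always
derived views, which is what makes `threshold_sweep()` free of
re-alignment. CLI commands load the store, operate, and rewrite the
file only on success, so every command is atomic.

## Synthetic cohorts

`generate_cohort()` is the package's source of ground truth. A family
is realised by mutating a random ancestor protein at per-site rate
`q = 1 − √(t/100)`, so two members, each diverged independently, meet
at pairwise identity ≈ `t`%. Realised identity is verified against the
first member with the package's own aligner and resampled (25 tries)
until within ±5 points of target. Divergence is substitution-only by
default: identity calibration stays analytic, and alignments of family
members are gapless, while the fused-gene constructs still exercise
gapped and partial-overlap alignment. DNA is back-translated with
translation table 11 using random synonymous codons; genes are placed
with 20–80 bp spacers, ~20% on the reverse strand; shared nucleotide
blocks are planted verbatim inside random background padding with their
coordinates recorded. The same seed yields byte-identical GenBank
files.

What the generator does *not* emulate: realistic codon usage and GC
skew, promoters/terminators, indel-rich divergence, repeat families, or
the skewed pham-size distributions of real collections. Passing tests
therefore demonstrate the correctness of the clustering, maintenance
and alignment machinery under controlled conditions — not field
performance on historical datasets, whose absolute numbers also depend
on the era-specific search tools used to produce them. For the same
reason the threshold sweep is asserted *qualitatively* (pham count
non-increasing, largest pham non-decreasing as thresholds loosen — a
structural property of single-linkage clustering) rather than against
any published absolute counts.

## Rendering

Maps: one baseline per genome, forward-strand genes boxed above and
reverse-strand below, fills from a fixed 32-colour palette cycled by
pham number (a pure function, so colours are stable across figures),
orphams forced white, pham number and member count labelled above each
box. Shading between vertically adjacent genomes is drawn per
nucleotide match, hue interpolated linearly from violet (270°) at E = 0
to red (0°) at the threshold over
`t = clamp((log10(max(E, 1e-180)) + 180)/(log10(thr) + 180), 0, 1)`;
the 1e-180 floor maps all effectively-zero E-values to violet.
Reverse-orientation matches are drawn as crossing quadrilaterals —
a convention choice, since the canonical figures never show one.
Genomes longer than `wrap_bp` wrap into tiers; shading is restricted to
matches that fall within one tier on both genomes.

Circles: all database phages on the circumference ordered by (cluster,
subcluster, name), labels bolded and annotated with member gene names
where the pham is present. For each genome pair holding related
members, a blue arc when the best pairwise identity passes the identity
threshold and a red arc when the best E-value passes the E-value
threshold, superimposed when both do (blue = identity channel is the
convention adopted here; the two published descriptions of the colour
assignment contradict each other, and we follow the body-text one).
Widths scale with identity (blue) and capped −log₁₀E (red) — the
specific scaling is this package's choice, as only "width reflects
strength" is canonical.

All SVG output is deterministic byte-for-byte for a given store, which
the test suite pins with golden files.

## Numerical and scale choices

* Alignment scores are exact DP results (Rcpp); the suite checks them
  against Biostrings' independent implementation on random pairs and
  against exhaustive alignment enumeration at tiny lengths.
* Test and acceptance problem sizes — cohorts of 2–5 genomes with 3–6
  genes each, 100–500 random graphs up to 200 nodes, 50 kb genomes for
  block recovery — are chosen so the full suite runs in about a minute
  while still exercising every code path; the quantities being checked
  (partition equality, monotonicity, coordinate error ≤ 5 bp) are
  scale-free properties.
* The degenerate inputs all have defined behaviour: empty stores and
  empty partitions give zero statistics, a genome with no CDS features
  parses to an empty gene table, an orpham's detail table and circle
  arc set are empty.

## Known limitations

External BLASTP/CLUSTALW are not invoked; the built-in aligners are the
normative backend, and adapter output would have to be mapped onto the
same edge contract. Profile/HMM searches, ortholog-aware deconvolution
of complex phams, multi-record GenBank files and gene calling are out
of scope. Conserved-domain hits are ingested from pre-computed tabular
searches only — hit counts are search-date and database-version
dependent, so the package never runs the search itself.
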