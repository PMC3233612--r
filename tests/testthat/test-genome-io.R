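test_that("complement CDS coordinates convert to 0-based half-open reverse", {
  set.seed(1)
  prot <- random_protein_str(83)
  # 252 bp span = 83 codons + stop, placed at GenBank 100..351
  genome <- paste0(paste(sample(c("A","C","G","T"), 99, TRUE), collapse = ""),
                   revcomp_str(paste0(simple_backtranslate(prot), "TAA")),
                   paste(sample(c("A","C","G","T"), 50, TRUE), collapse = ""))
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    sprintf("LOCUS       TestPhg           %d bp    DNA     linear   PHG 01-JAN-2000", nchar(genome)),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(genome)),
    "     CDS             complement(100..351)",
    '                     /gene="7"',
    paste0('                     /translation="', prot, '"'),
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(genome)),
    "//"), f)
  ph <- parse_genbank(f)
  expect_equal(nrow(ph$genes), 1)
  expect_equal(ph$genes$start, 99)
  expect_equal(ph$genes$stop, 351)
  expect_equal(ph$genes$strand, "reverse")
  expect_equal(ph$genes$translation, prot)
  expect_equal(ph$genes$name, "7")
})

test_that("written GenBank round-trips the gene table exactly", {
  set.seed(2)
  prots <- vapply(c(30, 45, 60), random_protein_str, character(1))
  ph <- make_protein_phage("RoundTrip", prots,
                           c("forward", "reverse", "forward"))
  f <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(ph, f)
  back <- parse_genbank(f)
  expect_equal(back$name, ph$name)
  expect_equal(back$length_bp, ph$length_bp)
  expect_equal(back$genome_sequence, ph$genome_sequence)
  expect_equal(back$genes[, c("gene_id", "name", "start", "stop",
                              "strand", "translation")],
               ph$genes[, c("gene_id", "name", "start", "stop",
                            "strand", "translation")])
})

test_that("file without CDS features yields an empty gene list", {
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       Bare           40 bp    DNA     linear   PHG 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     source          1..40",
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(strrep("ACGT", 10))),
    "//"), f)
  ph <- parse_genbank(f)
  expect_s3_class(ph, "phage")
  expect_equal(nrow(ph$genes), 0)
})

test_that("missing sequence is a hard error", {
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       NoSeq           0 bp    DNA     linear   PHG 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "//"), f)
  expect_error(parse_genbank(f), "ORIGIN|sequence")
  expect_error(parse_genbank(tempfile()), "no such file")
})

test_that("CDS lacking /translation is translated with table 11, warning", {
  prot <- "MKLVHEWQRTA"
  genome <- paste0("ACGTACGTAC", simple_backtranslate(prot), "TAA",
                   "ACGTACGTAC")
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    sprintf("LOCUS       NoTrans           %d bp    DNA     linear   PHG 01-JAN-2000", nchar(genome)),
    "FEATURES             Location/Qualifiers",
    sprintf("     CDS             11..%d", 10 + 3 * nchar(prot) + 3),
    '                     /gene="1"',
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(genome)),
    "//"), f)
  expect_warning(ph <- parse_genbank(f), "translation")
  expect_equal(ph$genes$translation, prot)
})

test_that("joined multi-interval CDS uses the outermost span with warning", {
  set.seed(3)
  prot <- random_protein_str(20)
  genome <- paste0(strrep("ACGT", 5), simple_backtranslate(prot), "TAA",
                   strrep("ACGT", 5))
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    sprintf("LOCUS       Joined           %d bp    DNA     linear   PHG 01-JAN-2000", nchar(genome)),
    "FEATURES             Location/Qualifiers",
    "     CDS             join(21..50,55..83)",
    '                     /gene="1"',
    paste0('                     /translation="', prot, '"'),
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(genome)),
    "//"), f)
  expect_warning(ph <- parse_genbank(f), "outermost")
  expect_equal(ph$genes$start, 20)
  expect_equal(ph$genes$stop, 83)
})

test_that("gene names fall back from /gene to /locus_tag to ordinal", {
  set.seed(4)
  prot <- random_protein_str(15)
  cds <- paste0(simple_backtranslate(prot), "TAA")
  genome <- paste0("ACGTACGTAC", cds, "AC", cds, "AC", cds, "ACGTACGTAC")
  n1 <- 10; s1 <- n1 + nchar(cds)
  n2 <- s1 + 2; s2 <- n2 + nchar(cds)
  n3 <- s2 + 2; s3 <- n3 + nchar(cds)
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    sprintf("LOCUS       Named           %d bp    DNA     linear   PHG 01-JAN-2000", nchar(genome)),
    "FEATURES             Location/Qualifiers",
    sprintf("     CDS             %d..%d", n1 + 1, s1),
    '                     /gene="geneA"',
    '                     /locus_tag="LT_1"',
    paste0('                     /translation="', prot, '"'),
    sprintf("     CDS             %d..%d", n2 + 1, s2),
    '                     /locus_tag="LT_2"',
    paste0('                     /translation="', prot, '"'),
    sprintf("     CDS             %d..%d", n3 + 1, s3),
    paste0('                     /translation="', prot, '"'),
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(genome)),
    "//"), f)
  ph <- parse_genbank(f)
  expect_equal(ph$genes$name, c("geneA", "LT_2", "3"))
})

test_that("ambiguity codes other than N are normalised to N with warning", {
  expect_warning(ph <- new_phage("Amb", "ACGTRYSWACGT"), "ambiguity")
  expect_equal(ph$genome_sequence, "ACGTNNNNACGT")
})

test_that("proteome FASTA export is ordered, round-trips, empty-safe", {
  set.seed(5)
  prots <- vapply(c(25, 40), random_protein_str, character(1))
  ph <- make_protein_phage("Prot", prots)
  fa <- export_proteome(ph)
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(fa, f, sep = "")
  aa <- Biostrings::readAAStringSet(f)
  expect_equal(names(aa), ph$genes$gene_id)
  expect_equal(unname(as.character(aa)), ph$genes$translation)
  expect_equal(export_proteome(make_protein_phage("E", character(0))), "")
})

test_that("gene table export carries the documented columns", {
  set.seed(6)
  ph <- make_protein_phage("Tab", c(random_protein_str(20)))
  tab <- export_gene_table(ph)
  expect_named(tab, c("phage", "gene", "start", "stop", "strand", "pham",
                      "translation_length"))
  expect_equal(tab$translation_length, 20)
})

test_that("coordinate conversion is a bijection", {
  set.seed(7)
  for (k in 1:20) {
    s1 <- sample(1:1e5, 1); e1 <- s1 + sample(0:999, 1)
    s0 <- s1 - 1; e0 <- e1
    expect_equal(c(s0 + 1, e0), c(s1, e1))
  }
})
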