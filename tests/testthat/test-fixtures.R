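test_that("the same seed yields byte-identical cohorts", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- cohort_spec(n_phages = 2, genes_per_phage = 5, n_families = 3,
                      seed = 7)
  c1 <- generate_cohort(spec, dir = d1)
  c2 <- generate_cohort(spec, dir = d2)
  for (k in seq_along(c1$files))
    expect_identical(readLines(c1$files[k]), readLines(c2$files[k]))
  expect_identical(c1$truth_genes, c2$truth_genes)
  # a different seed changes the output
  c3 <- generate_cohort(cohort_spec(n_phages = 2, genes_per_phage = 5,
                                    n_families = 3, seed = 8))
  expect_false(identical(c1$phages[[1]]$genome_sequence,
                         c3$phages[[1]]$genome_sequence))
})

test_that("cohort generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  generate_cohort(cohort_spec(n_phages = 1, genes_per_phage = 2,
                              n_families = 2, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("realised family identity is within 5 points of target", {
  co <- generate_cohort(cohort_spec(n_phages = 4, genes_per_phage = 3,
                                    n_families = 3,
                                    family_identity = c(90, 60, 40),
                                    orphan_fraction = 0, seed = 9))
  tg <- co$truth_genes
  genes <- do.call(rbind, lapply(co$phages, function(p) p$genes))
  for (fam in c("F1", "F2", "F3")) {
    ids <- tg$gene_id[tg$family == fam]
    target <- c(F1 = 90, F2 = 60, F3 = 40)[[fam]]
    tr <- genes$translation[match(ids, genes$gene_id)]
    first <- tr[1]
    for (other in tr[-1])
      expect_lte(abs(percent_identity(first, other) - target), 5)
  }
})

test_that("written cohorts parse back losslessly", {
  d <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(n_phages = 2, genes_per_phage = 4,
                                    n_families = 3, seed = 10), dir = d)
  for (k in seq_along(co$files)) {
    back <- parse_genbank(co$files[k])
    want <- co$phages[[k]]
    expect_identical(back$genome_sequence, want$genome_sequence)
    expect_equal(back$genes[, c("gene_id", "start", "stop", "strand",
                                "translation")],
                 want$genes[, c("gene_id", "start", "stop", "strand",
                                "translation")])
  }
  expect_true(file.exists(file.path(d, "truth_genes.tsv")))
  expect_true(file.exists(file.path(d, "cohort_spec.json")))
})

test_that("planted families are recovered exactly at default thresholds", {
  co <- generate_cohort(cohort_spec(n_phages = 3, genes_per_phage = 3,
                                    n_families = 3, family_identity = 90,
                                    orphan_fraction = 0, seed = 11))
  db <- build_db(co$phages)
  got <- canonical_partition(db)
  want <- lapply(split(co$truth_genes$gene_id, co$truth_genes$family), sort)
  want <- unname(want[order(vapply(want, `[`, character(1), 1))])
  expect_identical(got, want)
})

test_that("a fused gene merges its two families into one pham", {
  co <- generate_cohort(cohort_spec(n_phages = 3, genes_per_phage = 4,
                                    n_families = 4, orphan_fraction = 0,
                                    fused_gene_events = 1, seed = 12))
  db <- build_db(co$phages)
  tg <- co$truth_genes
  fused_id <- tg$gene_id[grepl("\\+", tg$family)]
  expect_equal(length(fused_id), 1)
  fams <- strsplit(tg$family[tg$gene_id == fused_id], "+", fixed = TRUE)[[1]]
  joined <- tg$gene_id[tg$family %in% c(fams, tg$family[tg$gene_id == fused_id])]
  pham_of_fused <- db$gene$pham_number[db$gene$gene_id == fused_id]
  members <- db$gene$gene_id[db$gene$pham_number == pham_of_fused]
  expect_setequal(members, joined)
})

test_that("infeasible specifications error out", {
  expect_error(cohort_spec(n_phages = 2, fused_gene_events = 1,
                           n_families = 1), "two families")
  expect_error(cohort_spec(protein_length = c(5, 4)))
  expect_error(cohort_spec(shared_blocks = list(list(length_bp = 5,
                                                     participants = 1))),
               ">= 20 bp")
  expect_error(cohort_spec(shared_blocks = list(list(length_bp = 100,
                                                     participants = 9))),
               "out of range")
})
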