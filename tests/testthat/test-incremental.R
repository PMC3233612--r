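# Incremental pham maintenance: merge, split, retirement, demotion and
# insertion-order invariance.

test_that("a bridging protein merges two phams, retiring both numbers", {
  fix <- bridge_fixture(seed = 51)
  db <- build_db(list(fix$g1, fix$g2))
  before <- sort(db$pham$number)
  expect_equal(length(before), 2)

  rep <- add_genome(db, fix$g3)
  expect_equal(nrow(db$pham), 1)
  expect_equal(db$pham$size, 3)
  expect_false(any(before %in% db$pham$number))
  expect_setequal(rep$retired, before)
  expect_equal(length(rep$merged), 1)
  expect_setequal(rep$merged[[1]]$old, before)
  expect_equal(rep$merged[[1]]$new, db$pham$number)
  ev <- db$pham_history
  expect_true(any(ev$event == "merge" &
                    ev$old_numbers == paste(before, collapse = ",")))
  expect_true(all(before %in% db$pham_old$number))
})

test_that("removing the bridge splits the pham with fresh numbers and demotions", {
  fix <- bridge_fixture(seed = 52)
  db <- build_db(list(fix$g1, fix$g2, fix$g3))
  merged_number <- db$pham$number
  expect_equal(length(merged_number), 1)

  rep <- remove_genome(db, "PhgFus")
  expect_equal(nrow(db$pham), 2)
  expect_true(all(db$pham$is_orpham))
  expect_false(merged_number %in% db$pham$number)
  expect_equal(length(rep$split), 1)
  expect_equal(rep$split[[1]]$old, merged_number)
  expect_setequal(rep$split[[1]]$new, db$pham$number)
  expect_true(any(db$pham_history$event == "split"))
  expect_true(any(db$pham_history$event == "demote_to_orpham"))
})

test_that("add then remove restores the member-set partition", {
  fix <- bridge_fixture(seed = 53)
  db <- build_db(list(fix$g1, fix$g2))
  before <- canonical_partition(db)
  add_genome(db, fix$g3)
  remove_genome(db, "PhgFus")
  expect_identical(canonical_partition(db), before)
  db_integrity_check(db)
})

test_that("an unrelated orpham addition disturbs no existing pham", {
  set.seed(54)
  anc <- random_protein_str(70)
  db <- build_db(list(
    make_protein_phage("P1", mutate_protein_str(anc, 0.05)),
    make_protein_phage("P2", mutate_protein_str(anc, 0.05))))
  before_phams <- db$pham
  rep <- add_genome(db, make_protein_phage("Lone", random_protein_str(60)))
  expect_equal(length(rep$retired), 0)
  expect_equal(length(rep$created), 1)
  expect_equal(rep$new_orphams, rep$created)
  expect_true(all(before_phams$number %in% db$pham$number))
})

test_that("duplicate additions and unknown removals are rejected", {
  fix <- bridge_fixture(seed = 55)
  db <- build_db(list(fix$g1))
  expect_error(add_genome(db, fix$g1), "already in database")
  expect_error(remove_genome(db, "Ghost"), "not in database")
})

test_that("retired numbers never reappear and the counter only grows", {
  fix <- bridge_fixture(seed = 56)
  db <- build_db(list(fix$g1, fix$g2))
  seen_retired <- integer(0)
  counters <- db$next_pham_number
  for (round in 1:3) {
    add_genome(db, fix$g3)
    seen_retired <- c(seen_retired, db$pham_old$number)
    counters <- c(counters, db$next_pham_number)
    expect_false(any(seen_retired %in% db$pham$number))
    remove_genome(db, "PhgFus")
    seen_retired <- c(seen_retired, db$pham_old$number)
    counters <- c(counters, db$next_pham_number)
    expect_false(any(seen_retired %in% db$pham$number))
    db_integrity_check(db)
  }
  expect_true(all(diff(counters) > 0))
})

test_that("a pham that only gains a member keeps its number", {
  set.seed(57)
  anc <- random_protein_str(70)
  db <- build_db(list(
    make_protein_phage("P1", mutate_protein_str(anc, 0.05)),
    make_protein_phage("P2", mutate_protein_str(anc, 0.05))))
  num <- db$pham$number[db$pham$size == 2]
  add_genome(db, make_protein_phage("P3", mutate_protein_str(anc, 0.05)))
  expect_true(num %in% db$pham$number)
  expect_equal(db$pham$size[db$pham$number == num], 3)
})

test_that("insertion order does not change the final member-set partition", {
  co <- generate_cohort(cohort_spec(n_phages = 3, genes_per_phage = 5,
                                    n_families = 3, seed = 58))
  reference <- NULL
  set.seed(580)
  for (k in 1:4) {
    ord <- sample(length(co$phages))
    db <- build_db(co$phages[ord])
    part <- canonical_partition(db)
    if (is.null(reference)) reference <- part
    expect_identical(part, reference)
  }
})
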