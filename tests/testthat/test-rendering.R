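# Rendering fixtures are rebuilt from the deterministic cohort seed 91,
# so SVG output can be compared byte-for-byte against stored goldens.

render_fixture_db <- function() {
  co <- generate_cohort(cohort_spec(n_phages = 3, genes_per_phage = 6,
                                    n_families = 4, seed = 91))
  build_db(co$phages)
}

test_that("map SVG matches the stored golden file byte for byte", {
  db <- render_fixture_db()
  svg <- render_map(layout_map(db, db$phage$name))
  golden <- test_path("golden-map.svg")
  if (!file.exists(golden)) {
    writeLines(svg, golden, sep = "")
    succeed("golden file generated")
  }
  expect_identical(svg, paste(readLines(golden), collapse = "\n") |> paste0("\n"))
})

test_that("circle SVG matches the stored golden file byte for byte", {
  db <- render_fixture_db()
  pn <- db$pham$number[db$pham$size == max(db$pham$size)][1]
  svg <- render_circle(layout_circle(db, pn))
  golden <- test_path("golden-circle.svg")
  if (!file.exists(golden)) {
    writeLines(svg, golden, sep = "")
    succeed("golden file generated")
  }
  expect_identical(svg, paste(readLines(golden), collapse = "\n") |> paste0("\n"))
})

test_that("rendering is deterministic and XML well-formed", {
  db <- render_fixture_db()
  lay <- layout_map(db, db$phage$name)
  expect_identical(render_map(lay), render_map(lay))
  expect_no_error(xml2::read_xml(render_map(lay)))
  pn <- db$pham$number[1]
  expect_no_error(xml2::read_xml(render_circle(layout_circle(db, pn))))
})

test_that("orpham boxes are white and strand picks the track", {
  db <- render_fixture_db()
  lay <- layout_map(db, db$phage$name)
  orpham_numbers <- db$pham$number[db$pham$is_orpham]
  orpham_genes <- db$gene$gene_id[db$gene$pham_number %in% orpham_numbers]
  expect_true(all(lay$genes$fill[lay$genes$gene_id %in% orpham_genes] == "#FFFFFF"))
  expect_true(all(lay$genes$fill[!lay$genes$gene_id %in% orpham_genes] != "#FFFFFF"))
  rows <- lay$rows
  for (k in seq_len(nrow(lay$genes))) {
    g <- lay$genes[k, ]
    base_y <- rows$y[rows$phage == g$phage][1]
    if (g$strand == "forward") expect_lt(g$y + g$h, base_y)
    else expect_gt(g$y, base_y)
  }
})

test_that("gene box widths equal span over scale and colours are pure functions", {
  db <- render_fixture_db()
  scale <- 40
  lay <- layout_map(db, db$phage$name, scale = scale)
  g <- db$gene[match(lay$genes$gene_id, db$gene$gene_id), ]
  expect_equal(lay$genes$w, (g$stop - g$start) / scale)
  expect_identical(pham_color(5), pham_color(5))
  expect_identical(pham_color(37), pham_color(5))  # 32-colour cycle
  expect_identical(pham_color(1, is_orpham = TRUE), "#FFFFFF")
})

test_that("two identical genomes shade the full span at the violet end", {
  set.seed(92)
  prot <- random_protein_str(300)
  p1 <- make_protein_phage("Twin1", prot)
  p2 <- make_protein_phage("Twin2", prot)
  db <- build_db(list(p1, p2))
  lay <- layout_map(db, c("Twin1", "Twin2"))
  expect_gte(nrow(lay$shading), 1)
  main <- lay$shading[which.max(lay$shading$ax1 - lay$shading$ax0), ]
  row <- lay$rows[lay$rows$phage == "Twin1", ]
  expect_equal(main$ax0, row$x0)
  expect_equal(main$ax1, row$x1)
  expect_identical(main$fill, grDevices::hsv(270 / 360, 1, 1))  # E = 0
})

test_that("reversing a two-genome stack mirrors the shading geometry", {
  co <- generate_cohort(cohort_spec(n_phages = 2, genes_per_phage = 5,
                                    n_families = 4, seed = 93))
  db <- build_db(co$phages)
  l1 <- layout_map(db, c("SynPhage01", "SynPhage02"))
  l2 <- layout_map(db, c("SynPhage02", "SynPhage01"))
  expect_equal(nrow(l1$shading), nrow(l2$shading))
  span_key <- function(s, swapped) {
    a <- paste(round(pmin(s$ax0, s$ax1), 6), round(pmax(s$ax0, s$ax1), 6))
    b <- paste(round(pmin(s$bx0, s$bx1), 6), round(pmax(s$bx0, s$bx1), 6))
    if (swapped) sort(paste(b, a, s$fill)) else sort(paste(a, b, s$fill))
  }
  expect_identical(span_key(l1$shading, FALSE), span_key(l2$shading, TRUE))
})

test_that("domain overlays appear as clipped yellow sub-boxes when enabled", {
  db <- render_fixture_db()
  g <- db$gene[1, ]
  db$domain <- data.frame(gene_id = g$gene_id, domain_accession = "pfam00001",
                          description = "test", query_start = 2L,
                          query_end = 12L, evalue = 1e-9,
                          stringsAsFactors = FALSE)
  lay <- layout_map(db, db$phage$name, show_domains = TRUE)
  expect_equal(nrow(lay$domains), 1)
  box <- lay$genes[lay$genes$gene_id == g$gene_id, ]
  expect_gte(lay$domains$x, box$x)
  expect_lte(lay$domains$x + lay$domains$w, box$x + box$w)
  expect_true(grepl("#FFD700", render_map(lay), fixed = TRUE))
})

test_that("phamily circles place every phage once and arc only related genomes", {
  fix <- bridge_fixture(seed = 94)
  extra <- make_protein_phage("PhgNone", random_protein_str(40))
  db <- build_db(list(fix$g1, fix$g2, fix$g3, extra))
  pn <- db$pham$number[db$pham$size == 3]
  lay <- layout_circle(db, pn)
  expect_equal(nrow(lay$nodes), 4)          # even genomes without the pham
  expect_equal(anyDuplicated(lay$nodes$phage), 0)
  pairs <- unique(paste(lay$arcs$phage_a, lay$arcs$phage_b))
  expect_setequal(pairs, c("PhgA PhgFus", "PhgB PhgFus"))  # never A-B direct
  # oracle: brute-force enumeration of passing genome pairs
  members <- db$gene[db$gene$pham_number == pn, ]
  e <- phamr:::passing_edges(db)
  e <- e[e$gene_a %in% members$gene_id & e$gene_b %in% members$gene_id, ]
  pha <- members$phage[match(e$gene_a, members$gene_id)]
  phb <- members$phage[match(e$gene_b, members$gene_id)]
  want <- unique(paste(pmin(pha, phb), pmax(pha, phb)))
  expect_setequal(pairs, want)
})

test_that("an orpham's circle has nodes but zero arcs", {
  fix <- bridge_fixture(seed = 95)
  db <- build_db(list(fix$g1, fix$g2))
  orph <- db$pham$number[db$pham$is_orpham][1]
  lay <- layout_circle(db, orph)
  expect_equal(nrow(lay$arcs), 0)
  expect_equal(nrow(lay$nodes), 2)
})

test_that("unknown phages and phams are layout errors", {
  db <- render_fixture_db()
  expect_error(layout_map(db, c("Nope")), "unknown phage")
  expect_error(layout_circle(db, 424242), "no such pham")
})
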