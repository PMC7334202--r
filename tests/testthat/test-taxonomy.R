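test_that("parse_taxdump reads the dump dialect and sets the index fields", {
  # minimal taxonomy: a single self-parented root
  idx <- parse_taxdump(
    dmp_line(1, "root", "", "scientific name"),
    dmp_line(1, 1, "no rank")
  )
  expect_equal(nrow(idx$nodes), 1)
  expect_equal(idx$max_tax_id, 1)
  expect_length(idx$minted_ids, 0)

  idx <- tiny_index()
  expect_equal(nrow(idx$nodes), 10)
  expect_equal(idx$max_tax_id, 104)
  # every species reaches the root in few steps
  for (id in c(101, 102, 103, 104)) {
    lin <- lineage(idx, id)
    expect_lte(nrow(lin), 5)
    expect_equal(lin$tax_id[nrow(lin)], 1)
  }
})

test_that("parse_taxdump rejects malformed and inconsistent dumps", {
  expect_error(
    parse_taxdump(dmp_line(1, "root", "", "scientific name"), "1\t|\t1\t|"),
    "line 1"
  )
  # duplicate tax_id
  nodes <- paste(dmp_line(1, 1, "no rank"), dmp_line(1, 1, "no rank"), sep = "\n")
  expect_error(
    parse_taxdump(dmp_line(1, "root", "", "scientific name"), nodes),
    "duplicate"
  )
  # node without a scientific name
  nodes <- paste(dmp_line(1, 1, "no rank"), dmp_line(2, 1, "genus"), sep = "\n")
  expect_error(
    parse_taxdump(dmp_line(1, "root", "", "scientific name"), nodes),
    "scientific name"
  )
})

test_that("resolve_name matches scientific names, then synonyms, never common names", {
  idx <- tiny_index()
  r <- resolve_name(idx, "Abra alba")
  expect_equal(r$tax_id, 101L)
  expect_equal(r$match_class, "exact_scientific")

  # synonymous species retain the correct TaxID
  r <- resolve_name(idx, "Abra ovata")
  expect_equal(r$tax_id, 102L)
  expect_equal(r$match_class, "synonym")

  # matching is case-insensitive with whitespace collapsed
  r <- resolve_name(idx, "  abra   ALBA ")
  expect_equal(r$tax_id, 101L)

  # common names are not eligible
  expect_equal(resolve_name(idx, "white abra")$match_class, "unresolved")
  r <- resolve_name(idx, "Nonexistens nemo")
  expect_true(is.na(r$tax_id))
  expect_equal(r$match_class, "unresolved")
})

test_that("homonyms resolve to the lowest TaxID, or via the focal lineage, and are flagged", {
  idx <- tiny_index()
  r <- resolve_name(idx, "Lupa lupa")
  expect_equal(r$tax_id, 103L) # lowest of {103, 104}
  expect_true(r$ambiguous)

  # focal taxon picks the candidate whose lineage intersects it
  r <- resolve_name(idx, "Lupa lupa", focal_tax_ids = 11L) # Lupidae
  expect_equal(r$tax_id, 104L)
  expect_true(r$ambiguous)
})

test_that("minting appends max_tax_id + 1, consecutively, nested under the genus", {
  idx <- tiny_index()
  m1 <- mint_taxid(idx, "Abra exemplum", 50L)
  expect_equal(m1$tax_id, 105L) # max was 104
  node <- m1$index$nodes[m1$index$nodes$tax_id == 105, ]
  expect_equal(node$parent_id, 50L)
  expect_equal(node$rank, "species")
  expect_equal(resolve_name(m1$index, "Abra exemplum")$tax_id, 105L)

  m2 <- mint_taxid(m1$index, "Abra secundum", 50L)
  expect_equal(m2$tax_id, 106L)
  expect_equal(m2$index$minted_ids, c(105L, 106L))
  expect_silent(validate_tax_index(m2$index))

  expect_error(mint_taxid(idx, "Abra tertium", 9999L), "not present")
  expect_error(mint_taxid(m1$index, "Abra exemplum", 50L), "already resolves")
})

test_that("lineage walks from the node to the root and errors on unknown ids", {
  idx <- tiny_index()
  lin <- lineage(idx, 101L)
  expect_equal(lin$rank, c("species", "genus", "family", "kingdom", "no rank"))
  expect_equal(lin$name, c("Abra alba", "Abra", "Abridae", "Animalia", "root"))
  expect_equal(nrow(lineage(idx, 1L)), 1)
  expect_error(lineage(idx, 777L), "unknown")

  # a minted species inherits its genus lineage
  m <- mint_taxid(idx, "Abra exemplum", 50L)
  expect_true(50L %in% lineage(m$index, m$tax_id)$tax_id)
})

test_that("expand_subtaxa lists descendants deterministically and reports unknowns", {
  idx <- tiny_index()
  sp <- expand_subtaxa(idx, "Abridae", rank_filter = "species")
  expect_equal(as.character(sp), c("Abra alba", "Abra nitida", "Lupa lupa"))

  # a leaf species has no proper descendants at species rank
  expect_length(expand_subtaxa(idx, "Abra alba", rank_filter = "species"), 0)

  # without a rank filter the focal node itself is part of the expansion
  all_abridae <- expand_subtaxa(idx, "Abridae")
  expect_true("Abridae" %in% all_abridae)

  out <- expand_subtaxa(idx, c("Abridae", "Atlantis"), rank_filter = "species")
  expect_equal(attr(out, "unresolved"), "Atlantis")
  expect_length(out, 3)
})

test_that("taxdump writing round-trips nodes, names and max_tax_id", {
  idx <- tiny_index()
  txt <- format_taxdump(idx)
  re <- parse_taxdump(txt$names, txt$nodes)
  expect_equal(dplyr::arrange(re$nodes, tax_id), dplyr::arrange(idx$nodes, tax_id))
  expect_setequal(
    paste(re$names$tax_id, re$names$name_txt, re$names$name_class),
    paste(idx$names$tax_id, idx$names$name_txt, idx$names$name_class)
  )
  expect_equal(re$max_tax_id, idx$max_tax_id)

  # one mint adds exactly one nodes line
  m <- mint_taxid(idx, "Abra exemplum", 50L)
  txt2 <- format_taxdump(m$index)
  n_lines <- function(x) length(strsplit(x, "\n")[[1]])
  expect_equal(n_lines(txt2$nodes), n_lines(txt$nodes) + 1)

  # a root-only index writes a single nodes line
  solo <- parse_taxdump(dmp_line(1, "root", "", "scientific name"),
                        dmp_line(1, 1, "no rank"))
  expect_equal(n_lines(format_taxdump(solo)$nodes), 1)
})

test_that("mint replay yields identical ids and preserves the tree invariant", {
  idx <- tiny_index()
  run <- function() {
    i <- idx
    ids <- integer()
    for (nm in c("Abra prima", "Abra secunda", "Lupus tertius")) {
      genus <- if (startsWith(nm, "Abra")) 50L else 51L
      m <- mint_taxid(i, nm, genus)
      i <- m$index
      ids <- c(ids, m$tax_id)
    }
    list(ids = ids, index = i)
  }
  a <- run(); b <- run()
  expect_equal(a$ids, b$ids)
  expect_equal(a$ids, 105:107)
  expect_silent(validate_tax_index(a$index))
})
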