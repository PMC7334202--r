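test_that("make_taxonomy builds the requested shape deterministically", {
  spec <- fixture_spec(seed = 1, n_families = 1, n_genera_per_family = 1,
                       n_species_per_genus = 2, synonym_fraction = 0,
                       contaminant_names = character())
  tx <- make_taxonomy(spec)
  idx <- parse_taxdump(tx$names, tx$nodes)
  # root, kingdom, family, genus, 2 species
  expect_equal(nrow(idx$nodes), 6)
  expect_equal(sum(idx$nodes$rank == "species"), 2)
  expect_equal(sum(idx$names$name_class == "synonym"), 0)

  expect_identical(make_taxonomy(spec), tx) # byte-identical on replay

  with_syn <- fixture_spec(seed = 1, synonym_fraction = 0.5)
  tx2 <- make_taxonomy(with_syn)
  idx2 <- parse_taxdump(tx2$names, tx2$nodes)
  expect_gt(sum(idx2$names$name_class == "synonym"), 0)
})

test_that("repository files respect overlap and planted-fact counts", {
  spec <- fixture_spec(seed = 2, overlap_fraction = 1, duplicate_fraction = 0,
                       novel_species_fraction = 0, n_unresolvable = 0,
                       synonym_fraction = 0, contaminant_names = character())
  repo <- make_repository_files(spec, make_taxonomy(spec))
  gb <- parse_genbank(repo$genbank)
  bold <- parse_bold_tsv(repo$bold)
  # full overlap: both repositories carry the same species
  expect_setequal(unique(gb$organism_name), unique(bold$organism_name))
  # no planted duplicates: dereplication is the identity on the merged set
  merged <- merge_records(gb, bold)
  expect_equal(nrow(dereplicate(merged)), nrow(merged))

  # planted mints are recovered exactly
  spec2 <- fixture_spec(seed = 3, novel_species_fraction = 0.3)
  repo2 <- make_repository_files(spec2, make_taxonomy(spec2))
  expect_gt(repo2$truth$n_expected_mints, 0)
  idx <- parse_taxdump(make_taxonomy(spec2)$names, make_taxonomy(spec2)$nodes)
  db <- dereplicate(filter_blacklist(
    merge_records(parse_genbank(repo2$genbank), parse_bold_tsv(repo2$bold)),
    read_blacklist(repo2$blacklist)
  ))
  res <- normalize_records(db, idx)
  expect_equal(nrow(res$report$minted_pairs), repo2$truth$n_expected_mints)
})

test_that("checklists cover the planted marine families and contaminants", {
  spec <- fixture_spec(seed = 4)
  tx <- make_taxonomy(spec)
  cl <- make_checklists(spec, tx)
  repo <- make_repository_files(spec, tx)
  expect_setequal(cl$marine$checklist$families, repo$truth$marine_families)
  expect_setequal(cl$contaminant$checklist$species, spec$contaminant_names)

  # all families marine -> every normalized record is flagged
  idx <- parse_taxdump(tx$names, tx$nodes)
  all_fams <- idx$names$name_txt[
    idx$names$tax_id %in% idx$nodes$tax_id[idx$nodes$rank == "family"] &
      idx$names$name_class == "scientific name"
  ]
  db <- normalize_records(
    dereplicate(merge_records(parse_genbank(repo$genbank),
                              parse_bold_tsv(repo$bold))),
    idx
  )
  flagged <- screen_marine(db$db, taxa_checklist("all", families = all_fams),
                           db$index)
  expect_true(all(has_flag(flagged, "marine")))

  # no marine families or species -> zero flags
  none <- screen_marine(db$db, taxa_checklist("none", families = "Nullidae"),
                        db$index)
  expect_equal(sum(has_flag(none, "marine")), 0)
})

test_that("write_fixture_dir emits a parseable, complete fixture directory", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(seed = 5)
  paths <- write_fixture_dir(spec, dir)
  expect_true(all(file.exists(paths)))
  idx <- read_taxdump(paths[["names"]], paths[["nodes"]])
  expect_gt(idx$max_tax_id, 1)
  truth <- readr::read_tsv(paths[["truth"]], col_types = "cd", progress = FALSE)
  expect_true(all(c("n_after_derep", "n_expected_mints", "n_marine_species")
                  %in% truth$metric))
})
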