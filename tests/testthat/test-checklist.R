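screened_fixture <- function(policy = "flag") {
  idx <- tiny_index()
  recs <- mk_records(
    c("R1", "R2", "R3", "R4"),
    c("Abra alba",   # family Abridae
      "Lupa lupa",   # homonym, resolves under Abridae (103)
      "Abra ovata",  # synonym -> 102, family Abridae
      "Lupus rufus"),# minted under Lupus, family Lupidae
    c("AAAA", "CCCC", "GGGG", "TTTT")
  )
  res <- normalize_records(recs, idx)
  list(db = res$db, index = res$index)
}

test_that("marine screening matches species lists and family lineages", {
  fx <- screened_fixture()

  # species on the list is flagged even when its family is not
  cl <- taxa_checklist("marine", species = "Lupus rufus")
  db <- screen_marine(fx$db, cl, fx$index)
  expect_equal(which(has_flag(db, "marine")), 4L)
  expect_equal(marine_summary(db)$n_marine_species, 1)

  # family membership flags all species in the family, including ones absent
  # from the species list (terrestrial relatives in marine families)
  cl <- taxa_checklist("marine", families = "Abridae")
  db <- screen_marine(fx$db, cl, fx$index)
  expect_equal(which(has_flag(db, "marine")), c(1L, 2L, 3L))

  # neither species nor family match -> unflagged
  cl <- taxa_checklist("marine", families = "Nullidae", species = "Nemo nemo")
  expect_equal(sum(has_flag(screen_marine(fx$db, cl, fx$index), "marine")), 0)
})

test_that("checklist TSVs parse with family and species ranks", {
  cl <- read_checklist("name\trank\nAbridae\tfamily\nLupus rufus\tspecies\n")
  expect_equal(cl$level, "mixed")
  expect_equal(cl$families, "Abridae")
  expect_equal(cl$species, "Lupus rufus")
  expect_error(read_checklist("name\trank\nAbra\tgenus\n"), "unknown checklist rank")
  expect_error(taxa_checklist("empty"), "at least one")
})

test_that("contaminant policies flag, remove, or merge-and-flag", {
  fx <- screened_fixture()
  cl <- taxa_checklist("contaminants", species = "Abra alba")

  flagged <- screen_contaminants(fx$db, cl, fx$index, policy = "flag")
  expect_equal(nrow(flagged$db), 4)
  expect_equal(sum(has_flag(flagged$db, "contaminant")), 1)
  expect_equal(flagged$report$n_records, 1)

  removed <- screen_contaminants(fx$db, cl, fx$index, policy = "remove")
  expect_equal(nrow(removed$db), 3)
  expect_false("Abra alba" %in% removed$db$canonical_name)
  # partition: removed + kept = input
  lg <- derivation_log(removed$db)
  rm_recs <- lg$details[[nrow(lg)]]$removed
  expect_setequal(c(removed$db$accession, rm_recs$accession), fx$db$accession)

  merged <- screen_contaminants(fx$db, cl, fx$index, policy = "merge")
  expect_equal(nrow(merged$db), 4)
  expect_equal(merged$db$accession[4], "R1") # contaminant appended last
  expect_true(has_flag(merged$db, "contaminant")[4])

  # empty-ish list: nothing matches, identity
  none <- screen_contaminants(fx$db, taxa_checklist("c", species = "Nemo nemo"),
                              fx$index, policy = "remove")
  expect_equal(nrow(none$db), 4)
})

test_that("screening never alters sequences or TaxIDs", {
  fx <- screened_fixture()
  cl <- taxa_checklist("marine", families = "Abridae")
  db <- screen_marine(fx$db, cl, fx$index)
  expect_equal(db$sequence, fx$db$sequence)
  expect_equal(db$tax_id, fx$db$tax_id)
  out <- screen_contaminants(db, taxa_checklist("c", species = "Abra alba"),
                             fx$index, policy = "flag")
  expect_equal(out$db$tax_id, fx$db$tax_id)
  # flags are independent: a record can be both marine and contaminant
  expect_true(has_flag(out$db, "marine")[1] && has_flag(out$db, "contaminant")[1])
})
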