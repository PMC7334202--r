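test_that("species_set keeps only unique, fully identified binomials", {
  idx <- tiny_index()
  recs <- mk_records(c("R1", "R2", "R3"),
                     c("Abra alba", "Abra alba", "Abra sp."),
                     c("AAAA", "CCCC", "GGGG"))
  db <- normalize_records(recs, idx)$db
  expect_equal(species_set(db), "Abra alba")
  expect_length(species_set(db[0, ]), 0)
  genus_only <- normalize_records(
    mk_records("R9", "Abra sp. B", "TTTT"), idx)$db
  expect_length(species_set(genus_only), 0)
})

test_that("composition percentages follow the printed-table formulas", {
  # % unique = unique species / total sequences; % marine = marine / unique
  s <- db_stats_from_counts(1491691, 71499, 19154)
  expect_equal(s$pct_unique_species, 4.79)
  expect_equal(s$pct_marine_species, 26.79)

  s <- db_stats_from_counts(5, 5, 5)
  expect_equal(s$pct_unique_species, 100.00)
  expect_equal(s$pct_marine_species, 100.00)

  # half-up rounding at the second decimal, where round() would go half-even
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(db_stats_from_counts(8000, 10, 0)$pct_unique_species, 0.13)
})

test_that("db_stats computed from records matches counting by hand", {
  idx <- tiny_index()
  recs <- mk_records(
    sprintf("R%d", 1:4),
    c("Abra alba", "Abra alba", "Abra nitida", "Abra sp."),
    c("AA", "CC", "GG", "TT")
  )
  db <- normalize_records(recs, idx)$db
  db <- screen_marine(db, taxa_checklist("m", species = "Abra alba"), idx)
  s <- db_stats(db)
  expect_equal(s$n_sequences, 4L)
  expect_equal(s$n_unique_species, 2L)
  expect_equal(s$pct_unique_species, 50.00)
  expect_equal(s$n_marine_species, 1L)
  expect_equal(s$pct_marine_species, 50.00)
})

test_that("jaccard_partition reproduces worked examples", {
  # identical sets: no dissimilarity, ratio undefined (0/0)
  p <- jaccard_partition(c("x", "y"), c("y", "x"))
  expect_equal(p$beta_jac, 0)
  expect_equal(p$beta_jtu, 0)
  expect_equal(p$beta_jne, 0)
  expect_true(is.na(p$beta_ratio))

  # pure nestedness: B strictly inside A
  p <- jaccard_partition(c("w", "x", "y", "z"), c("w", "x"))
  expect_equal(unlist(p[c("shared", "only_a", "only_b")]),
               c(shared = 2, only_a = 2, only_b = 0))
  expect_equal(p$beta_jac, 0.5)
  expect_equal(p$beta_jtu, 0)
  expect_equal(p$beta_jne, 0.5)
  expect_equal(p$beta_ratio, 1)

  # pure turnover: equal-size sets sharing one species
  p <- jaccard_partition(c("p", "q", "r"), c("r", "s", "t"))
  expect_equal(p$beta_jac, 0.8)
  expect_equal(p$beta_jtu, 0.8)
  expect_equal(p$beta_jne, 0)
  expect_equal(p$beta_ratio, 0)

  expect_error(jaccard_partition(character(), character()), "empty")
})

test_that("partition is symmetric, additive, and matches the brute-force oracle", {
  set.seed(101)
  universe <- paste0("sp", 1:30)
  for (i in 1:200) {
    A <- sample(universe, sample(0:20, 1))
    B <- sample(universe, sample(0:20, 1))
    if (length(A) + length(B) == 0) next
    p <- jaccard_partition(A, B)
    q <- jaccard_partition(B, A)
    o <- beta_oracle(A, B)
    expect_equal(c(p$shared, p$only_a, p$only_b), c(o$a, o$b, o$c))
    expect_equal(p$beta_jac, o$jac)
    expect_equal(p$beta_jtu, o$jtu)
    expect_equal(p$beta_jne, o$jne, tolerance = 1e-12)
    expect_equal(p$beta_jac, p$beta_jtu + p$beta_jne, tolerance = 1e-12)
    expect_equal(p$beta_jac, q$beta_jac)
    expect_equal(p$beta_jtu, q$beta_jtu)
  }
})

test_that("total Jaccard dissimilarity agrees with vegan", {
  skip_if_not_installed("vegan")
  set.seed(7)
  universe <- paste0("sp", 1:25)
  for (i in 1:25) {
    A <- sample(universe, sample(1:20, 1))
    B <- sample(universe, sample(1:20, 1))
    pa <- presence_absence(list(a = A, b = B))
    m <- t(as.matrix(pa[, c("a", "b")]))
    veg <- as.numeric(vegan::vegdist(m, method = "jaccard", binary = TRUE))
    expect_equal(jaccard_partition(A, B)$beta_jac, veg, tolerance = 1e-12)
  }
})

test_that("growing nestedness never increases turnover", {
  set.seed(5)
  A <- paste0("sp", 1:15)
  B <- paste0("sp", 1:3)
  prev <- jaccard_partition(A, B)$beta_jtu
  for (k in 4:15) {
    cur <- jaccard_partition(A, paste0("sp", 1:k))$beta_jtu
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("pairwise_beta builds symmetric matrices consistent with per-pair calls", {
  sets <- list(
    big = paste0("sp", 1:10),
    mid = paste0("sp", 1:6),
    small = paste0("sp", 1:3),
    other = paste0("tx", 1:6)
  )
  bm <- pairwise_beta(sets)
  for (nm in c("beta_jac", "beta_jtu", "beta_jne")) {
    expect_true(isSymmetric(bm[[nm]]))
    expect_equal(unname(diag(bm[[nm]])), rep(0, 4))
  }
  expect_true(all(is.na(diag(bm$beta_ratio))))
  p <- jaccard_partition(sets$big, sets$other)
  expect_equal(bm$beta_jac["big", "other"], p$beta_jac)
  expect_equal(bm$beta_jtu["other", "big"], p$beta_jtu)

  # nested chain: every pairwise difference is pure richness
  chain <- bm$beta_ratio[c("big", "mid", "small"), c("big", "mid", "small")]
  expect_equal(unname(chain[upper.tri(chain)]), rep(1, 3))

  # duplicate databases sit at zero dissimilarity
  bm2 <- pairwise_beta(list(a = sets$big, b = sets$big))
  expect_equal(bm2$beta_jac["a", "b"], 0)

  expect_error(pairwise_beta(list(a = sets$big)), "at least two")
})

test_that("interpret_ratio applies the 0.5 rule", {
  expect_equal(interpret_ratio(c(0.04, 0.06)),
               rep("turnover_dominated", 2))
  expect_equal(interpret_ratio(0.92), "nestedness_dominated")
  expect_equal(interpret_ratio(0.5), "balanced")
  expect_error(interpret_ratio(NA_real_), "undefined")
})

test_that("presence_absence marks each database's species", {
  pa <- presence_absence(list(a = c("X y", "Z w"), b = c("Z w")))
  expect_equal(pa$species, c("x y", "z w"))
  expect_equal(pa$a, c(1L, 1L))
  expect_equal(pa$b, c(0L, 1L))
})
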