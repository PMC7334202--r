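# Deterministic fixture generator: miniature taxonomies, GenBank flatfiles,
# BOLD TSVs, blacklists and checklists, with a truth table of every planted
# fact so the full pipeline can be verified exactly, offline.

#' Specification for a fixture dataset
#'
#' One seed drives all generation (sub-streams use `seed + k` offsets);
#' identical specs give byte-identical outputs. Duplicates, synonyms, novel
#' species (mint path) and unresolvable names (drop path) are planted, not
#' left to chance, so every expected count is exact.
#'
#' @param seed integer seed.
#' @param n_families,n_genera_per_family,n_species_per_genus taxonomy shape.
#' @param overlap_fraction fraction of species present in both simulated
#'   repositories (GenBank and BOLD).
#' @param duplicate_fraction fraction of records duplicated verbatim (identical
#'   sequence, new accession).
#' @param synonym_fraction fraction of species that carry a synonym name
#'   record; their BOLD rows use the synonym string.
#' @param novel_species_fraction fraction (of the species count) of extra
#'   records whose species is absent from the taxonomy but whose genus is
#'   known — the TaxID-minting path.
#' @param n_unresolvable number of planted records that cannot be resolved at
#'   all (unknown genus) — the drop path.
#' @param contaminant_names binomials added to the taxonomy under their own
#'   non-marine families and listed on the contaminant checklist.
#' @param seq_length sequence length in bases (random over ACGT; at 120 bp
#'   chance collisions are negligible, and duplicates are planted by copying).
#' @return a validated `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_families = 3L,
                         n_genera_per_family = 2L,
                         n_species_per_genus = 3L,
                         overlap_fraction = 0.5,
                         duplicate_fraction = 0.15,
                         synonym_fraction = 0.2,
                         novel_species_fraction = 0.15,
                         n_unresolvable = 2L,
                         contaminant_names = "Homo sapiens",
                         seq_length = 120L) {
  spec <- list(
    seed = as.integer(seed),
    n_families = as.integer(n_families),
    n_genera_per_family = as.integer(n_genera_per_family),
    n_species_per_genus = as.integer(n_species_per_genus),
    overlap_fraction = overlap_fraction,
    duplicate_fraction = duplicate_fraction,
    synonym_fraction = synonym_fraction,
    novel_species_fraction = novel_species_fraction,
    n_unresolvable = as.integer(n_unresolvable),
    contaminant_names = contaminant_names,
    seq_length = as.integer(seq_length)
  )
  fr <- c(spec$overlap_fraction, spec$duplicate_fraction,
          spec$synonym_fraction, spec$novel_species_fraction)
  stopifnot(all(fr >= 0 & fr <= 1),
            spec$n_families >= 1, spec$n_genera_per_family >= 1,
            spec$n_species_per_genus >= 1, spec$seq_length >= 1,
            spec$n_unresolvable >= 0)
  structure(spec, class = "fixture_spec")
}

fx_syllables <- c("ba", "ce", "di", "fo", "gu", "la", "mi", "no", "pe", "ra",
                  "su", "to", "ve", "xa", "zo")

fx_name <- function(n_syll, rng_n = 1) {
  syl <- sample(fx_syllables, n_syll, replace = TRUE)
  paste(syl, collapse = "")
}

fx_unique_names <- function(n, n_syll, capitalize = FALSE, taken = character()) {
  out <- character(0)
  while (length(out) < n) {
    nm <- fx_name(n_syll)
    if (capitalize) nm <- paste0(toupper(substr(nm, 1, 1)), substr(nm, 2, nchar(nm)))
    if (!nm %in% c(out, taken)) out <- c(out, nm)
  }
  out
}

fx_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a miniature taxonomy dump
#'
#' Shape: root, one kingdom, `n_families` families each with
#' `n_genera_per_family` genera of `n_species_per_genus` species, plus one
#' family/genus/species triple per contaminant binomial. A
#' `synonym_fraction` of the non-contaminant species carry an extra
#' synonym-class name record. Byte-identical for identical specs.
#'
#' @param spec a `fixture_spec`.
#' @return list (`names`, `nodes`) of taxdump text, parseable by
#'   [parse_taxdump()].
#' @export
make_taxonomy <- function(spec) {
  withr::with_seed(spec$seed, {
    nodes <- tibble(tax_id = c(1L, 2L), parent_id = c(1L, 1L),
                    rank = c("no rank", "kingdom"))
    names_tbl <- tibble(tax_id = c(1L, 2L),
                        name_txt = c("root", "Eukaryota"),
                        name_class = "scientific name")
    next_id <- 3L
    add_node <- function(parent, rank, name, class = "scientific name") {
      id <- next_id
      next_id <<- next_id + 1L
      nodes <<- bind_rows(nodes, tibble(tax_id = id, parent_id = parent, rank = rank))
      names_tbl <<- bind_rows(names_tbl,
                              tibble(tax_id = id, name_txt = name, name_class = class))
      id
    }

    fam_names <- paste0(fx_unique_names(spec$n_families, 3, capitalize = TRUE), "idae")
    taken <- character()
    species_rows <- list()
    for (f in seq_len(spec$n_families)) {
      fam_id <- add_node(2L, "family", fam_names[f])
      gen_names <- fx_unique_names(spec$n_genera_per_family, 2, capitalize = TRUE,
                                   taken = taken)
      taken <- c(taken, gen_names)
      for (g in seq_along(gen_names)) {
        gen_id <- add_node(fam_id, "genus", gen_names[g])
        epithets <- fx_unique_names(spec$n_species_per_genus, 3, taken = taken)
        taken <- c(taken, epithets)
        for (s in seq_along(epithets)) {
          sp_name <- paste(gen_names[g], epithets[s])
          sp_id <- add_node(gen_id, "species", sp_name)
          species_rows[[length(species_rows) + 1]] <-
            tibble(tax_id = sp_id, name = sp_name, genus = gen_names[g],
                   family = fam_names[f], contaminant = FALSE)
        }
      }
    }

    # contaminant taxa live under their own (non-marine) families
    for (cn in spec$contaminant_names) {
      words <- strsplit(stringr::str_squish(cn), " ")[[1]]
      fam_id <- add_node(2L, "family", paste0(words[1], "idae"))
      gen_id <- add_node(fam_id, "genus", words[1])
      sp_id <- add_node(gen_id, "species", cn)
      species_rows[[length(species_rows) + 1]] <-
        tibble(tax_id = sp_id, name = cn, genus = words[1],
               family = paste0(words[1], "idae"), contaminant = TRUE)
    }

    species <- bind_rows(species_rows)

    # plant synonyms on the first k non-contaminant species (tax_id order)
    focal <- species[!species$contaminant, ]
    k <- round(spec$synonym_fraction * nrow(focal))
    synonyms <- tibble(tax_id = integer(), name_txt = character())
    if (k > 0) {
      syn_for <- focal[seq_len(k), ]
      syn_names <- paste(syn_for$genus,
                         paste0(sub("^.* ", "", syn_for$name), "oides"))
      names_tbl <- bind_rows(names_tbl,
                             tibble(tax_id = syn_for$tax_id, name_txt = syn_names,
                                    name_class = "synonym"))
      synonyms <- tibble(tax_id = syn_for$tax_id, name_txt = syn_names)
    }

    idx <- new_tax_index(nodes, mutate(names_tbl, name_key = name_key(.data$name_txt)))
    dump <- format_taxdump(idx)
    structure(list(names = dump$names, nodes = dump$nodes),
              class = "fixture_taxonomy")
  })
}

fx_genbank_entry <- function(accession, organism, sequence) {
  plain <- strip_version(accession)
  seq_lines <- character()
  for (i in seq(1, nchar(sequence), by = 60)) {
    chunk <- substr(sequence, i, min(i + 59, nchar(sequence)))
    grp <- gsub("(.{10})", "\\1 ", tolower(chunk))
    seq_lines <- c(seq_lines, sprintf("%9d %s", i, sub(" $", "", grp)))
  }
  paste(c(
    sprintf("LOCUS       %s  %d bp    DNA     linear   INV 01-JAN-2019",
            plain, nchar(sequence)),
    "DEFINITION  cytochrome oxidase subunit 1 (COI) gene, partial cds.",
    sprintf("ACCESSION   %s", plain),
    sprintf("VERSION     %s", accession),
    sprintf("SOURCE      %s", organism),
    sprintf("  ORGANISM  %s", organism),
    "            Eukaryota.",
    "ORIGIN",
    seq_lines,
    "//"
  ), collapse = "\n")
}

#' Generate miniature repository files with a planted truth table
#'
#' Builds a GenBank flatfile and a BOLD-style TSV over the taxonomy from
#' [make_taxonomy()]: species split between the two repositories with
#' `overlap_fraction` shared; BOLD rows use the planted synonym names where
#' one exists; novel species (mint path), unresolvable records (drop path),
#' verbatim duplicates and a two-entry blacklist are planted. The truth table
#' is computed from the generation plan by set logic, independently of the
#' pipeline implementation.
#'
#' @param spec a `fixture_spec`.
#' @param taxonomy result of [make_taxonomy(spec)][make_taxonomy].
#' @return list: `genbank` (flatfile text), `bold` (TSV text), `blacklist`
#'   (text), `truth` (named list of expected counts), `plan` (per-record plan
#'   tibble, for debugging).
#' @export
make_repository_files <- function(spec, taxonomy) {
  idx <- parse_taxdump(taxonomy$names, taxonomy$nodes)
  sci <- idx$names[idx$names$name_class == "scientific name", ]
  syn <- idx$names[idx$names$name_class == "synonym", ]
  sp_nodes <- idx$nodes[idx$nodes$rank == "species", ]
  species <- tibble(
    tax_id = sp_nodes$tax_id,
    name = sci$name_txt[match(sp_nodes$tax_id, sci$tax_id)],
    genus_id = sp_nodes$parent_id
  ) %>% arrange(.data$tax_id)
  species$genus <- sci$name_txt[match(species$genus_id, sci$tax_id)]
  fam_id <- idx$nodes$parent_id[match(species$genus_id, idx$nodes$tax_id)]
  species$family <- sci$name_txt[match(fam_id, sci$tax_id)]
  species$synonym <- syn$name_txt[match(species$tax_id, syn$tax_id)]
  species$contaminant <- name_key(species$name) %in% name_key(spec$contaminant_names)

  # marine rule shared with make_checklists(): first half of the
  # non-contaminant families, in tax_id order
  noncont_fams <- unique(species$family[!species$contaminant])
  marine_fams <- noncont_fams[seq_len(ceiling(length(noncont_fams) / 2))]

  withr::with_seed(spec$seed + 1L, {
    focal <- species[!species$contaminant, ]
    n <- nrow(focal)
    n_shared <- round(spec$overlap_fraction * n)
    membership <- rep("shared", n)
    if (n_shared < n) {
      rest <- seq(n_shared + 1, n)
      membership[rest] <- rep(c("gb_only", "bold_only"), length.out = length(rest))
    }
    focal$membership <- membership

    plan <- list()
    gb_i <- 0L
    bold_i <- 0L
    add <- function(file, organism, resolve_as, species_key, sequence = NULL,
                    dup_of = NA_character_, family = NA_character_,
                    contaminant = FALSE) {
      if (file == "genbank") {
        gb_i <<- gb_i + 1L
        acc <- sprintf("FXGB%04d.1", gb_i)
      } else {
        bold_i <<- bold_i + 1L
        acc <- sprintf("FXBOLD%04d", bold_i)
      }
      plan[[length(plan) + 1]] <<- tibble(
        accession = acc, file = file, organism = organism,
        resolve_as = resolve_as, species_key = species_key,
        sequence = sequence %||% fx_sequence(spec$seq_length),
        dup_of = dup_of, family = family, contaminant = contaminant
      )
      acc
    }

    # species_key is keyed on the organism string as planted (the synonym
    # spelling for synonym records), because downstream species identity is
    # the binomial string a record carries, not the resolved TaxID
    for (i in seq_len(n)) {
      row <- focal[i, ]
      if (row$membership %in% c("shared", "gb_only")) {
        add("genbank", row$name, "exact", name_key(row$name), family = row$family)
      }
      if (row$membership %in% c("shared", "bold_only")) {
        org <- if (!is.na(row$synonym)) row$synonym else row$name
        add("bold", org, if (!is.na(row$synonym)) "synonym" else "exact",
            name_key(org), family = row$family)
      }
    }
    for (cn in spec$contaminant_names) {
      crow <- species[name_key(species$name) == name_key(cn), ][1, ]
      add("genbank", crow$name, "exact", name_key(crow$name),
          family = crow$family, contaminant = TRUE)
    }

    # novel species: known genus, unknown epithet -> mint path
    n_novel <- round(spec$novel_species_fraction * n)
    if (n_novel > 0) {
      genera <- rep(unique(focal$genus), length.out = n_novel)
      for (j in seq_len(n_novel)) {
        # epithets must be clean lowercase words or the mint path is not taken
        suffix <- paste0(letters[(j - 1) %/% 26 + 1], letters[(j - 1) %% 26 + 1])
        nm <- paste(genera[j], paste0("novellus", suffix))
        fam <- focal$family[match(genera[j], focal$genus)]
        add("genbank", nm, "mint", name_key(nm), family = fam)
      }
    }

    # unresolvable records: unknown genus -> drop path
    if (spec$n_unresolvable > 0) {
      for (j in seq_len(spec$n_unresolvable)) {
        nm <- sprintf("Zzyzxus incognitus%02d", j)
        add("bold", nm, "drop", name_key(nm))
      }
    }

    base <- bind_rows(plan)

    # planted duplicates: copy the sequence of the first d resolvable records
    # into new records appended to the BOLD file (same organism, new accession)
    d <- round(spec$duplicate_fraction * nrow(base))
    donors <- utils::head(base[base$resolve_as != "drop", ], d)
    if (nrow(donors) > 0) {
      dups <- donors
      dups$accession <- sprintf("FXBOLD%04d", bold_i + seq_len(nrow(donors)))
      dups$file <- "bold"
      dups$dup_of <- donors$accession
      plan <- bind_rows(base, dups)
    } else {
      plan <- base
    }

    # blacklist: up to two non-duplicated GenBank records of species that also
    # appear under the same name in BOLD, so the species survives the removal
    bl_pool <- plan$accession[plan$file == "genbank" & plan$resolve_as == "exact" &
                                !plan$contaminant & is.na(plan$dup_of) &
                                !plan$accession %in% plan$dup_of &
                                plan$species_key %in%
                                  plan$species_key[plan$file == "bold"]]
    blacklisted <- utils::head(bl_pool, 2)
    plan$blacklisted <- plan$accession %in% blacklisted

    # ---- truth table, by set logic on the plan ----
    surv <- plan[!plan$blacklisted, ]
    # merged order: genbank block then bold block, each in file order
    surv <- bind_rows(surv[surv$file == "genbank", ], surv[surv$file == "bold", ])
    kept <- surv[!duplicated(toupper(surv$sequence)), ]
    marine_keys <- unique(kept$species_key[!is.na(kept$family) &
                                             kept$family %in% marine_fams &
                                             kept$resolve_as != "drop"])
    truth <- list(
      n_genbank_records = sum(plan$file == "genbank"),
      n_bold_records = sum(plan$file == "bold"),
      n_blacklisted = length(blacklisted),
      n_merged = nrow(surv),
      n_after_derep = nrow(kept),
      n_duplicate_clusters = sum(table(toupper(surv$sequence)) > 1),
      n_exact = sum(kept$resolve_as == "exact"),
      n_synonym = sum(kept$resolve_as == "synonym"),
      n_minted = sum(kept$resolve_as == "mint"),
      n_expected_mints = dplyr::n_distinct(kept$species_key[kept$resolve_as == "mint"]),
      n_dropped = sum(kept$resolve_as == "drop"),
      n_normalized = sum(kept$resolve_as != "drop"),
      n_marine_species = length(marine_keys),
      n_contaminant_records = sum(kept$contaminant & kept$resolve_as != "drop"),
      marine_families = marine_fams
    )

    # ---- render files ----
    gb <- plan[plan$file == "genbank", ]
    genbank_text <- paste0(paste(
      purrr::pmap_chr(list(gb$accession, gb$organism, gb$sequence), fx_genbank_entry),
      collapse = "\n"
    ), "\n")

    bold <- plan[plan$file == "bold", ]
    bold_text <- paste0(
      "processid\tspecies_name\tmarkercode\tnucleotides\n",
      if (nrow(bold) > 0) paste(sprintf("%s\t%s\tCOI-5P\t%s", bold$accession,
                                        bold$organism, bold$sequence),
                                collapse = "\n"),
      if (nrow(bold) > 0) "\n" else ""
    )

    blacklist_text <- paste0(
      "# fixture blacklist\n",
      if (length(blacklisted) > 0) paste0(paste(blacklisted, collapse = "\n"), "\n") else ""
    )

    list(genbank = genbank_text, bold = bold_text, blacklist = blacklist_text,
         truth = truth, plan = plan)
  })
}

#' Generate marine and contaminant checklists for a fixture
#'
#' The marine checklist lists the first half (ceiling) of the non-contaminant
#' families in TaxID order — the same deterministic rule
#' [make_repository_files()] uses when computing the expected marine counts.
#' The contaminant checklist lists `spec$contaminant_names` at species rank.
#'
#' @param spec a `fixture_spec`.
#' @param taxonomy result of [make_taxonomy()].
#' @return list: `marine` and `contaminant`, each a list with `text` (TSV) and
#'   the parsed `checklist`.
#' @export
make_checklists <- function(spec, taxonomy) {
  idx <- parse_taxdump(taxonomy$names, taxonomy$nodes)
  sci <- idx$names[idx$names$name_class == "scientific name", ]
  cont_genera <- vapply(strsplit(spec$contaminant_names, " "), `[`, "", 1)
  cont_fams <- paste0(cont_genera, "idae")
  fams <- idx$nodes[idx$nodes$rank == "family", ] %>% arrange(.data$tax_id)
  fam_names <- sci$name_txt[match(fams$tax_id, sci$tax_id)]
  noncont <- fam_names[!fam_names %in% cont_fams]
  marine_fams <- noncont[seq_len(ceiling(length(noncont) / 2))]

  marine_text <- paste0(
    "name\trank\n",
    paste(sprintf("%s\tfamily", marine_fams), collapse = "\n"), "\n"
  )
  cont_text <- paste0(
    "name\trank\n",
    paste(sprintf("%s\tspecies", spec$contaminant_names), collapse = "\n"), "\n"
  )
  list(
    marine = list(text = marine_text,
                  checklist = read_checklist(marine_text, "marine")),
    contaminant = list(text = cont_text,
                       checklist = read_checklist(cont_text, "contaminants"))
  )
}

#' Write a complete fixture directory
#'
#' Emits names.dmp/nodes.dmp, genbank.gb, bold.tsv, blacklist.txt, the two
#' checklist TSVs and truth_table.tsv under `dir`.
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory.
#' @return invisibly, a named vector of file paths.
#' @export
write_fixture_dir <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  taxonomy <- make_taxonomy(spec)
  repo <- make_repository_files(spec, taxonomy)
  cl <- make_checklists(spec, taxonomy)
  paths <- c(
    names = file.path(dir, "names.dmp"),
    nodes = file.path(dir, "nodes.dmp"),
    genbank = file.path(dir, "genbank.gb"),
    bold = file.path(dir, "bold.tsv"),
    blacklist = file.path(dir, "blacklist.txt"),
    marine = file.path(dir, "marine_checklist.tsv"),
    contaminant = file.path(dir, "contaminant_checklist.tsv"),
    truth = file.path(dir, "truth_table.tsv")
  )
  writeLines(sub("\n$", "", taxonomy$names), paths[["names"]])
  writeLines(sub("\n$", "", taxonomy$nodes), paths[["nodes"]])
  writeLines(sub("\n$", "", repo$genbank), paths[["genbank"]])
  writeLines(sub("\n$", "", repo$bold), paths[["bold"]])
  writeLines(sub("\n$", "", repo$blacklist), paths[["blacklist"]])
  writeLines(sub("\n$", "", cl$marine$text), paths[["marine"]])
  writeLines(sub("\n$", "", cl$contaminant$text), paths[["contaminant"]])
  truth <- repo$truth
  scalar <- truth[vapply(truth, function(v) length(v) == 1 && is.numeric(v), logical(1))]
  readr::write_tsv(tibble(metric = names(scalar), value = unlist(scalar)),
                   paths[["truth"]], progress = FALSE)
  invisible(paths)
}
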