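# Checklist screening: marine membership and contaminant flagging against
# user-supplied family/species lists (WoRMS-style crosswalk by name, not TaxID,
# because external checklists and the NCBI taxonomy disagree on identifiers).

#' Construct a taxa checklist
#'
#' @param name checklist label.
#' @param families character vector of family names (may be empty).
#' @param species character vector of species binomials (may be empty).
#' @return object of class `taxa_checklist` with `level` derived from which
#'   sets are non-empty (`family`, `species`, or `mixed`).
#' @export
taxa_checklist <- function(name, families = character(), species = character()) {
  families <- unique(stringr::str_squish(families))
  species <- unique(stringr::str_squish(species))
  families <- families[nzchar(families)]
  species <- species[nzchar(species)]
  if (length(families) + length(species) == 0) {
    stop("a checklist needs at least one family or species")
  }
  level <- if (length(families) > 0 && length(species) > 0) "mixed"
  else if (length(families) > 0) "family" else "species"
  structure(
    list(name = name, families = families, species = species, level = level),
    class = "taxa_checklist"
  )
}

#' @export
print.taxa_checklist <- function(x, ...) {
  cat(sprintf("<taxa_checklist> '%s' (%s): %d families, %d species\n",
              x$name, x$level, length(x$families), length(x$species)))
  invisible(x)
}

#' Read a checklist TSV
#'
#' Expects columns `name` and `rank` (values `family` or `species`).
#' @param text TSV contents.
#' @param name checklist label.
#' @return a `taxa_checklist`.
#' @export
read_checklist <- function(text, name = "checklist") {
  df <- readr::read_tsv(I(text), col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("name", "rank") %in% names(df))) {
    stop("checklist TSV needs columns 'name' and 'rank'")
  }
  bad <- setdiff(unique(df$rank), c("family", "species"))
  if (length(bad) > 0) {
    stop(sprintf("unknown checklist rank(s): %s", paste(bad, collapse = ", ")))
  }
  taxa_checklist(name,
                 families = df$name[df$rank == "family"],
                 species = df$name[df$rank == "species"])
}

#' Family name in each record's lineage
#' @keywords internal
family_of_taxids <- function(index, tax_ids) {
  uniq <- unique(tax_ids[!is.na(tax_ids)])
  fam <- vapply(uniq, function(id) {
    lin <- lineage(index, id)
    f <- lin$name[lin$rank == "family"]
    if (length(f) == 0) NA_character_ else f[1]
  }, character(1))
  fam[match(tax_ids, uniq)]
}

#' Flag marine taxa against a checklist
#'
#' A record is marine when its canonical species binomial is on the species
#' list, or any family in its lineage is on the family list (family matching
#' deliberately also catches terrestrial relatives inside marine families, so
#' genus/family-level assignment stays possible when no marine congener has
#' been sequenced). Matching is name-based and case-insensitive. Records whose
#' lineage has no family rank are evaluated on the species list only and
#' counted in a `no_family` tally.
#'
#' @param db normalized record tibble (TaxIDs present).
#' @param checklist a `taxa_checklist`.
#' @param index the `tax_index` the records were normalized against.
#' @return the db with the `"marine"` flag set; summary counts in the
#'   derivation log and via [marine_summary()].
#' @export
screen_marine <- function(db, checklist, index) {
  fam <- family_of_taxids(index, db$tax_id)
  sp_hit <- !is.na(db$canonical_name) & db$level == "species" &
    name_key(db$canonical_name) %in% name_key(checklist$species)
  fam_hit <- !is.na(fam) & name_key(fam) %in% name_key(checklist$families)
  marine <- sp_hit | fam_hit
  db$flags <- add_flag(db$flags, marine, "marine")
  summary <- list(
    n_flagged_records = sum(marine),
    n_marine_species = dplyr::n_distinct(
      name_key(db$canonical_name[marine & db$level == "species"])),
    n_no_family = sum(is.na(fam))
  )
  log_step(with_refdb_attrs(db, db), "screen_marine", nrow(db), nrow(db),
           details = list(summary))
}

#' Summary of the last marine screen
#' @param db a marine-screened refdb.
#' @return list (`n_flagged_records`, `n_marine_species`, `n_no_family`) or NULL.
#' @export
marine_summary <- function(db) {
  lg <- derivation_log(db)
  at <- which(lg$step == "screen_marine")
  if (length(at) == 0) return(NULL)
  lg$details[[max(at)]]
}

#' Screen contaminants with a flag/remove/merge policy
#'
#' A record matches when its binomial is on the contaminant species list or
#' its lineage family is on the family list. Policies: `flag` only marks
#' matching records; `remove` drops them (the removed records are kept in the
#' log details, so output plus removed partitions the input); `merge` keeps
#' them, flagged, appended after the non-matching records. Screening never
#' alters sequences or TaxIDs.
#'
#' @param db normalized record tibble.
#' @param checklist a `taxa_checklist` of contaminants.
#' @param index the `tax_index`.
#' @param policy one of `"flag"`, `"remove"`, `"merge"`.
#' @return list: `db` (screened database) and `report` (per-taxon hit counts).
#' @export
screen_contaminants <- function(db, checklist, index,
                                policy = c("flag", "remove", "merge")) {
  policy <- match.arg(policy)
  fam <- family_of_taxids(index, db$tax_id)
  hit <- (!is.na(db$canonical_name) &
            name_key(db$canonical_name) %in% name_key(checklist$species)) |
    (!is.na(fam) & name_key(fam) %in% name_key(checklist$families))
  db$flags <- add_flag(db$flags, hit, "contaminant")
  report <- tibble(canonical_name = db$canonical_name[hit]) %>%
    dplyr::count(.data$canonical_name, name = "n_records")
  out <- switch(policy,
    flag = with_refdb_attrs(db, db),
    remove = with_refdb_attrs(db[!hit, ], db),
    merge = with_refdb_attrs(bind_rows(db[!hit, ], db[hit, ]), db)
  )
  out <- log_step(out, paste0("screen_contaminants_", policy), nrow(db), nrow(out),
                  details = list(list(report = report, removed = db[hit & policy == "remove", ])))
  list(db = out, report = report)
}
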