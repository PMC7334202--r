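# Taxonomic normalisation: canonical binomials, TaxID attachment via the
# resolve -> synonym -> mint-under-genus cascade, removal of unresolvables.

# Open nomenclature qualifiers that demote a name to genus level.
NAME_QUALIFIERS <- c("sp", "sp.", "spp", "spp.", "cf", "cf.", "aff", "aff.",
                     "nr", "nr.", "indet", "indet.")

#' Extract a canonical binomial from an organism name
#'
#' Applies the rules used to decide what counts as a fully identified taxon:
#' open-nomenclature qualifiers ("sp.", "cf.", "aff.", "nr.") and quoted
#' epithets demote the name to genus level; trinomials are truncated to the
#' binomial; two clean words give a species-level binomial; a single
#' capitalised word is treated as a bare genus; anything else is unusable.
#'
#' @param organism_name character vector of repository organism strings.
#' @return tibble (`organism_name`, `canonical_name`, `level`) with `level`
#'   one of `"species"`, `"genus"`, `"unusable"`.
#' @export
#' @examples
#' extract_binomial(c("Abra alba", "Abra sp. NZ-2019", "Abra alba alba"))
extract_binomial <- function(organism_name) {
  one <- function(x) {
    x <- stringr::str_squish(x %||% "")
    if (!nzchar(x)) return(c(NA_character_, "unusable"))
    words <- strsplit(x, " ", fixed = TRUE)[[1]]
    genus <- words[1]
    if (!grepl("^[A-Z][A-Za-z-]+$", genus)) return(c(NA_character_, "unusable"))
    if (length(words) == 1) return(c(genus, "genus"))
    epithet <- words[2]
    quoted <- grepl("^['\"]", epithet)
    qualifier <- tolower(epithet) %in% NAME_QUALIFIERS
    clean <- grepl("^[a-z][a-z-]+$", epithet)
    if (qualifier || quoted || !clean) return(c(genus, "genus"))
    c(paste(genus, epithet), "species") # trinomials truncate here
  }
  res <- vapply(organism_name, one, character(2), USE.NAMES = FALSE)
  tibble(
    organism_name = organism_name,
    canonical_name = res[1, ],
    level = res[2, ]
  )
}

#' Attach TaxIDs to every record (normalisation cascade)
#'
#' For each distinct canonical name, in first-occurrence order:
#' \enumerate{
#'   \item resolve the canonical name against the taxonomy (scientific names,
#'     then synonym-type classes);
#'   \item if unresolved and the name is a species-level binomial, resolve the
#'     genus word; if it resolves to a genus-rank node, mint one new species
#'     TaxID nested under it (one mint per distinct name, reused by all
#'     records sharing it);
#'   \item otherwise drop the record — a sequence without a TaxID cannot be
#'     used by LCA-based assignment tools.
#' }
#' Genus-level names that resolve take the genus TaxID directly; no node is
#' minted for them. Ambiguous homonyms take the policy choice from
#' [resolve_name()] and are flagged `"ambiguous_homonym"`.
#'
#' @param db record tibble (dereplicated).
#' @param index a `tax_index`.
#' @param focal_tax_ids optional focal TaxIDs for homonym disambiguation.
#' @return list of class `normalization`: `db` (surviving records with
#'   `tax_id`, `canonical_name`, `level` filled), `index` (taxonomy augmented
#'   with minted nodes), `report` (see [normalization_report()]).
#' @export
normalize_records <- function(db, index, focal_tax_ids = NULL) {
  n_in <- nrow(db)
  bins <- extract_binomial(db$organism_name)
  db$canonical_name <- bins$canonical_name
  db$level <- bins$level

  uniq <- tibble(canonical_name = db$canonical_name, level = db$level) %>%
    mutate(key = name_key(dplyr::coalesce(.data$canonical_name, ""))) %>%
    distinct(.data$key, .keep_all = TRUE)

  assign <- vector("list", nrow(uniq))
  for (i in seq_len(nrow(uniq))) {
    cn <- uniq$canonical_name[i]
    lv <- uniq$level[i]
    if (is.na(cn) || lv == "unusable") {
      assign[[i]] <- list(tax_id = NA_integer_, outcome = "dropped", ambiguous = FALSE)
      next
    }
    res <- resolve_name(index, cn, focal_tax_ids = focal_tax_ids)
    if (!is.na(res$tax_id)) {
      assign[[i]] <- list(
        tax_id = res$tax_id,
        outcome = if (res$match_class == "exact_scientific") "exact" else "synonym",
        ambiguous = res$ambiguous
      )
      next
    }
    if (lv == "species") {
      genus <- strsplit(cn, " ", fixed = TRUE)[[1]][1]
      gres <- resolve_name(index, genus, focal_tax_ids = focal_tax_ids)
      genus_rank <- if (!is.na(gres$tax_id)) {
        index$nodes$rank[match(gres$tax_id, index$nodes$tax_id)]
      } else {
        NA_character_
      }
      if (!is.na(gres$tax_id) && identical(genus_rank, "genus")) {
        minted <- mint_taxid(index, cn, gres$tax_id)
        index <- minted$index
        assign[[i]] <- list(tax_id = minted$tax_id, outcome = "minted",
                            ambiguous = gres$ambiguous)
        next
      }
    }
    assign[[i]] <- list(tax_id = NA_integer_, outcome = "dropped", ambiguous = FALSE)
  }

  uniq$tax_id <- vapply(assign, function(a) a$tax_id, 1L)
  uniq$outcome <- vapply(assign, function(a) a$outcome, "")
  uniq$ambiguous <- vapply(assign, function(a) a$ambiguous, logical(1))

  rec_key <- name_key(dplyr::coalesce(db$canonical_name, ""))
  at <- match(rec_key, uniq$key)
  db$tax_id <- uniq$tax_id[at]
  outcome <- uniq$outcome[at]
  db$flags <- add_flag(db$flags, uniq$ambiguous[at], "ambiguous_homonym")

  report <- structure(
    list(
      n_exact = sum(outcome == "exact"),
      n_synonym = sum(outcome == "synonym"),
      n_minted = sum(outcome == "minted"),
      n_dropped = sum(outcome == "dropped"),
      dropped_names = unique(db$organism_name[outcome == "dropped"]),
      minted_pairs = uniq %>%
        filter(.data$outcome == "minted") %>%
        select(species_name = "canonical_name", "tax_id")
    ),
    class = "normalization_report"
  )
  stopifnot(report$n_exact + report$n_synonym + report$n_minted +
              report$n_dropped == n_in)

  kept <- with_refdb_attrs(db[outcome != "dropped", ], db)
  kept <- log_step(kept, "normalize", n_in, nrow(kept),
                   details = list(list(report = report)))
  structure(list(db = kept, index = index, report = report),
            class = "normalization")
}

#' @export
print.normalization_report <- function(x, ...) {
  cat(sprintf(
    "<normalization_report> exact %d | synonym %d | minted %d | dropped %d\n",
    x$n_exact, x$n_synonym, x$n_minted, x$n_dropped
  ))
  invisible(x)
}

#' @export
print.normalization <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' @export
glance.normalization <- function(x, ...) {
  r <- x$report
  tibble(n_exact = r$n_exact, n_synonym = r$n_synonym, n_minted = r$n_minted,
         n_dropped = r$n_dropped, n_out = nrow(x$db))
}

#' @export
tidy.normalization <- function(x, ...) {
  r <- x$report
  tibble(
    outcome = c("exact", "synonym", "minted", "dropped"),
    n = c(r$n_exact, r$n_synonym, r$n_minted, r$n_dropped)
  )
}

#' Normalisation report as a tibble (for TSV export)
#' @param x a `normalization` result or `normalization_report`.
#' @return two-column tibble (`metric`, `value`).
#' @export
normalization_report <- function(x) {
  r <- if (inherits(x, "normalization")) x$report else x
  tibble(
    metric = c("n_exact", "n_synonym", "n_minted", "n_dropped"),
    value = c(r$n_exact, r$n_synonym, r$n_minted, r$n_dropped)
  )
}

#' Normalised FASTA header for a record
#'
#' Layout (bit-stable): `accession;taxlabel=<name>;taxid=<id>;gene=<label>`.
#' @param db normalized record tibble.
#' @return character vector of headers (no leading `>`).
#' @export
normalized_headers <- function(db) {
  if (any(is.na(db$tax_id))) {
    stop(sprintf("record %s has no TaxID; normalize before export",
                 db$accession[which(is.na(db$tax_id))[1]]))
  }
  sprintf("%s;taxlabel=%s;taxid=%d;gene=%s",
          db$accession, db$canonical_name, db$tax_id, db$gene_label)
}
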