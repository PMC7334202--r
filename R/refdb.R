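# Reference database container: a tibble of records carrying provenance and a
# derivation log (per-step before/after counts) as attributes, so a piped
# filter -> merge -> dereplicate -> normalize chain stays auditable.

new_refdb <- function(records, provenance = NULL, log = NULL) {
  attr(records, "provenance") <- provenance %||%
    tibble(source = character(), label = character(), n_records = integer())
  attr(records, "derivation_log") <- log %||%
    tibble(step = character(), n_in = integer(), n_out = integer(), details = list())
  class(records) <- unique(c("refdb", class(records)))
  records
}

#' Derivation log of a reference database
#'
#' Each pipeline step appends one row with its input/output record counts and
#' a step-specific `details` payload (e.g. the dereplication cluster map).
#' @param db a reference database (tibble of records).
#' @return tibble (`step`, `n_in`, `n_out`, `details`).
#' @export
derivation_log <- function(db) {
  attr(db, "derivation_log") %||%
    tibble(step = character(), n_in = integer(), n_out = integer(), details = list())
}

#' Provenance table of a reference database
#' @param db a reference database.
#' @return tibble (`source`, `label`, `n_records`).
#' @export
db_provenance <- function(db) {
  attr(db, "provenance") %||%
    tibble(source = character(), label = character(), n_records = integer())
}

log_step <- function(db, step, n_in, n_out, details = list(NULL)) {
  attr(db, "derivation_log") <- bind_rows(
    derivation_log(db),
    tibble(step = step, n_in = as.integer(n_in), n_out = as.integer(n_out),
           details = details)
  )
  db
}

with_refdb_attrs <- function(records, template) {
  new_refdb(as_tibble(records),
            provenance = db_provenance(template),
            log = derivation_log(template))
}

#' @export
print.refdb <- function(x, ...) {
  cat(sprintf("<refdb> %d records", nrow(x)))
  lg <- derivation_log(x)
  if (nrow(lg) > 0) cat(sprintf(" | steps: %s", paste(lg$step, collapse = " > ")))
  cat("\n")
  NextMethod()
}

#' Check if records carry a flag
#' @param db record tibble.
#' @param flag flag string (e.g. "marine", "contaminant").
#' @return logical vector, one per record.
#' @export
has_flag <- function(db, flag) {
  vapply(db$flags, function(f) flag %in% f, logical(1))
}

add_flag <- function(flags, where, flag) {
  flags[where] <- lapply(flags[where], function(f) union(f, flag))
  flags
}

#' Read a blacklist of accessions
#'
#' One accession per line; blank lines and `#` comments are ignored.
#' @param text file contents (or use [readLines()] + paste for a path).
#' @return character vector of accessions.
#' @export
read_blacklist <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- stringr::str_squish(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

strip_version <- function(acc) sub("\\.\\d+$", "", acc)

#' Remove blacklisted accessions
#'
#' A record is removed when its accession — versioned or version-stripped —
#' appears in the blacklist. Unknown blacklist entries are ignored but
#' reported, so typos in the blacklist are visible.
#'
#' @param records record tibble.
#' @param blacklist character vector of accessions (see [read_blacklist()]).
#' @return the surviving records, with attributes `removed` (count) and
#'   `unused_blacklist` (entries that matched nothing); also logged if the
#'   input is a refdb.
#' @export
filter_blacklist <- function(records, blacklist) {
  bl <- unique(c(blacklist, strip_version(blacklist)))
  hit <- records$accession %in% bl | strip_version(records$accession) %in% bl
  out <- with_refdb_attrs(records[!hit, ], records)
  used <- blacklist[blacklist %in% c(records$accession, strip_version(records$accession)) |
                      strip_version(blacklist) %in% strip_version(records$accession)]
  unused <- setdiff(blacklist, used)
  out <- log_step(out, "filter_blacklist", nrow(records), nrow(out),
                  details = list(list(removed_accessions = records$accession[hit],
                                      unused_blacklist = unused)))
  attr(out, "removed") <- sum(hit)
  attr(out, "unused_blacklist") <- unused
  out
}

#' Merge two record sets into one reference database
#'
#' Plain concatenation, `a` then `b`, preserving input order — no
#' deduplication happens here. Accession collisions across the two inputs are
#' kept (dereplication resolves identical sequences) but reported.
#'
#' @param db_a,db_b record tibbles (e.g. GenBank- and BOLD-derived).
#' @param labels length-2 character vector naming the two inputs in the
#'   provenance table.
#' @return a refdb of `nrow(db_a) + nrow(db_b)` records with attribute
#'   `accession_collisions`.
#' @export
merge_records <- function(db_a, db_b, labels = c("a", "b")) {
  merged <- bind_rows(as_tibble(db_a), as_tibble(db_b))
  collisions <- intersect(db_a$accession, db_b$accession)
  prov <- tibble(
    source = c(if (nrow(db_a)) unique(db_a$source) else "empty",
               if (nrow(db_b)) unique(db_b$source) else "empty"),
    label = labels,
    n_records = c(nrow(db_a), nrow(db_b))
  )
  out <- new_refdb(merged, provenance = prov)
  out <- log_step(out, "merge", nrow(db_a) + nrow(db_b), nrow(merged),
                  details = list(list(accession_collisions = collisions)))
  attr(out, "accession_collisions") <- collisions
  out
}

#' Dereplicate identical sequences
#'
#' Collapses exact, full-length, case-insensitive duplicates (after
#' canonicalisation) to the first-seen record, mirroring full-length
#' dereplication as done by tools like vsearch. Reverse complements are NOT
#' treated as duplicates. The cluster map (kept accession -> collapsed
#' accessions) is retained in the derivation log. Idempotent. Records that
#' collapse under the same sequence but disagree on the organism name keep the
#' first record's name; such conflicts are reported in the log details.
#'
#' @param db record tibble (sequences already canonical: uppercase, no gaps).
#' @return dereplicated refdb; log gains a `dereplicate` step whose details
#'   hold `clusters` (tibble `kept`, `collapsed` list-column) and
#'   `name_conflicts`.
#' @export
dereplicate <- function(db) {
  key <- toupper(db$sequence)
  keep <- !duplicated(key)
  kept_acc <- db$accession[keep][match(key, key[keep])]
  clusters <- tibble(kept = kept_acc, accession = db$accession,
                     organism_name = db$organism_name) %>%
    group_by(.data$kept) %>%
    summarise(
      collapsed = list(.data$accession[-1]),
      n_members = n(),
      name_conflict = dplyr::n_distinct(.data$organism_name) > 1,
      .groups = "drop"
    ) %>%
    filter(.data$n_members > 1)
  out <- with_refdb_attrs(db[keep, ], db)
  out <- log_step(out, "dereplicate", nrow(db), sum(keep),
                  details = list(list(
                    clusters = clusters,
                    name_conflicts = clusters$kept[clusters$name_conflict]
                  )))
  out
}

#' Cluster map from the last dereplication
#' @param db a dereplicated refdb.
#' @return tibble (`kept`, `collapsed`, `n_members`, `name_conflict`) of
#'   duplicate clusters (size > 1), or NULL if never dereplicated.
#' @export
derep_clusters <- function(db) {
  lg <- derivation_log(db)
  at <- which(lg$step == "dereplicate")
  if (length(at) == 0) return(NULL)
  lg$details[[max(at)]]$clusters
}

#' @export
glance.refdb <- function(x, ...) {
  tibble(
    n_records = nrow(x),
    n_sources = dplyr::n_distinct(x$source),
    n_with_taxid = sum(!is.na(x$tax_id)),
    n_marine_flagged = sum(has_flag(x, "marine")),
    n_contaminant_flagged = sum(has_flag(x, "contaminant")),
    n_steps = nrow(derivation_log(x))
  )
}
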