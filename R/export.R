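# Export: Kraken2-, MEGAN- and BLAST-ready files from a normalized database.

check_exportable <- function(db) {
  if (nrow(db) == 0) return(invisible(db))
  if (any(is.na(db$tax_id))) {
    stop(sprintf("record %s has no TaxID; run normalize_records() first",
                 db$accession[which(is.na(db$tax_id))[1]]))
  }
  invisible(db)
}

check_unique_accessions <- function(db) {
  dup <- db$accession[duplicated(db$accession)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate accession(s) after merge: %s; disambiguate before export",
                 paste(unique(dup), collapse = ", ")))
  }
  invisible(db)
}

#' Kraken2 custom-database FASTA
#'
#' One entry per record with the header syntax Kraken2 expects for custom
#' databases: `>accession|kraken:taxid|TaxID`. Sequences wrap at `width`.
#'
#' @param db normalized record tibble (every record has a TaxID).
#' @param width FASTA wrap width (default 80).
#' @return FASTA text ("" for an empty database).
#' @export
to_kraken_fasta <- function(db, width = 80) {
  check_exportable(db)
  format_fasta(sprintf("%s|kraken:taxid|%d", db$accession, db$tax_id),
               db$sequence, width = width)
}

#' MEGAN inputs: FASTA + accession-to-TaxID map
#'
#' The FASTA carries the normalized header layout
#' (`accession;taxlabel=...;taxid=...;gene=...`); the map is a two-column TSV
#' (`accession<TAB>tax_id`) consumed when building the BLAST database MEGAN
#' aligns against. Duplicate accessions are an error: the map must be a
#' function of accession.
#'
#' @param db normalized record tibble.
#' @param width FASTA wrap width.
#' @return list with elements `fasta` and `taxid_map` (both text).
#' @export
to_megan_inputs <- function(db, width = 80) {
  check_exportable(db)
  check_unique_accessions(db)
  list(
    fasta = format_fasta(normalized_headers(db), db$sequence, width = width),
    taxid_map = if (nrow(db) == 0) "" else
      paste0(paste(sprintf("%s\t%d", db$accession, db$tax_id), collapse = "\n"), "\n")
  )
}

#' BLAST inputs: FASTA + makeblastdb -taxid_map file
#'
#' Same FASTA as the MEGAN export; the map follows the `makeblastdb
#' -taxid_map` dialect (accession, single space, taxid).
#'
#' @inheritParams to_megan_inputs
#' @return list with elements `fasta` and `taxid_map`.
#' @export
to_blast_inputs <- function(db, width = 80) {
  check_exportable(db)
  check_unique_accessions(db)
  list(
    fasta = format_fasta(normalized_headers(db), db$sequence, width = width),
    taxid_map = if (nrow(db) == 0) "" else
      paste0(paste(sprintf("%s %d", db$accession, db$tax_id), collapse = "\n"), "\n")
  )
}

#' Parse (accession, tax_id) pairs back out of exported FASTA headers
#'
#' Round-trip helper: works on both the Kraken header dialect and the
#' normalized header layout.
#' @param fasta_text exported FASTA text.
#' @return tibble (`accession`, `tax_id`, `sequence`).
#' @export
parse_export_fasta <- function(fasta_text) {
  fa <- parse_fasta(fasta_text)
  if (nrow(fa) == 0) {
    return(tibble(accession = character(), tax_id = integer(), sequence = character()))
  }
  kraken <- grepl("|kraken:taxid|", fa$header, fixed = TRUE)
  acc <- ifelse(kraken,
                sub("\\|kraken:taxid\\|\\d+$", "", fa$header),
                sub(";.*$", "", fa$header))
  tid <- ifelse(kraken,
                sub("^.*\\|kraken:taxid\\|", "", fa$header),
                stringr::str_match(fa$header, ";taxid=(\\d+);")[, 2])
  tibble(accession = acc, tax_id = as.integer(tid), sequence = fa$sequence)
}
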