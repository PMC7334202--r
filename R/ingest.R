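# Ingest: GenBank flatfiles and BOLD-style TSV exports -> sequence record tibbles.

#' Construct a sequence-record tibble
#'
#' The common currency of the pipeline: one row per reference sequence with
#' `accession`, `source` ("genbank"/"bold"), `organism_name`, `gene_label`,
#' `sequence`, `tax_id` (NA until normalisation) and a `flags` list-column.
#' @param accession,source,organism_name,gene_label,sequence character vectors
#'   of equal length.
#' @return tibble of sequence records.
#' @export
seq_records <- function(accession, source, organism_name, gene_label, sequence) {
  n <- length(accession)
  tibble(
    accession = as.character(accession),
    source = as.character(source),
    organism_name = as.character(organism_name),
    gene_label = as.character(gene_label),
    sequence = as.character(sequence),
    tax_id = rep(NA_integer_, n),
    flags = rep(list(character()), n)
  )
}

#' Ingest report attached to a record tibble
#' @param records a tibble returned by an ingest function.
#' @return tibble describing skipped entries (`reason`, `detail`).
#' @export
ingest_report <- function(records) {
  attr(records, "ingest_report") %||% tibble(reason = character(), detail = character())
}

set_ingest_report <- function(records, reasons, details) {
  attr(records, "ingest_report") <- tibble(reason = reasons, detail = details)
  records
}

#' Parse a GenBank flatfile into sequence records
#'
#' Understands the subset of the GB format needed to convert flatfiles to
#' FASTA: `LOCUS`...`//` entry boundaries, `ACCESSION`/`VERSION`, the
#' `ORGANISM` line, and the `ORIGIN` sequence block (digits and whitespace
#' stripped, uppercased). Entries lacking an organism or sequence are skipped
#' and reported; a truncated final entry (no `//`) is a parse error.
#'
#' @param text flatfile contents (one or more concatenated entries).
#' @param gene_label gene region label attached to each record (default "COI").
#' @return tibble of records (`source = "genbank"`); skipped entries are
#'   listed in [ingest_report()].
#' @export
parse_genbank <- function(text, gene_label = "COI") {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  locus_at <- grep("^LOCUS", lines)
  if (length(locus_at) == 0) {
    return(set_ingest_report(
      seq_records(character(), character(), character(), character(), character()),
      character(), character()
    ))
  }
  end_at <- grep("^//\\s*$", lines)
  if (length(end_at) < length(locus_at) || max(locus_at) > max(end_at)) {
    stop("truncated GenBank entry: final record has no '//' terminator")
  }

  recs <- list()
  skip_reason <- character()
  skip_detail <- character()
  for (i in seq_along(locus_at)) {
    from <- locus_at[i]
    to <- end_at[end_at > from][1]
    entry <- lines[from:to]

    locus_name <- strsplit(stringr::str_squish(entry[1]), " ")[[1]][2]
    acc_line <- grep("^ACCESSION", entry, value = TRUE)
    ver_line <- grep("^VERSION", entry, value = TRUE)
    accession <- if (length(ver_line) > 0) {
      strsplit(stringr::str_squish(ver_line[1]), " ")[[1]][2]
    } else if (length(acc_line) > 0) {
      strsplit(stringr::str_squish(acc_line[1]), " ")[[1]][2]
    } else {
      locus_name
    }

    org_line <- grep("^\\s+ORGANISM", entry, value = TRUE)
    organism <- if (length(org_line) > 0) {
      stringr::str_squish(sub("^\\s+ORGANISM", "", org_line[1]))
    } else {
      ""
    }
    if (!nzchar(organism)) {
      skip_reason <- c(skip_reason, "missing_organism")
      skip_detail <- c(skip_detail, accession %||% locus_name)
      next
    }

    origin_at <- grep("^ORIGIN", entry)
    sequence <- if (length(origin_at) > 0 && origin_at[1] + 1 <= length(entry) - 1) {
      raw <- paste(entry[(origin_at[1] + 1):(length(entry) - 1)], collapse = "")
      clean_sequence(raw)
    } else {
      NA_character_
    }
    if (is.na(sequence)) {
      skip_reason <- c(skip_reason, "missing_or_invalid_sequence")
      skip_detail <- c(skip_detail, accession)
      next
    }
    recs[[length(recs) + 1]] <- list(accession = accession, organism = organism,
                                     sequence = sequence)
  }
  out <- seq_records(
    accession = vapply(recs, `[[`, "", "accession"),
    source = rep("genbank", length(recs)),
    organism_name = vapply(recs, `[[`, "", "organism"),
    gene_label = rep(gene_label, length(recs)),
    sequence = vapply(recs, `[[`, "", "sequence")
  )
  set_ingest_report(out, skip_reason, skip_detail)
}

#' Parse a BOLD-style TSV export into sequence records
#'
#' Requires columns `processid`, `species_name`, `markercode`, `nucleotides`
#' (any order). The process id serves as the accession, the marker code as the
#' gene label; gap characters are stripped from the nucleotides. Rows with
#' empty nucleotides, or an alphabet outside IUPAC codes, are skipped and
#' counted. Rows lacking a species name fall back to a `genus_name`/`genus`
#' column when one is present, preserving genus-level assignability.
#'
#' @param text TSV contents.
#' @return tibble of records (`source = "bold"`); skips in [ingest_report()].
#' @export
parse_bold_tsv <- function(text) {
  df <- readr::read_tsv(I(text), col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("processid", "species_name", "markercode", "nucleotides")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("BOLD TSV is missing mandatory column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    return(set_ingest_report(
      seq_records(character(), character(), character(), character(), character()),
      character(), character()
    ))
  }
  genus_col <- intersect(c("genus_name", "genus"), names(df))[1]
  organism <- df$species_name
  if (!is.na(genus_col)) {
    fallback <- is.na(organism) | !nzchar(organism)
    organism[fallback] <- df[[genus_col]][fallback]
  }
  seq_clean <- clean_sequence(dplyr::coalesce(df$nucleotides, ""))
  empty_nt <- is.na(df$nucleotides) | !nzchar(df$nucleotides)
  bad_alpha <- !empty_nt & is.na(seq_clean)
  no_name <- is.na(organism) | !nzchar(organism)
  keep <- !empty_nt & !bad_alpha & !no_name

  out <- seq_records(
    accession = df$processid[keep],
    source = rep("bold", sum(keep)),
    organism_name = organism[keep],
    gene_label = df$markercode[keep],
    sequence = seq_clean[keep]
  )
  set_ingest_report(
    out,
    reasons = c(rep("empty_nucleotides", sum(empty_nt)),
                rep("non_iupac_sequence", sum(bad_alpha)),
                rep("missing_name", sum(no_name & !empty_nt & !bad_alpha))),
    details = c(df$processid[empty_nt], df$processid[bad_alpha],
                df$processid[no_name & !empty_nt & !bad_alpha])
  )
}

#' Build repository search terms for focal taxa
#'
#' One term per taxon, carrying the gene-name synonyms (for COI: CO1, COI,
#' COX1, COXI), an upload-year window, the origin restriction and whether the
#' "barcode" keyword is included (the keyword distinguishes the stricter BAR
#' variant of a database from the NOBAR variant).
#'
#' @param taxa character vector of taxon names (non-empty).
#' @param gene_synonyms gene-name synonyms, OR-joined in the rendered query.
#' @param year_from,year_to upload-date window.
#' @param origin origin restriction (default "Eukaryota").
#' @param barcode_keyword include the "barcode" keyword?
#' @return tibble of search terms with a `query` column holding the rendered
#'   Entrez-style string.
#' @export
build_search_terms <- function(taxa,
                               gene_synonyms = c("CO1", "COI", "COX1", "COXI"),
                               year_from = 2003, year_to = 2019,
                               origin = "Eukaryota",
                               barcode_keyword = FALSE) {
  if (length(taxa) == 0) stop("taxa list must be non-empty")
  stopifnot(length(gene_synonyms) > 0, year_from <= year_to)
  out <- tibble(
    taxon = as.character(taxa),
    gene_synonyms = rep(list(gene_synonyms), length(taxa)),
    year_from = as.integer(year_from),
    year_to = as.integer(year_to),
    barcode_keyword = isTRUE(barcode_keyword),
    origin = origin
  )
  out$query <- vapply(seq_len(nrow(out)), function(i) {
    render_search_term(out[i, ])
  }, character(1))
  out
}

#' Render one search term as an Entrez-style query string
#' @param term one row of the tibble from [build_search_terms()].
#' @return character scalar.
#' @export
render_search_term <- function(term) {
  stopifnot(nrow(term) == 1)
  genes <- paste(sprintf("%s[All Fields]", term$gene_synonyms[[1]]), collapse = " OR ")
  q <- sprintf(
    "%s[ORGN] AND (%s) AND (\"%d\"[PDAT] : \"%d\"[PDAT]) AND %s[ORGN]",
    term$taxon, genes, term$year_from, term$year_to, term$origin
  )
  if (isTRUE(term$barcode_keyword)) q <- paste(q, "AND barcode[All Fields]")
  q
}
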