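# Shared low-level helpers: name keys, rounding, sequence hygiene, FASTA text.

# IUPAC nucleotide alphabet accepted after cleaning (U tolerated for RNA-coded
# submissions; gaps are stripped before validation).
IUPAC_CHARS <- "ACGTUMRWSYKVHDBN"

#' Canonical key for case-insensitive name matching
#'
#' Lowercases and collapses internal whitespace. Names are never fuzzy-matched;
#' this is the only normalisation applied before lookup.
#' @param x character vector of taxon names.
#' @return character vector of keys.
#' @keywords internal
name_key <- function(x) {
  tolower(stringr::str_squish(x))
}

#' Round half up
#'
#' Base `round()` rounds half to even; composition percentages here use the
#' conventional half-up rule so printed tables are reproduced digit for digit.
#' @param x numeric vector (non-negative).
#' @param digits decimal places.
#' @return numeric vector.
#' @export
#' @examples
#' round_half_up(10.7998, 2) # 10.80
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Canonicalise a nucleotide sequence
#'
#' Strips gap characters (`-`, `.`) and whitespace, uppercases, and validates
#' against the IUPAC nucleotide alphabet. Invalid sequences become `NA` so
#' callers can skip and report them.
#' @param x character vector of raw sequences.
#' @return character vector; `NA` where a sequence contains non-IUPAC letters.
#' @export
clean_sequence <- function(x) {
  out <- toupper(gsub("[-.[:space:][:digit:]]", "", x))
  bad <- !grepl(paste0("^[", IUPAC_CHARS, "]+$"), out)
  out[bad | !nzchar(out)] <- NA_character_
  out
}

#' Format sequences as FASTA text
#'
#' @param headers character vector of header lines (without the leading `>`).
#' @param sequences character vector of sequences, same length.
#' @param width line-wrap width in bases (default 80).
#' @return a single string of FASTA text ("" for zero records).
#' @export
format_fasta <- function(headers, sequences, width = 80) {
  stopifnot(length(headers) == length(sequences))
  if (length(headers) == 0) return("")
  entries <- purrr::map2_chr(headers, sequences, function(h, s) {
    wrapped <- gsub(sprintf("(.{%d})", width), "\\1\n", s)
    wrapped <- sub("\n$", "", wrapped)
    paste0(">", h, "\n", wrapped)
  })
  paste0(paste(entries, collapse = "\n"), "\n")
}

#' Parse FASTA text into a tibble
#'
#' Minimal reader used for round-trip checks of this package's own exports.
#' @param text FASTA text.
#' @return tibble with columns `header`, `sequence`.
#' @export
parse_fasta <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(header = character(), sequence = character()))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("FASTA text does not start with a header line")
  grp <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  seqs <- vapply(
    split(lines[!is_hdr], grp[!is_hdr]),
    paste, collapse = "", FUN.VALUE = character(1)
  )
  # entries with empty sequence blocks keep ""
  out <- rep("", length(headers))
  out[as.integer(names(seqs))] <- unname(seqs)
  tibble(header = headers, sequence = out)
}

read_text <- function(path) {
  paste0(paste(readLines(path, warn = FALSE), collapse = "\n"), "\n")
}
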