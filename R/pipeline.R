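# End-to-end pipeline: ingest -> blacklist -> merge -> dereplicate ->
# normalize -> screen -> export -> stats, with a machine-readable derivation
# report. Stage logging goes to stderr; all outputs are files.

#' Read a pipeline configuration file
#'
#' YAML with a `paths:` section (`names_dmp`, `nodes_dmp`, `genbank`, `bold`,
#' optional `blacklist`, `marine_checklist`, `contaminant_checklist`,
#' `out_dir`) and optional top-level keys `gene_label`, `contaminant_policy`,
#' `fasta_width`.
#' @param path YAML file path.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full curation pipeline
#'
#' Executes, in order: taxonomy load, GenBank + BOLD ingest, blacklist
#' filtering, merge, dereplication, taxonomic normalisation (with TaxID
#' minting), marine and contaminant screening, exports (Kraken2, MEGAN,
#' BLAST), the augmented taxonomy dump, and composition statistics. All
#' referenced input paths are checked before any work. Given fixed inputs the
#' run is deterministic and idempotent: rerunning produces byte-identical
#' outputs.
#'
#' @param config a config list (see [read_pipeline_config()]) or a YAML path.
#' @return invisibly, a list: `db` (final records), `index` (augmented
#'   taxonomy), `normalization` report, `stats`, `report` (derivation tibble),
#'   `paths` (written files).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  p <- config$paths
  required <- c("names_dmp", "nodes_dmp", "genbank", "bold", "out_dir")
  missing_keys <- setdiff(required, names(p))
  if (length(missing_keys) > 0) {
    stop(sprintf("config is missing paths: %s", paste(missing_keys, collapse = ", ")))
  }
  in_paths <- unlist(p[setdiff(names(p), "out_dir")])
  absent <- in_paths[!file.exists(in_paths)]
  if (length(absent) > 0) {
    stop(sprintf("input path(s) do not exist: %s", paste(absent, collapse = ", ")))
  }
  gene_label <- config$gene_label %||% "COI"
  policy <- config$contaminant_policy %||% "flag"
  width <- config$fasta_width %||% 80
  out_dir <- p$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  pipeline_log("taxonomy", "reading %s / %s", p$names_dmp, p$nodes_dmp)
  index <- read_taxdump(p$names_dmp, p$nodes_dmp)

  pipeline_log("ingest", "parsing GenBank flatfile %s", p$genbank)
  gb <- parse_genbank(read_text(p$genbank), gene_label = gene_label)
  pipeline_log("ingest", "%d GenBank records (%d skipped)", nrow(gb),
               nrow(ingest_report(gb)))
  bold <- parse_bold_tsv(read_text(p$bold))
  pipeline_log("ingest", "%d BOLD records (%d skipped)", nrow(bold),
               nrow(ingest_report(bold)))

  db <- merge_records(gb, bold, labels = c("genbank", "bold"))
  if (!is.null(p$blacklist)) {
    bl <- read_blacklist(read_text(p$blacklist))
    db <- filter_blacklist(db, bl)
    pipeline_log("blacklist", "removed %d record(s)", attr(db, "removed"))
  }
  db <- dereplicate(db)
  pipeline_log("dereplicate", "%d unique sequences", nrow(db))

  norm <- normalize_records(db, index)
  db <- norm$db
  index <- norm$index
  pipeline_log("normalize", "exact %d | synonym %d | minted %d | dropped %d",
               norm$report$n_exact, norm$report$n_synonym,
               norm$report$n_minted, norm$report$n_dropped)

  if (!is.null(p$marine_checklist)) {
    marine <- read_checklist(read_text(p$marine_checklist), "marine")
    db <- screen_marine(db, marine, index)
    pipeline_log("screen", "%d marine species",
                 marine_summary(db)$n_marine_species)
  }
  contaminant_report <- NULL
  if (!is.null(p$contaminant_checklist)) {
    cont <- read_checklist(read_text(p$contaminant_checklist), "contaminants")
    scr <- screen_contaminants(db, cont, index, policy = policy)
    db <- scr$db
    contaminant_report <- scr$report
    pipeline_log("screen", "contaminant policy '%s': %d taxa hit", policy,
                 nrow(scr$report))
  }

  pipeline_log("export", "writing Kraken2/MEGAN/BLAST inputs to %s", out_dir)
  out <- list()
  out$kraken_fasta <- file.path(out_dir, "kraken.fasta")
  writeLines(sub("\n$", "", to_kraken_fasta(db, width = width)), out$kraken_fasta)
  megan <- to_megan_inputs(db, width = width)
  out$megan_fasta <- file.path(out_dir, "megan.fasta")
  out$megan_map <- file.path(out_dir, "megan_taxid_map.tsv")
  writeLines(sub("\n$", "", megan$fasta), out$megan_fasta)
  writeLines(sub("\n$", "", megan$taxid_map), out$megan_map)
  blast <- to_blast_inputs(db, width = width)
  out$blast_fasta <- file.path(out_dir, "blast.fasta")
  out$blast_map <- file.path(out_dir, "blast_taxid_map.txt")
  writeLines(sub("\n$", "", blast$fasta), out$blast_fasta)
  writeLines(sub("\n$", "", blast$taxid_map), out$blast_map)
  taxdump_paths <- write_taxdump(index, file.path(out_dir, "taxonomy"))
  out$names_dmp <- taxdump_paths[["names"]]
  out$nodes_dmp <- taxdump_paths[["nodes"]]

  stats <- db_stats(db)
  out$stats <- file.path(out_dir, "stats.tsv")
  readr::write_tsv(stats, out$stats, progress = FALSE)
  out$normalization_report <- file.path(out_dir, "normalization_report.tsv")
  readr::write_tsv(normalization_report(norm), out$normalization_report,
                   progress = FALSE)

  report <- derivation_log(db) %>% select("step", "n_in", "n_out")
  out$derivation_report <- file.path(out_dir, "derivation_report.tsv")
  readr::write_tsv(report, out$derivation_report, progress = FALSE)

  invisible(list(db = db, index = index, normalization = norm$report,
                 stats = stats, report = report, paths = out))
}

#' Check the internal consistency of a derivation report
#'
#' Steps that only re-flag records keep `n_in == n_out`; for the others each
#' step's output count must equal the next step's input count.
#' @param report tibble (`step`, `n_in`, `n_out`).
#' @return TRUE (invisibly) or an error describing the first inconsistency.
#' @export
check_derivation_chain <- function(report) {
  if (nrow(report) < 2) return(invisible(TRUE))
  for (i in seq_len(nrow(report) - 1)) {
    if (report$n_out[i] != report$n_in[i + 1]) {
      stop(sprintf("derivation chain broken between '%s' (out %d) and '%s' (in %d)",
                   report$step[i], report$n_out[i],
                   report$step[i + 1], report$n_in[i + 1]))
    }
  }
  invisible(TRUE)
}
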