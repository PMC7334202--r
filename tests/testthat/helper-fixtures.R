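# Hand-written miniature inputs, transcribed independently of the package's
# own generators so parsers are checked against a human-readable oracle.

dmp_line <- function(...) paste0(paste(list(...), collapse = "\t|\t"), "\t|")

# root(1) > kingdom Animalia(2) > family Abridae(10) > genus Abra(50)
#   > species Abra alba(101), Abra nitida(102)
# plus family Lupidae(11) > genus Lupus(51) used for the homonym case:
# "Lupa lupa" is the scientific name of two nodes (103 under Abra, 104 under
# Lupus). "Abra ovata" is a synonym of 102; "white abra" a common name of 101.
tiny_nodes <- paste(c(
  dmp_line(1, 1, "no rank"),
  dmp_line(2, 1, "kingdom"),
  dmp_line(10, 2, "family"),
  dmp_line(11, 2, "family"),
  dmp_line(50, 10, "genus"),
  dmp_line(51, 11, "genus"),
  dmp_line(101, 50, "species"),
  dmp_line(102, 50, "species"),
  dmp_line(103, 50, "species"),
  dmp_line(104, 51, "species")
), collapse = "\n")

tiny_names <- paste(c(
  dmp_line(1, "root", "", "scientific name"),
  dmp_line(2, "Animalia", "", "scientific name"),
  dmp_line(10, "Abridae", "", "scientific name"),
  dmp_line(11, "Lupidae", "", "scientific name"),
  dmp_line(50, "Abra", "", "scientific name"),
  dmp_line(51, "Lupus", "", "scientific name"),
  dmp_line(101, "Abra alba", "", "scientific name"),
  dmp_line(101, "white abra", "", "common name"),
  dmp_line(102, "Abra nitida", "", "scientific name"),
  dmp_line(102, "Abra ovata", "", "synonym"),
  dmp_line(103, "Lupa lupa", "", "scientific name"),
  dmp_line(104, "Lupa lupa", "", "scientific name")
), collapse = "\n")

tiny_index <- function() parse_taxdump(tiny_names, tiny_nodes)

# Two GenBank entries; the first ORIGIN block is exactly 60 bp.
gb_entry_1_seq <- paste0(
  "acgtacgtac", "gtacgtacgt", "acgtacgtac",
  "gtacgtacgt", "acgtacgtac", "gtacgtacgt"
)
tiny_genbank <- paste(c(
  "LOCUS       AB000001  60 bp    DNA     linear   INV 01-JAN-2010",
  "DEFINITION  cytochrome oxidase subunit 1 (COI) gene, partial cds.",
  "ACCESSION   AB000001",
  "VERSION     AB000001.1",
  "SOURCE      Abra alba",
  "  ORGANISM  Abra alba",
  "            Animalia; Abridae; Abra.",
  "ORIGIN",
  "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
  "//",
  "LOCUS       AB000002  20 bp    DNA     linear   INV 02-JAN-2010",
  "ACCESSION   AB000002",
  "VERSION     AB000002.2",
  "SOURCE      Abra nitida",
  "  ORGANISM  Abra nitida",
  "ORIGIN",
  "        1 ttttaaaacc ccggggttaa",
  "//"
), collapse = "\n")

tiny_bold <- paste(c(
  "processid\tspecies_name\tmarkercode\tnucleotides",
  "FIX001\tAbra alba\tCOI-5P\tAACCGGTT--AACC",
  "FIX002\tAbra nitida\tCOI-5P\t",
  "FIX003\tAbra ovata\tCOI-5P\tGGGGCCCCAAAATT"
), collapse = "\n")

# Brute-force beta-partition oracle: enumerate membership element by element.
beta_oracle <- function(A, B) {
  A <- unique(tolower(trimws(A)))
  B <- unique(tolower(trimws(B)))
  a <- 0L; b <- 0L; cc <- 0L
  for (x in union(A, B)) {
    in_a <- x %in% A
    in_b <- x %in% B
    if (in_a && in_b) a <- a + 1L else if (in_a) b <- b + 1L else cc <- cc + 1L
  }
  jac <- (b + cc) / (a + b + cc)
  m <- min(b, cc)
  jtu <- if (a + 2 * m == 0) 0 else 2 * m / (a + 2 * m)
  list(a = a, b = b, c = cc, jac = jac, jtu = jtu, jne = jac - jtu)
}

# Records tibble shortcut for merge/export tests.
mk_records <- function(acc, org, seqs, source = "genbank") {
  seq_records(acc, rep(source, length(acc)), org,
              rep("COI", length(acc)), seqs)
}

fixture_pipeline_config <- function(paths, out_dir, policy = "flag") {
  list(
    paths = list(
      names_dmp = paths[["names"]], nodes_dmp = paths[["nodes"]],
      genbank = paths[["genbank"]], bold = paths[["bold"]],
      blacklist = paths[["blacklist"]],
      marine_checklist = paths[["marine"]],
      contaminant_checklist = paths[["contaminant"]],
      out_dir = out_dir
    ),
    contaminant_policy = policy
  )
}
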