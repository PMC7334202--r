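Package: refdbkit
Title: Curated Metabarcoding Reference Databases with a Unified Taxonomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building curated DNA-barcode reference databases for
    metabarcoding (for example COI databases for marine eukaryotes). Ingests
    GenBank flatfiles and BOLD-style TSV exports, unifies records under a
    single NCBI-style taxonomy with synonym resolution and deterministic
    minting of new taxon identifiers, filters blacklisted accessions, merges
    and dereplicates sequences, screens taxa against marine and contaminant
    checklists, exports Kraken2-, MEGAN- and BLAST-ready files, and
    quantifies database composition and pairwise differences via partitioned
    Jaccard beta-diversity (turnover vs nestedness). A deterministic fixture
    generator produces miniature taxonomies and repository files so the full
    pipeline can be exercised without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
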