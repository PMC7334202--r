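---
title: "Curating barcode reference databases: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating barcode reference databases: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refdbkit)
```

## The curation model

`refdbkit` builds metabarcoding reference databases by composing seven
stages, each a pure function over a tibble of sequence records:

1. **Ingest** — GenBank flatfiles and BOLD-style TSVs become records with an
   accession, a source, an organism name string, a gene label and a cleaned
   sequence. Cleaning strips gap characters (`-`, `.`) and whitespace,
   uppercases, and rejects anything outside the IUPAC nucleotide alphabet
   (rejected rows are skipped and reported, never silently repaired).
2. **Blacklist** — records whose accession (versioned or version-stripped)
   appears on a user list of suspect sequences are removed; unmatched
   blacklist entries are reported so typos are visible.
3. **Merge** — plain concatenation, GenBank-derived records before
   BOLD-derived ones, each block in input order. Accession collisions across
   sources are kept and reported; identical sequences are the dereplication
   stage's job. Because both blacklist matching and dereplication are
   order-respecting set operations, filtering after the concatenation yields
   the same database as filtering each source first; the merged form keeps
   the removal counts in one derivation log.
4. **Dereplicate** — exact, full-length, case-insensitive duplicate sequences
   collapse to the first record in merged order (so GenBank representatives
   win ties against BOLD copies). This mirrors standard full-length
   dereplication (as in `vsearch --derep_fulllength`); prefix matching and
   reverse-complement matching are deliberately not performed — a
   reverse-complemented submission is a distinct record a user can screen
   separately, and treating it as a duplicate would silently discard strand
   information. The cluster map (kept accession → collapsed accessions) is
   retained, and organism-name conflicts inside a cluster are reported with
   the kept record's name winning.
5. **Normalize** — every record must end up with a TaxID from a single
   NCBI-style taxonomy, because LCA-based classifiers (MEGAN, Kraken2)
   operate on one taxonomy tree. See the cascade below.
6. **Screen** — marine membership and contaminant status are independent
   flags assigned by name against user checklists.
7. **Export** — Kraken2 (`>acc|kraken:taxid|ID`), MEGAN and BLAST
   (`makeblastdb -taxid_map`) inputs, plus the augmented taxonomy dump.
   Invoking `kraken2-build`/`makeblastdb` themselves is left to the user;
   the files are the contract.

Every stage appends its before/after counts to a derivation log
(`derivation_log()`, `check_derivation_chain()`), so a finished database
carries its own audit trail.

## The name-resolution cascade

For each distinct canonical name, in first-occurrence order:

1. exact match against scientific names (case-insensitive, internal
   whitespace collapsed — never fuzzy);
2. failing that, match against the synonym-type name classes `synonym`,
   `equivalent name`, `includes` and `genbank synonym`. `common name` is
   excluded: vernacular strings collide across kingdoms and would
   misassign silently;
3. failing that, for a species-level binomial whose genus word resolves to a
   **genus-rank** node, a new species TaxID is minted: `max TaxID + 1`,
   species rank, parented on that genus. One distinct name mints exactly one
   id, reused by all records sharing the name. Requiring genus rank on the
   parent keeps minted nodes nested where downstream LCA walks expect
   species to sit; a binomial whose first word resolves to something other
   than a genus is treated as unresolvable.
4. otherwise the record is dropped and enumerated in the report. Families
   without a resolvable genus are deliberately out of scope for minting.

Canonical names come from `extract_binomial()`: open-nomenclature qualifiers
(`sp.`, `cf.`, `aff.`, `nr.`, `spp.`, `indet.`) and quoted epithets demote a
name to genus level; trinomials truncate to the binomial; a bare capitalised
word is a genus; anything else is unusable. Genus-level names that resolve
take the genus TaxID directly — no node is minted for them.

**Homonyms** (one string, several TaxIDs — a real hazard between algal and
animal genera) resolve to the candidate whose lineage intersects the focal
taxa if that candidate is unique, otherwise to the lowest TaxID; either way
the record is flagged `ambiguous_homonym`. The choice is deterministic and
visible rather than clever: the flag lets a user audit exactly the records
where the policy mattered.

## Checklist screening

Marine and contaminant screening match by **name** at family and species
rank, not by TaxID, because external checklists (WoRMS-style) and the NCBI
taxonomy disagree on identifiers. A record is marine if its binomial is on
the species list or any family in its lineage is on the family list; family
matching intentionally includes terrestrial members of marine families, so
sequences remain assignable at genus/family level where no marine congener
has been sequenced. Records whose lineage lacks a family rank are evaluated
on the species list only and tallied. The contaminant policies: `flag` marks,
`remove` drops (removed records stay in the log, so output ∪ removed
partitions the input), and `merge` keeps matching records flagged and
appended after the rest — the reading of "merge contaminants into the
database" that applies when the contaminant records are already in hand
rather than in a separately built database.

## Composition statistics and β-diversity

`db_stats()` computes, per database: % unique species = unique, fully
identified binomials / total sequences; % marine species = marine species /
unique species. Percentages round **half-up** to two decimals — the
convention that reproduces published composition tables cell for cell (R's
default half-to-even does not). One known caveat: in the published table
these numbers come from, two cells (the BAR-variant unique-species
percentage, printed 4.91 where its own counts give 4.99, and one other
database's 9.10 vs 9.09) are inconsistent with their printed counts at any
2-decimal rounding; the package documents rather than reproduces them.

`jaccard_partition()` decomposes total Jaccard dissimilarity between two
species sets into turnover and nestedness-resultant components:
β_JAC = (b+c)/(a+b+c), β_JTU = 2·min(b,c)/(a+2·min(b,c)),
β_JNE = β_JAC − β_JTU, β_ratio = β_JNE/β_JAC. Species identity is the
canonical binomial string, case-insensitive. β_ratio at β_JAC = 0 is 0/0 and
is surfaced as `NA`, not imputed: identical databases are neither
turnover- nor nestedness-dominated. The implementation is checked in the
test suite against a brute-force membership counter on ≥1000 random set
pairs and against `vegan::vegdist(method = "jaccard", binary = TRUE)` for the
total component, and additivity β_JAC = β_JTU + β_JNE is asserted to 1e-12.

## The fixture generator

`fixture_spec()` describes a miniature study: a taxonomy of
`n_families × n_genera_per_family × n_species_per_genus` species (defaults
3 × 2 × 3 — small enough to hand-check, large enough that every code path has
several exemplars), two repositories sharing `overlap_fraction` (default
0.5) of the species, a `synonym_fraction` (0.2) of species whose BOLD rows
use a planted synonym spelling, a `novel_species_fraction` (0.15) of records
exercising the minting path, `n_unresolvable = 2` drop-path records,
`duplicate_fraction = 0.15` verbatim sequence copies, one contaminant
(*Homo sapiens* by default, under its own non-marine family), a two-entry
blacklist, and 120 bp random ACGT sequences. Duplicates are planted by
copying, not left to chance, so every expected count is exact; at 120 bp the
chance-collision probability is negligible, and the truth table is computed
from the actually generated sequences regardless. The marine checklist is
the first half (ceiling) of the non-contaminant families in TaxID order —
the same deterministic rule the truth table uses. One seed drives
everything; sub-streams use fixed offsets, and identical specs yield
byte-identical files.

The truth table is derived from the generation plan by set logic
(independent of the pipeline code), and the test suite verifies that the
full pipeline recovers every planted count exactly across 20 randomized
specs, alongside a 50-seed taxonomy round-trip identity check. These runs
use dozens-of-records databases: ample to pin the set/count semantics
exactly, which is what the pipeline computes — the operations are
scale-invariant set manipulations, so passing here says the logic is right,
not that repository-scale inputs have been exercised. What the fixtures do
**not** emulate: realistic COI sequence evolution (sequences are uniform
random), amplicon structure or primer bias, ragged metadata, or the name
messiness of real repositories beyond the planted qualifier/synonym cases.

## Numerical and formatting choices

- FASTA wraps at 80 columns; the normalized header layout is
  `accession;taxlabel=<name>;taxid=<id>;gene=<label>`, bit-stable.
- Taxdump output: fields joined by tab-pipe-tab, records terminated by
  tab-pipe, nodes sorted by TaxID, names sorted scientific-first; only the
  tax_id/parent/rank and tax_id/name/class columns are interpreted, the
  remaining taxdump columns are emitted empty.
- Merged/deleted-node files (`merged.dmp`, `delnodes.dmp`) are not handled.
- Minting is purely a function of index state (`max TaxID + 1`), so minted
  ids vary across taxonomy versions by design; replays on the same index are
  identical.
- Degenerate inputs: empty databases export empty text; `db_stats` on zero
  sequences reports `NA` percentages; `jaccard_partition` on two empty sets
  and `interpret_ratio` on `NA` are errors rather than silent zeros.

## Known limitations

- Name matching is exact after case/whitespace normalisation; misspelled
  repository names are dropped rather than rescued.
- Live retrieval (Entrez/BOLD APIs) is out of scope; ingest is file-based,
  with `build_search_terms()` provided for constructing repository queries.
- The GenBank parser covers the LOCUS/ACCESSION/VERSION/ORGANISM/ORIGIN
  subset sufficient for flatfile-to-FASTA conversion, not the full feature
  table.
- Reverse-complement duplicates survive dereplication, as noted above.
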