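# NCBI-style taxonomy: taxdump parsing/writing, name resolution, TaxID minting.

# Name classes eligible for synonym-style matching. "common name" is
# deliberately excluded: vernacular strings collide across kingdoms.
SYNONYM_CLASSES <- c("synonym", "equivalent name", "includes", "genbank synonym")

new_tax_index <- function(nodes, names_tbl, minted_ids = integer()) {
  structure(
    list(
      nodes = nodes,
      names = names_tbl,
      max_tax_id = max(nodes$tax_id),
      minted_ids = as.integer(minted_ids)
    ),
    class = "tax_index"
  )
}

#' @export
print.tax_index <- function(x, ...) {
  cat(sprintf(
    "<tax_index> %d nodes, %d names, max TaxID %d, %d locally minted\n",
    nrow(x$nodes), nrow(x$names), x$max_tax_id, length(x$minted_ids)
  ))
  invisible(x)
}

split_dump_line <- function(line) {
  # taxdump records end with "\t|"; fields are separated by "\t|\t"
  strsplit(sub("\t\\|$", "", line), "\t|\t", fixed = TRUE)[[1]]
}

#' Parse an NCBI-style taxonomy dump
#'
#' Reads `names.dmp` / `nodes.dmp` text in the NCBI taxdump dialect (fields
#' separated by tab-pipe-tab, records terminated by tab-pipe). Only the
#' `tax_id`, `parent`, `rank` (nodes) and `tax_id`, `name_txt`, `name_class`
#' (names) fields are interpreted.
#'
#' @param names_text contents of `names.dmp` as a single string.
#' @param nodes_text contents of `nodes.dmp` as a single string.
#' @return a `tax_index`: a list with tibbles `nodes`
#'   (`tax_id`, `parent_id`, `rank`) and `names`
#'   (`tax_id`, `name_txt`, `name_class`, `name_key`), the current
#'   `max_tax_id`, and an empty `minted_ids` vector.
#' @seealso [format_taxdump()], [resolve_name()], [mint_taxid()]
#' @export
parse_taxdump <- function(names_text, nodes_text) {
  node_lines <- strsplit(nodes_text, "\n", fixed = TRUE)[[1]]
  node_lines <- node_lines[nzchar(node_lines)]
  name_lines <- strsplit(names_text, "\n", fixed = TRUE)[[1]]
  name_lines <- name_lines[nzchar(name_lines)]
  if (length(node_lines) == 0) stop("nodes.dmp is empty: no root node")

  node_fields <- lapply(node_lines, split_dump_line)
  bad <- which(vapply(node_fields, length, 1L) < 3)
  if (length(bad) > 0) {
    stop(sprintf("malformed nodes.dmp line %d: fewer than 3 fields", bad[1]))
  }
  nodes <- tibble(
    tax_id = vapply(node_fields, function(f) as.integer(f[1]), 1L),
    parent_id = vapply(node_fields, function(f) as.integer(f[2]), 1L),
    rank = vapply(node_fields, function(f) f[3], "")
  )
  if (anyNA(nodes$tax_id) || anyNA(nodes$parent_id)) {
    stop("nodes.dmp contains a non-integer tax_id or parent")
  }
  if (anyDuplicated(nodes$tax_id)) {
    dup <- nodes$tax_id[duplicated(nodes$tax_id)][1]
    stop(sprintf("duplicate tax_id %d in nodes.dmp", dup))
  }

  name_fields <- lapply(name_lines, split_dump_line)
  bad <- which(vapply(name_fields, length, 1L) < 4)
  if (length(bad) > 0) {
    stop(sprintf("malformed names.dmp line %d: fewer than 4 fields", bad[1]))
  }
  names_tbl <- tibble(
    tax_id = vapply(name_fields, function(f) as.integer(f[1]), 1L),
    name_txt = vapply(name_fields, function(f) f[2], ""),
    name_class = vapply(name_fields, function(f) f[4], "")
  )
  names_tbl$name_key <- name_key(names_tbl$name_txt)

  idx <- new_tax_index(nodes, names_tbl)
  validate_tax_index(idx)
  idx
}

#' Read a taxonomy dump from files
#' @param names_path path to `names.dmp`.
#' @param nodes_path path to `nodes.dmp`.
#' @return a `tax_index` (see [parse_taxdump()]).
#' @export
read_taxdump <- function(names_path, nodes_path) {
  parse_taxdump(read_text(names_path), read_text(nodes_path))
}

#' Validate tax_index invariants
#'
#' Checks parent references, exactly one scientific name per node, rootedness
#' and acyclicity (every node walks to the root).
#' @param index a `tax_index`.
#' @return the index, invisibly; errors on violation.
#' @export
validate_tax_index <- function(index) {
  nodes <- index$nodes
  missing_parent <- setdiff(nodes$parent_id, nodes$tax_id)
  if (length(missing_parent) > 0) {
    stop(sprintf("parent tax_id %d does not exist", missing_parent[1]))
  }
  sci <- index$names[index$names$name_class == "scientific name", ]
  per_node <- table(sci$tax_id)
  no_name <- setdiff(nodes$tax_id, as.integer(names(per_node)))
  if (length(no_name) > 0) {
    stop(sprintf("node %d has no scientific name", no_name[1]))
  }
  multi <- as.integer(names(per_node)[per_node > 1])
  if (length(multi) > 0) {
    stop(sprintf("node %d has %d scientific names", multi[1],
                 per_node[[as.character(multi[1])]]))
  }
  roots <- nodes$tax_id[nodes$tax_id == nodes$parent_id]
  if (length(roots) != 1) {
    stop(sprintf("taxonomy must have exactly one root, found %d", length(roots)))
  }
  # acyclicity: every node reaches the root within n steps
  parent_of <- setNames(nodes$parent_id, nodes$tax_id)
  n <- nrow(nodes)
  for (id in nodes$tax_id) {
    cur <- id
    steps <- 0L
    while (cur != parent_of[[as.character(cur)]]) {
      cur <- parent_of[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n) stop(sprintf("cycle detected in parent graph at tax_id %d", id))
    }
  }
  if (index$max_tax_id != max(nodes$tax_id)) {
    stop("max_tax_id out of sync with node table")
  }
  invisible(index)
}

scientific_name_of <- function(index, tax_ids) {
  sci <- index$names[index$names$name_class == "scientific name", ]
  sci$name_txt[match(tax_ids, sci$tax_id)]
}

#' Resolve a taxon name to a TaxID
#'
#' Exact match against scientific names first; if none, against synonym-type
#' name classes (`synonym`, `equivalent name`, `includes`, `genbank synonym`,
#' never `common name`). Matching is case-insensitive with internal whitespace
#' collapsed; no fuzzy matching. Homonyms (one name, several TaxIDs) resolve
#' to the candidate whose lineage intersects `focal_tax_ids` if that candidate
#' is unique, otherwise to the lowest TaxID, with `ambiguous = TRUE` so the
#' call can be audited.
#'
#' @param index a `tax_index`.
#' @param name taxon name to resolve.
#' @param focal_tax_ids optional integer vector of focal taxa used to
#'   disambiguate homonyms by lineage.
#' @return one-row tibble: `query`, `tax_id` (NA if unresolved),
#'   `match_class` (one of `exact_scientific`, `synonym`, `unresolved`),
#'   `minted` (always FALSE here; see [mint_taxid()]), `ambiguous`.
#' @export
resolve_name <- function(index, name, focal_tax_ids = NULL) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  key <- name_key(name)
  hit <- function(classes) {
    sort(unique(index$names$tax_id[
      index$names$name_key == key & index$names$name_class %in% classes
    ]))
  }
  ids <- hit("scientific name")
  cls <- "exact_scientific"
  if (length(ids) == 0) {
    ids <- hit(SYNONYM_CLASSES)
    cls <- "synonym"
  }
  if (length(ids) == 0) {
    return(tibble(query = name, tax_id = NA_integer_,
                  match_class = "unresolved", minted = FALSE, ambiguous = FALSE))
  }
  ambiguous <- length(ids) > 1
  chosen <- ids[1]
  if (ambiguous && length(focal_tax_ids) > 0) {
    in_focus <- vapply(ids, function(id) {
      any(lineage(index, id)$tax_id %in% focal_tax_ids)
    }, logical(1))
    if (sum(in_focus) == 1) chosen <- ids[in_focus]
  }
  tibble(query = name, tax_id = as.integer(chosen), match_class = cls,
         minted = FALSE, ambiguous = ambiguous)
}

#' Mint a new species TaxID under a genus
#'
#' Allocates `max_tax_id + 1`, adds a species-rank node with the given genus
#' as parent plus a scientific-name record, and records the id in
#' `minted_ids`. Allocation is deterministic: replaying the same mint sequence
#' on the same index yields identical ids.
#'
#' @param index a `tax_index`.
#' @param species_name binomial to register; must not already resolve.
#' @param genus_tax_id existing TaxID of the parent genus.
#' @return list with elements `index` (updated) and `tax_id` (the minted id).
#' @export
mint_taxid <- function(index, species_name, genus_tax_id) {
  genus_tax_id <- as.integer(genus_tax_id)
  if (!genus_tax_id %in% index$nodes$tax_id) {
    stop(sprintf("genus tax_id %d not present in taxonomy", genus_tax_id))
  }
  res <- resolve_name(index, species_name)
  if (!is.na(res$tax_id)) {
    stop(sprintf("'%s' already resolves to TaxID %d; resolve, don't mint",
                 species_name, res$tax_id))
  }
  new_id <- index$max_tax_id + 1L
  index$nodes <- bind_rows(
    index$nodes,
    tibble(tax_id = new_id, parent_id = genus_tax_id, rank = "species")
  )
  index$names <- bind_rows(
    index$names,
    tibble(tax_id = new_id, name_txt = species_name,
           name_class = "scientific name", name_key = name_key(species_name))
  )
  index$max_tax_id <- new_id
  index$minted_ids <- c(index$minted_ids, new_id)
  list(index = index, tax_id = new_id)
}

#' Lineage of a node, from the node up to the root
#'
#' @param index a `tax_index`.
#' @param tax_id node to start from.
#' @return tibble (`tax_id`, `rank`, `name`), first row the query node, last
#'   the root.
#' @export
lineage <- function(index, tax_id) {
  tax_id <- as.integer(tax_id)
  nodes <- index$nodes
  pos <- match(tax_id, nodes$tax_id)
  if (is.na(pos)) stop(sprintf("unknown tax_id %d", tax_id))
  ids <- integer()
  cur <- pos
  repeat {
    ids <- c(ids, nodes$tax_id[cur])
    parent <- nodes$parent_id[cur]
    if (parent == nodes$tax_id[cur]) break
    cur <- match(parent, nodes$tax_id)
    if (length(ids) > nrow(nodes)) stop("cycle detected in parent graph")
  }
  tibble(
    tax_id = ids,
    rank = nodes$rank[match(ids, nodes$tax_id)],
    name = scientific_name_of(index, ids)
  )
}

#' Expand focal taxa to their subtaxa
#'
#' Resolves each focal name and collects its descendant nodes (the focal node
#' itself is included unless `rank_filter` is given and the focal node matches
#' that rank — "subtaxa" at a requested rank means proper descendants).
#' Results are deduplicated, ordered by ascending TaxID, and returned as
#' scientific names. Unresolvable focal names are reported, not fatal.
#'
#' @param index a `tax_index`.
#' @param focal_names character vector of focal taxon names.
#' @param rank_filter optional rank (e.g. `"species"`) to restrict results.
#' @return character vector of scientific names, with attribute `unresolved`
#'   holding any focal names that did not resolve.
#' @export
expand_subtaxa <- function(index, focal_names, rank_filter = NULL) {
  children_of <- split(index$nodes$tax_id, index$nodes$parent_id)
  collect <- integer()
  unresolved <- character()
  for (nm in focal_names) {
    res <- resolve_name(index, nm)
    if (is.na(res$tax_id)) {
      unresolved <- c(unresolved, nm)
      next
    }
    focal_id <- res$tax_id
    queue <- focal_id
    seen <- focal_id
    while (length(queue) > 0) {
      kids <- unlist(children_of[as.character(queue)], use.names = FALSE)
      kids <- setdiff(kids, seen) # root is its own child; guard self-loops
      seen <- c(seen, kids)
      queue <- kids
    }
    if (!is.null(rank_filter)) {
      focal_rank <- index$nodes$rank[match(focal_id, index$nodes$tax_id)]
      if (identical(focal_rank, rank_filter)) seen <- setdiff(seen, focal_id)
    }
    collect <- c(collect, seen)
  }
  collect <- sort(unique(collect))
  if (!is.null(rank_filter)) {
    ranks <- index$nodes$rank[match(collect, index$nodes$tax_id)]
    collect <- collect[ranks == rank_filter]
  }
  out <- scientific_name_of(index, collect)
  attr(out, "unresolved") <- unresolved
  out
}

#' Serialise a tax_index back to taxdump text
#'
#' Emits the NCBI taxdump dialect with nodes sorted by TaxID and uninterpreted
#' columns empty (nodes lines carry the standard 13 fields, names lines 4).
#' The round trip `parse_taxdump(format_taxdump(x))` reproduces the node set,
#' name set and `max_tax_id`, including locally minted nodes.
#'
#' @param index a `tax_index`.
#' @return list with elements `names` and `nodes`, each a single string.
#' @export
format_taxdump <- function(index) {
  nodes <- arrange(index$nodes, .data$tax_id)
  node_lines <- sprintf(
    "%d\t|\t%d\t|\t%s\t|\t%s\t|",
    nodes$tax_id, nodes$parent_id, nodes$rank,
    paste(rep("", 10), collapse = "\t|\t")
  )
  nm <- index$names %>%
    mutate(class_order = if_else(.data$name_class == "scientific name", 0L, 1L)) %>%
    arrange(.data$tax_id, .data$class_order, .data$name_class, .data$name_txt)
  name_lines <- sprintf(
    "%d\t|\t%s\t|\t\t|\t%s\t|",
    nm$tax_id, nm$name_txt, nm$name_class
  )
  list(
    names = paste0(paste(name_lines, collapse = "\n"), "\n"),
    nodes = paste0(paste(node_lines, collapse = "\n"), "\n")
  )
}

#' Write a tax_index to names.dmp / nodes.dmp files
#' @param index a `tax_index`.
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
write_taxdump <- function(index, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  txt <- format_taxdump(index)
  names_path <- file.path(dir, "names.dmp")
  nodes_path <- file.path(dir, "nodes.dmp")
  writeLines(sub("\n$", "", txt$names), names_path)
  writeLines(sub("\n$", "", txt$nodes), nodes_path)
  invisible(c(names = names_path, nodes = nodes_path))
}
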