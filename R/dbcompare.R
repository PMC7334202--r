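# Database comparison: composition statistics and partitioned Jaccard
# beta-diversity (total dissimilarity split into turnover and
# nestedness-resultant components, Baselga-style), computed on
# presence/absence of species binomials.

#' Unique species binomials of a database
#'
#' Only fully identified, species-level binomials count: genus-level and
#' unusable names are excluded. Identity is the canonical binomial string,
#' case-insensitive (TaxIDs are not comparable across independently normalized
#' databases).
#'
#' @param db normalized record tibble.
#' @return character vector of unique binomials (first-seen capitalisation),
#'   sorted.
#' @export
species_set <- function(db) {
  sp <- db$canonical_name[db$level == "species" & !is.na(db$canonical_name)]
  sort(sp[!duplicated(name_key(sp))])
}

#' Composition statistics of a reference database
#'
#' "% unique species" is the number of unique species over the total number of
#' sequences; "% marine species" is the number of marine species over the
#' number of unique species. Percentages are rounded half-up to 2 decimals.
#'
#' @param db normalized, marine-screened record tibble.
#' @return one-row tibble (`db_stats`): `n_sequences`, `n_unique_species`,
#'   `pct_unique_species`, `n_marine_species`, `pct_marine_species`.
#' @export
db_stats <- function(db) {
  species <- species_set(db)
  marine_sp <- db$canonical_name[db$level == "species" & has_flag(db, "marine") &
                                   !is.na(db$canonical_name)]
  db_stats_from_counts(
    n_sequences = nrow(db),
    n_unique_species = length(species),
    n_marine_species = dplyr::n_distinct(name_key(marine_sp))
  )
}

#' Composition percentages from raw counts
#'
#' The percentage formulas applied directly to counts — useful for published
#' tables where the counts are printed but the database itself is not in hand.
#'
#' @param n_sequences total sequences.
#' @param n_unique_species unique, fully identified species.
#' @param n_marine_species unique species present on the marine checklist.
#' @return one-row tibble of class `db_stats`; percentages are `NA` when their
#'   denominator is zero.
#' @export
#' @examples
#' db_stats_from_counts(1491691, 71499, 19154) # 4.79% unique, 26.79% marine
db_stats_from_counts <- function(n_sequences, n_unique_species, n_marine_species) {
  stopifnot(n_marine_species <= n_unique_species, n_unique_species <= n_sequences)
  out <- tibble(
    n_sequences = as.integer(n_sequences),
    n_unique_species = as.integer(n_unique_species),
    pct_unique_species = if (n_sequences > 0)
      round_half_up(100 * n_unique_species / n_sequences, 2) else NA_real_,
    n_marine_species = as.integer(n_marine_species),
    pct_marine_species = if (n_unique_species > 0)
      round_half_up(100 * n_marine_species / n_unique_species, 2) else NA_real_
  )
  class(out) <- c("db_stats", class(out))
  out
}

#' Partitioned Jaccard dissimilarity for one pair of species sets
#'
#' With `a` the number of shared species, `b` and `c` the numbers unique to
#' each set:
#' \deqn{\beta_{JAC} = (b+c)/(a+b+c)}
#' \deqn{\beta_{JTU} = 2\min(b,c)/(a + 2\min(b,c))}
#' \deqn{\beta_{JNE} = \beta_{JAC} - \beta_{JTU}}
#' \deqn{\beta_{ratio} = \beta_{JNE}/\beta_{JAC}}
#' The turnover component measures species substitution; the
#' nestedness-resultant component measures richness difference when one set is
#' (partly) nested in the other. The ratio is undefined (`NA`) for identical
#' sets (0/0).
#'
#' @param set_a,set_b character vectors of species names (case-insensitive);
#'   at least one must be non-empty.
#' @return one-row tibble: `shared`, `only_a`, `only_b`, `beta_jac`,
#'   `beta_jtu`, `beta_jne`, `beta_ratio`.
#' @export
#' @examples
#' jaccard_partition(c("w", "x", "y", "z"), c("w", "x")) # pure nestedness
jaccard_partition <- function(set_a, set_b) {
  ka <- unique(name_key(set_a))
  kb <- unique(name_key(set_b))
  ka <- ka[nzchar(ka)]
  kb <- kb[nzchar(kb)]
  if (length(ka) + length(kb) == 0) {
    stop("both species sets are empty; the partition is undefined")
  }
  a <- length(intersect(ka, kb))
  b <- length(setdiff(ka, kb))
  c_ <- length(setdiff(kb, ka))
  beta_jac <- (b + c_) / (a + b + c_)
  m <- min(b, c_)
  beta_jtu <- if (a + 2 * m == 0) 0 else 2 * m / (a + 2 * m)
  beta_jne <- beta_jac - beta_jtu
  tibble(
    shared = a, only_a = b, only_b = c_,
    beta_jac = beta_jac, beta_jtu = beta_jtu, beta_jne = beta_jne,
    beta_ratio = if (beta_jac == 0) NA_real_ else beta_jne / beta_jac
  )
}

#' Pairwise partitioned beta-diversity across databases
#'
#' @param sets a named list of at least two species sets (character vectors),
#'   or of normalized record tibbles (converted via [species_set()]).
#' @return object of class `beta_matrices`: list of symmetric matrices
#'   `beta_jac`, `beta_jtu`, `beta_jne`, `beta_ratio` (diagonals 0; the
#'   `beta_ratio` diagonal is `NA`), plus `pairs`, a long tibble of all pairs.
#' @export
pairwise_beta <- function(sets) {
  if (length(sets) < 2) stop("need at least two databases to compare")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("db", seq_along(sets))
  }
  sets <- lapply(sets, function(s) if (is.data.frame(s)) species_set(s) else s)
  k <- length(sets)
  nm <- names(sets)
  mk <- function(diag_val) {
    m <- matrix(diag_val, k, k, dimnames = list(nm, nm))
    m
  }
  m_jac <- mk(0); m_jtu <- mk(0); m_jne <- mk(0); m_ratio <- mk(NA_real_)
  pairs <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- jaccard_partition(sets[[i]], sets[[j]])
      m_jac[i, j] <- m_jac[j, i] <- p$beta_jac
      m_jtu[i, j] <- m_jtu[j, i] <- p$beta_jtu
      m_jne[i, j] <- m_jne[j, i] <- p$beta_jne
      m_ratio[i, j] <- m_ratio[j, i] <- p$beta_ratio
      pairs[[length(pairs) + 1]] <- mutate(p, db_a = nm[i], db_b = nm[j],
                                           .before = 1)
    }
  }
  structure(
    list(beta_jac = m_jac, beta_jtu = m_jtu, beta_jne = m_jne,
         beta_ratio = m_ratio, pairs = bind_rows(pairs)),
    class = "beta_matrices"
  )
}

#' @export
print.beta_matrices <- function(x, ...) {
  cat(sprintf("<beta_matrices> %d databases, %d pairs\n",
              nrow(x$beta_jac), nrow(x$pairs)))
  print(round(x$beta_jac, 3))
  invisible(x)
}

#' @export
tidy.beta_matrices <- function(x, ...) {
  tidyr::pivot_longer(x$pairs, cols = dplyr::starts_with("beta_"),
                      names_to = "component", values_to = "value")
}

#' Presence/absence matrix of species across databases
#' @param sets named list of species sets or record tibbles.
#' @return tibble, one row per species, one 0/1 column per database.
#' @export
presence_absence <- function(sets) {
  sets <- lapply(sets, function(s) if (is.data.frame(s)) species_set(s) else s)
  if (is.null(names(sets))) names(sets) <- paste0("db", seq_along(sets))
  all_sp <- sort(unique(unlist(lapply(sets, name_key))))
  out <- tibble(species = all_sp)
  for (nm in names(sets)) {
    out[[nm]] <- as.integer(all_sp %in% name_key(sets[[nm]]))
  }
  out
}

#' Classify a beta-ratio as turnover- or nestedness-dominated
#'
#' Below 0.5 the turnover component dominates the dissimilarity (the
#' databases contain different species); above 0.5 the nestedness-resultant
#' component dominates (differences are driven by richness, one database
#' largely containing the other); exactly 0.5 is balanced.
#'
#' @param beta_ratio numeric vector of defined ratios (no `NA`).
#' @return character vector: `"turnover_dominated"`, `"nestedness_dominated"`,
#'   or `"balanced"`.
#' @export
#' @examples
#' interpret_ratio(c(0.04, 0.92, 0.5))
interpret_ratio <- function(beta_ratio) {
  if (any(is.na(beta_ratio))) {
    stop("beta_ratio is undefined (identical sets); cannot classify")
  }
  dplyr::case_when(
    beta_ratio < 0.5 ~ "turnover_dominated",
    beta_ratio > 0.5 ~ "nestedness_dominated",
    TRUE ~ "balanced"
  )
}
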