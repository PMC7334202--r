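# ggplot2 displays for comparison results and pipeline audit trails.

#' Heatmap of pairwise beta-diversity matrices
#'
#' One tile panel per component (total Jaccard dissimilarity, turnover,
#' nestedness-resultant, and their ratio).
#' @param object a `beta_matrices` result from [pairwise_beta()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.beta_matrices <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$db_a, y = .data$db_b,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::facet_wrap(~.data$component) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "value",
                  title = "Pairwise beta-diversity between databases") +
    ggplot2::theme_minimal()
}

#' Record counts along the derivation chain
#'
#' @param db a refdb that has been through one or more pipeline steps.
#' @return a ggplot of record counts per step.
#' @export
plot_derivation <- function(db) {
  lg <- derivation_log(db)
  if (nrow(lg) == 0) stop("database has no derivation log")
  lg$step <- factor(lg$step, levels = lg$step)
  ggplot2::ggplot(lg, ggplot2::aes(x = .data$step, y = .data$n_out, group = 1)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.8, size = 3) +
    ggplot2::labs(x = NULL, y = "records after step",
                  title = "Database derivation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Composition bars for one or more databases
#'
#' @param stats a `db_stats` row or several bound together, with an optional
#'   `database` column naming each.
#' @return a ggplot of unique-species and marine-species percentages.
#' @export
plot_db_stats <- function(stats) {
  if (!"database" %in% names(stats)) {
    stats$database <- paste0("db", seq_len(nrow(stats)))
  }
  long <- tidyr::pivot_longer(stats,
                              cols = c("pct_unique_species", "pct_marine_species"),
                              names_to = "metric", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$database, y = .data$pct,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "percent",
                  title = "Database composition") +
    ggplot2::theme_minimal()
}
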