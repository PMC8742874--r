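# Category-summary plot: stacked per-class motif-presence percentages per
# gene category, alongside the random-gene-set expectation.

#' Stacked bar plot of per-category motif presence
#'
#' One bar per gene category showing the percent of genes with a motif,
#' stacked by gene class (UTR only / CDS only / both / intron only), in the
#' style of per-category motif-landscape summaries. Optionally adds bars
#' for the random-set expectation (mean percent per set size).
#'
#' @param category_stats A tibble of [category_percent()] rows, one per
#'   category, with a `category` column naming each.
#' @param expected Optional [expected_percent()] result; drawn as extra
#'   bars labelled by set size.
#' @return A ggplot object.
#' @export
plot_category_breakdown <- function(category_stats, expected = NULL) {
  stopifnot("category" %in% names(category_stats))
  cls <- intersect(paste0("percent_", setdiff(GENE_CLASSES, "none")),
                   names(category_stats))
  long <- category_stats |>
    select("category", all_of(cls)) |>
    tidyr::pivot_longer(-"category", names_to = "class",
                        values_to = "percent") |>
    mutate(class = sub("^percent_", "", .data$class))
  p <- ggplot(long, aes(x = .data$category, y = .data$percent,
                        fill = .data$class)) +
    geom_col(position = position_stack()) +
    labs(x = NULL, y = "% of genes with motif", fill = "motif location") +
    theme_minimal()
  if (!is.null(expected)) {
    exp_d <- tidy(expected) |>
      transmute(category = sprintf("expected (n=%d)", .data$set_size),
                class = "expected", percent = .data$mean_percent)
    p <- p + geom_col(data = exp_d, position = position_stack())
  }
  p
}
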