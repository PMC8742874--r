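# Gene-level motif-presence summaries, per-category percentages with a
# random-gene-set Monte-Carlo expectation, and two-motif co-occurrence.

GENE_CLASSES <- c("UTR_only", "CDS_only", "UTR_and_CDS", "intron_only",
                  "exon_only", "none")

#' Summarise motif presence per gene
#'
#' Collapses annotated hits to one row per (gene, motif) with region
#' booleans and a single class: `UTR_and_CDS` when the gene has both a
#' UTR-region hit and a CDS hit, else `UTR_only` / `CDS_only`,
#' `intron_only` when only intronic hits exist, and `none` when the gene has
#' no hit of that motif. Genes whose only hits fall in exonic sequence
#' without CDS/UTR sub-annotation (e.g. non-coding transcripts) are classed
#' `exon_only`. The `intron` flag is true whenever any intronic hit exists,
#' whatever the class.
#'
#' @param ahits Region-classified hits from [classify_regions()] /
#'   [annotate_hits()].
#' @param ann The [gene_annotation()] object; every annotated gene gets a
#'   summary row (class `none` if it has no hits).
#' @param motifs Motif names to summarise; defaults to those present in
#'   `ahits`. A requested motif absent from the hits yields all-`none`
#'   summaries (with a message).
#' @return A tibble with columns `gene_id`, `motif`, `has_5UTR`, `has_3UTR`,
#'   `has_CDS`, `has_exon`, `has_intron`, `class`.
#' @export
summarize_genes <- function(ahits, ann, motifs = NULL) {
  stopifnot(inherits(ann, "gene_annotation"))
  motifs <- motifs %||% sort(unique(ahits$motif))
  if (length(motifs) == 0) abort("no motifs to summarise")
  missing <- setdiff(motifs, unique(ahits$motif))
  if (length(missing)) {
    inform(sprintf("motif(s) with no hits, summarised as all-none: %s",
                   paste(missing, collapse = ", ")))
  }
  grid <- expand_grid(gene_id = ann$genes$gene_id, motif = motifs)
  flags <- ahits |>
    filter(.data$motif %in% motifs) |>
    group_by(.data$gene_id, .data$motif) |>
    summarise(has_5UTR = any(.data$in_5UTR), has_3UTR = any(.data$in_3UTR),
              has_CDS = any(.data$in_CDS), has_exon = any(.data$in_exon),
              has_intron = any(.data$in_intron), .groups = "drop")
  grid |>
    left_join(flags, by = c("gene_id", "motif")) |>
    mutate(across(starts_with("has_"), ~ replace_na(.x, FALSE))) |>
    mutate(class = case_when(
      (has_5UTR | has_3UTR) & has_CDS ~ "UTR_and_CDS",
      has_5UTR | has_3UTR ~ "UTR_only",
      has_CDS ~ "CDS_only",
      has_intron ~ "intron_only",
      has_exon ~ "exon_only",
      .default = "none"
    ))
}

# motif-presence indicator under a region scope
has_motif_flag <- function(summaries, scope = c("any", "utr_cds")) {
  scope <- match.arg(scope)
  if (scope == "any") summaries$class != "none"
  else summaries$has_5UTR | summaries$has_3UTR | summaries$has_CDS
}

#' Percent of genes in a category carrying a motif
#'
#' The observed statistic behind per-category motif summaries: the percent
#' of genes in a set with at least one motif instance, with a breakdown by
#' gene class.
#'
#' @param summaries Output of [summarize_genes()].
#' @param gene_set Character vector of gene ids (the category). Genes absent
#'   from the summaries are ignored with a message; an empty set is an
#'   error.
#' @param motif Motif name (defaults to the single motif in `summaries`).
#' @param scope Which hits count as "has a motif": `"any"` region (default)
#'   or `"utr_cds"` (UTR or CDS hits only).
#' @return A one-row tibble: `motif`, `n_genes`, `percent_with_motif`, and
#'   `percent_<class>` breakdown columns (breakdown percents over the same
#'   denominator sum to `percent_with_motif`).
#' @export
category_percent <- function(summaries, gene_set, motif = NULL,
                             scope = c("any", "utr_cds")) {
  scope <- match.arg(scope)
  motif <- motif %||% single_motif(summaries)
  s <- filter(summaries, .data$motif == !!motif)
  if (length(gene_set) == 0) abort("empty gene set")
  unknown <- setdiff(gene_set, s$gene_id)
  if (length(unknown)) {
    inform(sprintf("%d gene(s) in the set are not in the annotation; ignored",
                   length(unknown)))
  }
  gene_set <- unique(intersect(gene_set, s$gene_id))
  if (length(gene_set) == 0) abort("no genes of the set are annotated")
  s <- filter(s, .data$gene_id %in% gene_set)
  n <- nrow(s)
  withm <- has_motif_flag(s, scope)
  breakdown <- vapply(setdiff(GENE_CLASSES, "none"),
                      function(cl) 100 * sum(s$class == cl) / n, numeric(1))
  out <- tibble(motif = motif, n_genes = n,
                percent_with_motif = 100 * sum(withm) / n,
                percent_with_intron_motif = 100 * sum(s$has_intron) / n)
  for (cl in names(breakdown)) out[[paste0("percent_", cl)]] <- breakdown[[cl]]
  out
}

single_motif <- function(summaries) {
  m <- unique(summaries$motif)
  if (length(m) != 1) abort("several motifs present; give `motif` explicitly")
  m
}

#' Random-gene-set expectation of motif presence
#'
#' Monte-Carlo expectation for category percentages: for each requested set
#' size, draws `n_sims` random gene sets of that size (without replacement,
#' from all annotated genes) and records the percent of genes with a motif
#' in each, reporting the mean and standard deviation per size. Sampling
#' without replacement makes the mean an unbiased estimate of the population
#' fraction at every size.
#'
#' @inheritParams category_percent
#' @param set_sizes Integer vector of set sizes. Default
#'   `c(100, 500, 1000, 3000)`.
#' @param n_sims Number of random sets per size; default 150.
#' @param seed Integer seed for reproducible draws (optional).
#' @return An `expected_stat` tibble: `motif`, `set_size`, `n_sims`,
#'   `mean_percent`, `sd_percent`; attributes `seed` and `scope`.
#' @export
expected_percent <- function(summaries, motif = NULL,
                             set_sizes = c(100, 500, 1000, 3000),
                             n_sims = 150, seed = NULL,
                             scope = c("any", "utr_cds")) {
  scope <- match.arg(scope)
  motif <- motif %||% single_motif(summaries)
  if (n_sims < 1) abort("n_sims must be >= 1")
  s <- filter(summaries, .data$motif == !!motif)
  flags <- has_motif_flag(s, scope)
  n_pop <- length(flags)
  if (any(set_sizes > n_pop)) {
    abort(sprintf("set size %d exceeds the %d annotated genes",
                  max(set_sizes), n_pop))
  }
  if (any(set_sizes < 1)) abort("set sizes must be >= 1")
  draw <- function() {
    map(set_sizes, function(sz) {
      pct <- vapply(seq_len(n_sims), function(i) {
        100 * mean(flags[sample.int(n_pop, sz)])
      }, numeric(1))
      tibble(set_size = sz, n_sims = n_sims,
             mean_percent = mean(pct), sd_percent = sd(pct))
    }) |> list_rbind()
  }
  res <- if (is.null(seed)) draw() else with_seed(seed, draw())
  res <- mutate(res, motif = motif, .before = 1)
  structure(res, seed = seed, scope = scope,
            class = c("expected_stat", class(res)))
}

#' @exportS3Method generics::tidy
tidy.expected_stat <- function(x, ...) as_tibble(unclass(x))

#' @exportS3Method generics::glance
glance.expected_stat <- function(x, ...) {
  tibble(motif = x$motif[1], n_sizes = nrow(x), n_sims = x$n_sims[1],
         seed = attr(x, "seed") %||% NA_integer_, scope = attr(x, "scope"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.expected_stat <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = factor(.data$set_size), y = .data$mean_percent)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$mean_percent - .data$sd_percent,
                      ymax = .data$mean_percent + .data$sd_percent),
                  width = 0.2) +
    labs(x = "random set size (genes)",
         y = "% of genes with motif (mean ± sd)",
         title = sprintf("Expected %s motif frequency in random gene sets",
                         d$motif[1])) +
    theme_minimal()
}

#' Percent of genes carrying both of two motifs
#'
#' Two-motif co-occurrence: the percent of genes with instances of both
#' motif A and motif B. By default the denominator is the set of genes with
#' at least one instance of either motif (the conditioning used when
#' comparing e.g. sarcomere genes against all genes); `denominator = "all"`
#' uses every gene considered.
#'
#' @param summaries_a,summaries_b [summarize_genes()] outputs for the two
#'   motifs (over the same annotation).
#' @param gene_set Optional character vector restricting the universe of
#'   genes (e.g. a category) before the denominator rule is applied.
#' @param denominator `"either"` (default: genes with >= 1 motif of either)
#'   or `"all"`.
#' @inheritParams category_percent
#' @return A one-row tibble: `n_universe`, `n_denominator`, `n_both`,
#'   `percent_both`, `denominator`.
#' @export
cooccurrence_fraction <- function(summaries_a, summaries_b, gene_set = NULL,
                                  denominator = c("either", "all"),
                                  scope = c("any", "utr_cds")) {
  denominator <- match.arg(denominator)
  scope <- match.arg(scope)
  a <- summaries_a |> mutate(has = has_motif_flag(summaries_a, scope)) |>
    select("gene_id", has_a = "has")
  b <- summaries_b |> mutate(has = has_motif_flag(summaries_b, scope)) |>
    select("gene_id", has_b = "has")
  d <- inner_join(a, b, by = "gene_id")
  if (!is.null(gene_set)) d <- filter(d, .data$gene_id %in% gene_set)
  n_universe <- nrow(d)
  denom <- if (denominator == "either") filter(d, .data$has_a | .data$has_b) else d
  if (nrow(denom) == 0) abort("empty denominator gene set")
  n_both <- sum(denom$has_a & denom$has_b)
  tibble(n_universe = n_universe, n_denominator = nrow(denom),
         n_both = n_both, percent_both = 100 * n_both / nrow(denom),
         denominator = denominator)
}
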