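# Gene-level motif classes, category percentages, the random-gene-set
# expectation and two-motif co-occurrence.

# minimal annotated-hit rows for class logic, bypassing the scan
fake_ahit <- function(gene, motif, region) {
  tibble::tibble(
    motif = motif, seq_id = "chr1", start = 0L, end = 6L, strand = "+",
    score = 0, gene_id = gene, gene_strand = "+",
    in_exon = region %in% c("exon", "CDS", "5UTR", "3UTR"),
    in_CDS = region == "CDS", in_5UTR = region == "5UTR",
    in_3UTR = region == "3UTR", in_intron = region == "intron",
    regions = region)
}

fake_ann <- function(gene_ids) {
  n <- length(gene_ids)
  gene_annotation(
    tibble::tibble(gene_id = gene_ids, seq_id = "chr1",
                   start = seq(0L, by = 1000L, length.out = n),
                   end = seq(900L, by = 1000L, length.out = n), strand = "+"),
    tibble::tibble(transcript_id = paste0("t_", gene_ids), gene_id = gene_ids,
                   seq_id = "chr1", start = seq(0L, by = 1000L, length.out = n),
                   end = seq(900L, by = 1000L, length.out = n), strand = "+"),
    tibble::tibble(transcript_id = paste0("t_", gene_ids), gene_id = gene_ids,
                   seq_id = "chr1", start = seq(0L, by = 1000L, length.out = n),
                   end = seq(900L, by = 1000L, length.out = n), strand = "+",
                   type = "exon"))
}

test_that("gene classes follow the UTR/CDS/intron hierarchy", {
  ann <- fake_ann(c("gA", "gB", "gC", "gD"))
  ahits <- dplyr::bind_rows(
    fake_ahit("gA", "m", "3UTR"),                       # UTR_only
    fake_ahit("gB", "m", "CDS"), fake_ahit("gB", "m", "intron"), # CDS_only + flag
    fake_ahit("gC", "m", "5UTR"), fake_ahit("gC", "m", "CDS"))   # UTR_and_CDS
  s <- summarize_genes(ahits, ann)
  cls <- setNames(s$class, s$gene_id)
  expect_equal(unname(cls[c("gA", "gB", "gC", "gD")]),
               c("UTR_only", "CDS_only", "UTR_and_CDS", "none"))
  expect_true(s$has_intron[s$gene_id == "gB"])
  expect_false(s$has_intron[s$gene_id == "gA"])
  # exactly one class per (gene, motif); counts partition the gene set
  expect_equal(nrow(s), 4L)
  expect_equal(sum(table(s$class)), 4L)
})

test_that("category percent is the fraction of genes with any motif", {
  ids <- sprintf("g%02d", 1:10)
  ann <- fake_ann(ids)
  ahits <- purrr::map(ids[1:4], fake_ahit, motif = "m", region = "CDS") |>
    purrr::list_rbind()
  s <- summarize_genes(ahits, ann)
  cp <- category_percent(s, ids)
  expect_equal(cp$percent_with_motif, 40)
  expect_equal(cp$percent_CDS_only, 40)
  expect_equal(cp$n_genes, 10L)

  # all-none set
  cp0 <- category_percent(s, ids[5:10])
  expect_equal(cp0$percent_with_motif, 0)
  expect_error(category_percent(s, character(0)), "empty")
})

test_that("a planted 7-in-20 category reads out 35%", {
  ids <- sprintf("g%02d", 1:20)
  ann <- fake_ann(ids)
  withm <- sample(ids, 7)
  ahits <- purrr::map(withm, fake_ahit, motif = "m", region = "intron") |>
    purrr::list_rbind()
  s <- summarize_genes(ahits, ann)
  expect_equal(category_percent(s, ids)$percent_with_motif, 35)
  expect_equal(category_percent(s, ids)$percent_intron_only, 35)
})

test_that("breakdown percents sum to the percent with motif", {
  withr::with_seed(61, {
    g <- make_genome(genome_spec(n_seqs = 1, seq_length = 80000, n_genes = 25))
    pl <- plant_motifs(g, plant_spec(), seed = 3)
    ah <- suppressMessages(
      annotate_hits(scan_motif_set(pl$sequences, plant_spec()$motifs),
                    g$annotation))
    s <- summarize_genes(ah, g$annotation, motifs = "Rbfox1")
    cp <- category_percent(s, g$annotation$genes$gene_id)
    parts <- cp$percent_UTR_only + cp$percent_CDS_only +
      cp$percent_UTR_and_CDS + cp$percent_intron_only + cp$percent_exon_only
    expect_equal(parts, cp$percent_with_motif, tolerance = 1e-9)
  })
})

test_that("expected_percent with one full-population draw is exact", {
  s <- make_flag_summaries(500, 200)
  e <- expected_percent(s, set_sizes = 500, n_sims = 1, seed = 1)
  expect_equal(e$mean_percent, 40)
  expect_true(is.na(e$sd_percent) || e$sd_percent == 0)
})

test_that("expected_percent is unbiased within Monte-Carlo error", {
  n_pop <- 2000; f <- 0.25
  s <- make_flag_summaries(n_pop, n_pop * f)
  e <- expected_percent(s, set_sizes = c(100, 500), n_sims = 150, seed = 42)
  for (i in seq_len(nrow(e))) {
    sz <- e$set_size[i]
    se_hat <- 100 * sqrt(f * (1 - f) / sz * (n_pop - sz) / (n_pop - 1)) /
      sqrt(150)
    expect_lt(abs(e$mean_percent[i] - 100 * f), 3 * se_hat)
  }
  # hypergeometric variance ordering
  expect_lt(e$sd_percent[2], e$sd_percent[1])
})

test_that("expected_percent validates sizes and reproduces under a seed", {
  s <- make_flag_summaries(50, 10)
  expect_error(expected_percent(s, set_sizes = 100), "exceeds")
  e1 <- expected_percent(s, set_sizes = c(10, 25), n_sims = 20, seed = 7)
  e2 <- expected_percent(s, set_sizes = c(10, 25), n_sims = 20, seed = 7)
  expect_identical(tidy(e1), tidy(e2))
})

test_that("adding a motif-bearing gene never lowers the category percent", {
  s <- make_flag_summaries(100, 30)
  base_set <- s$gene_id[c(1:10, 51:70)]
  p0 <- category_percent(s, base_set)$percent_with_motif
  p1 <- category_percent(s, c(base_set, s$gene_id[11]))$percent_with_motif
  expect_gte(p1, p0)
})

test_that("co-occurrence fractions mirror the printed arithmetic", {
  # 20 genes, 9 with both motifs -> 45%
  a <- make_flag_summaries(20, 12, motif = "A")
  b <- make_flag_summaries(20, 9, motif = "B")  # first 9 overlap the 12
  cc <- cooccurrence_fraction(a, b, denominator = "all")
  expect_equal(cc$percent_both, 45)
  expect_equal(cc$n_both, 9L)

  # disjoint motif gene sets -> 0% whatever the denominator
  a3 <- make_flag_summaries(20, 10, motif = "A")
  b3 <- make_flag_summaries(20, 0, motif = "B") |>
    dplyr::mutate(has_CDS = dplyr::row_number() > 10,
                  class = ifelse(has_CDS, "CDS_only", "none"))
  expect_equal(cooccurrence_fraction(a3, b3)$percent_both, 0)
  none <- make_flag_summaries(20, 0, motif = "B")
  expect_error(cooccurrence_fraction(none, none), "empty")
})

test_that("co-occurrence estimates a planted joint probability", {
  withr::with_seed(77, {
    n <- 1000
    both <- stats::runif(n) < 0.30
    a_only <- !both & stats::runif(n) < 0.2
    b_only <- !both & !a_only & stats::runif(n) < 0.2
    a <- make_flag_summaries(n, 0, motif = "A") |>
      dplyr::mutate(has_CDS = both | a_only,
                    class = ifelse(has_CDS, "CDS_only", "none"))
    b <- make_flag_summaries(n, 0, motif = "B") |>
      dplyr::mutate(has_CDS = both | b_only,
                    class = ifelse(has_CDS, "CDS_only", "none"))
    cc <- cooccurrence_fraction(a, b, denominator = "all")
    se <- 100 * sqrt(0.3 * 0.7 / n)
    expect_lt(abs(cc$percent_both - 30), 3 * se)
  })
})
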