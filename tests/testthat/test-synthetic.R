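# The fixture generators: structural invariants, determinism, round-trips
# through the format readers, and ground-truth recovery.

test_that("generated genomes satisfy the annotation invariants", {
  g <- make_genome(genome_spec(n_seqs = 2, seq_length = 50000, n_genes = 15),
                   seed = 101)
  ann <- g$annotation
  expect_equal(nrow(ann$genes), 15L)
  # genes do not overlap within a sequence
  by_seq <- split(ann$genes, ann$genes$seq_id)
  for (d in by_seq) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  # exons lie within gene spans; introns are the exon complement
  f <- dplyr::inner_join(ann$features,
                         dplyr::select(ann$genes, gene_id,
                                       g_start = start, g_end = end),
                         by = "gene_id")
  expect_true(all(f$start >= f$g_start & f$end <= f$g_end))
  spans <- f |>
    dplyr::filter(type %in% c("exon", "intron")) |>
    dplyr::group_by(gene_id, type) |>
    dplyr::summarise(len = sum(end - start), .groups = "drop") |>
    tidyr::pivot_wider(names_from = type, values_from = len,
                       values_fill = 0) |>
    dplyr::inner_join(dplyr::mutate(ann$genes, span = end - start),
                      by = "gene_id")
  expect_equal(spans$exon + spans$intron, spans$span)
  # every gene has 5'UTR, 3'UTR and CDS
  counts <- dplyr::count(ann$features, gene_id, type)
  for (ty in c("5UTR", "3UTR", "CDS")) {
    expect_setequal(counts$gene_id[counts$type == ty], ann$genes$gene_id)
  }
})

test_that("an infeasible genome spec errors before writing", {
  expect_error(make_genome(genome_spec(n_seqs = 1, seq_length = 2000,
                                       n_genes = 50), seed = 1),
               "infeasible")
})

test_that("genome generation is byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  g1 <- make_genome(genome_spec(n_genes = 10), seed = 77, dir = d1)
  g2 <- make_genome(genome_spec(n_genes = 10), seed = 77, dir = d2)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$annotation$features, g2$annotation$features)
  expect_identical(readLines(g1$files["fasta"]), readLines(g2$files["fasta"]))
  expect_identical(readLines(g1$files["gff3"]), readLines(g2$files["gff3"]))
})

test_that("generated files round-trip through the format readers", {
  d <- tempfile()
  g <- make_genome(genome_spec(n_seqs = 1, seq_length = 40000, n_genes = 8),
                   seed = 55, dir = d)
  fa <- read_fasta(g$files["fasta"])
  expect_equal(fa, g$sequences)
  ann <- read_gff3(g$files["gff3"])
  expect_equal(ann$genes, g$annotation$genes)
  expect_equal(ann$transcripts, g$annotation$transcripts)
  expect_equal(dplyr::arrange(ann$features, gene_id, type, start),
               dplyr::arrange(g$annotation$features, gene_id, type, start))
})

test_that("planted motifs are recovered exactly by a consensus scan", {
  g <- make_genome(genome_spec(n_seqs = 1, seq_length = 60000, n_genes = 18),
                   seed = 31)
  pl <- plant_motifs(g, plant_spec(), seed = 32)
  hits <- scan_motif_set(pl$sequences, plant_spec()$motifs)
  tr <- dplyr::arrange(pl$truth[, c("motif", "seq_id", "start", "end",
                                    "strand")],
                       motif, seq_id, start)
  sc <- dplyr::arrange(hits[, c("motif", "seq_id", "start", "end", "strand")],
                       motif, seq_id, start)
  expect_equal(as.data.frame(sc), as.data.frame(tr))
  # planted instances lie wholly inside their declared region
  feats <- pl$annotation$features
  inside <- purrr::map_lgl(seq_len(nrow(pl$truth)), function(i) {
    t <- pl$truth[i, ]
    any(feats$gene_id == t$gene_id & feats$type == t$region &
          feats$start <= t$start & feats$end >= t$end)
  })
  expect_true(all(inside))
})

test_that("planting probability zero yields zero hits", {
  g <- make_genome(genome_spec(n_seqs = 1, seq_length = 20000, n_genes = 5),
                   seed = 41)
  spec0 <- plant_spec(motifs = list(
    Rbfox1 = list(consensus = "TGCATG", p_5UTR = 0, p_3UTR = 0, p_CDS = 0,
                  p_intron = 0)))
  pl <- plant_motifs(g, spec0, seed = 42)
  expect_equal(nrow(pl$truth), 0L)
  hits <- scan_motifs(pl$sequences,
                      settings = scan_settings("consensus", iupac = "TGCATG",
                                               both_strands = TRUE))
  expect_equal(nrow(hits), 0L)
})

test_that("coupled planting keeps B within the declared distance of A", {
  g <- make_genome(genome_spec(n_seqs = 1, seq_length = 80000, n_genes = 20),
                   seed = 51)
  spec <- plant_spec(
    motifs = list(
      Rbfox1 = list(consensus = "TGCATG", p_3UTR = 0.8, p_intron = 0.8),
      Bru1 = list(consensus = "TGTTGT", p_3UTR = 0, p_intron = 0)),
    coupling = list(a = "Rbfox1", b = "Bru1", d_max = 50, q = 1))
  pl <- plant_motifs(g, spec, seed = 52)
  a <- dplyr::filter(pl$truth, motif == "Rbfox1")
  b <- dplyr::filter(pl$truth, motif == "Bru1")
  expect_gt(nrow(b), 0)
  d <- nearest_distance(a, b)
  # q = 1: every A that could host a partner has one within 50 nt; allow the
  # skipped ones (reported by the generator) to be absent
  expect_lte(sum(d$distance > 50), pl$n_skipped)
})

test_that("antisense planting is recorded and excluded by the strand filter", {
  g <- make_genome(genome_spec(n_seqs = 1, seq_length = 60000, n_genes = 15),
                   seed = 61)
  pl <- plant_motifs(g, plant_spec(antisense = 0.5), seed = 62)
  expect_gt(sum(!pl$truth$sense), 0)
  hits <- scan_motif_set(pl$sequences, plant_spec()$motifs)
  kept <- suppressMessages(
    filter_transcribed_strand(assign_genes(hits, pl$annotation)))
  sense_truth <- dplyr::filter(pl$truth, sense)
  expect_equal(nrow(kept), nrow(sense_truth))
  expect_setequal(paste(kept$motif, kept$seq_id, kept$start, kept$strand),
                  paste(sense_truth$motif, sense_truth$seq_id,
                        sense_truth$start, sense_truth$strand))
})

test_that("synthetic SJ tables parse and carry the declared truth", {
  ev <- tibble::tibble(event_id = "e1", anchor_type = "donor",
                       seq_id = "chr2L", anchor_coord = 1000L,
                       partner_coord = c(2000L, 3000L),
                       partner_label = c("short", "long"), strand = "+",
                       prob = c(0.6, 0.4))
  d <- tempfile()
  sj <- make_sj(ev, depth = 1e6, n_samples = 1, seed = 71, dir = d)
  # high depth: empirical usage within 0.2% of truth
  u <- junction_usage(sj$events, sj$junctions)
  joined <- dplyr::inner_join(u, sj$truth,
                              by = c("event_id", "partner_label",
                                     "partner_coord"))
  expect_true(all(abs(joined$percent - joined$true_percent) < 0.2))
  # the written file parses back to the same table
  parsed <- read_sj_tab(sj$files, sample = unique(sj$junctions$sample))
  expect_equal(parsed, sj$junctions)
})

test_that("zero-depth events emit no junction lines", {
  ev <- tibble::tibble(event_id = "e1", anchor_type = "donor",
                       seq_id = "c", anchor_coord = 100L,
                       partner_coord = c(300L, 500L),
                       partner_label = c("a", "b"), strand = "+",
                       prob = c(0.5, 0.5))
  sj <- make_sj(ev, depth = 0, seed = 1)
  expect_equal(nrow(sj$junctions), 0L)
  u <- junction_usage(sj$events, sj$junctions)
  expect_true(all(u$undefined))
  # a single alternative has 100% truth by construction
  ev1 <- dplyr::slice(ev, 1) |> dplyr::mutate(prob = 1)
  expect_equal(make_sj(ev1, depth = 10, seed = 2)$truth$true_percent, 100)
})

test_that("the full fixture is deterministic end to end", {
  run_once <- function() {
    g <- make_genome(genome_spec(n_seqs = 1, seq_length = 40000,
                                 n_genes = 10), seed = 91)
    pl <- plant_motifs(g, plant_spec(), seed = 92)
    list(seq = pl$sequences$seq, truth = pl$truth)
  }
  expect_identical(run_once(), run_once())
})
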