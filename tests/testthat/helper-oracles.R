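# Independent brute-force reference implementations used to validate the
# package's optimised paths, plus small fixture builders.

# Brute-force PWM scan: walks every window explicitly, summing log-odds by
# direct matrix lookup; reverse-strand hits are found by scanning the
# reverse-complemented sequence forward and mapping coordinates back.
oracle_scan <- function(seqs, motif_pwm, settings) {
  lom <- log_odds(motif_pwm)
  thr <- resolve_threshold(motif_pwm, settings)
  L <- nrow(lom)
  scan_fwd <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    idx <- match(ch, c("A", "C", "G", "T"))
    n <- length(ch)
    starts <- integer(0); scores <- numeric(0)
    if (n >= L) {
      for (i in 1:(n - L + 1)) {
        w <- idx[i:(i + L - 1)]
        if (anyNA(w)) next
        sc <- 0
        for (j in 1:L) sc <- sc + unname(lom[j, w[j]])
        if (sc >= thr) {
          starts <- c(starts, i - 1L); scores <- c(scores, sc)
        }
      }
    }
    list(start = starts, score = scores)
  }
  out <- list()
  for (r in seq_len(nrow(seqs))) {
    f <- scan_fwd(seqs$seq[r])
    out[[length(out) + 1]] <- tibble::tibble(
      motif = motif_pwm$name, seq_id = seqs$id[r], start = f$start,
      end = f$start + L, strand = "+", score = f$score)
    if (isTRUE(settings$both_strands)) {
      n <- nchar(seqs$seq[r])
      rc <- scan_fwd(reverse_complement(seqs$seq[r]))
      out[[length(out) + 1]] <- tibble::tibble(
        motif = motif_pwm$name, seq_id = seqs$id[r],
        start = n - rc$start - L, end = n - rc$start, strand = "-",
        score = rc$score)
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), seq_id, start, strand)
}

# random PWM of length L: Dirichlet-ish rows (normalised uniforms)
random_pwm <- function(L, name = "rand", pseudocount = 0.01) {
  m <- matrix(stats::runif(4 * L), nrow = L)
  m <- m / rowSums(m)
  pwm(name, m, pseudocount = pseudocount)
}

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Brute-force all-pairs nearest distance under the package's gap convention
oracle_nearest <- function(a, b) {
  gap <- function(s1, e1, s2, e2) max(0, s2 - e1, s1 - e2)
  res <- rep(NA_real_, nrow(a))
  for (i in seq_len(nrow(a))) {
    bs <- b[b$seq_id == a$seq_id[i], , drop = FALSE]
    if (nrow(bs) == 0) next
    res[i] <- min(vapply(seq_len(nrow(bs)), function(j) {
      gap(a$start[i], a$end[i], bs$start[j], bs$end[j])
    }, numeric(1)))
  }
  res
}

# A one-gene annotation used across the annotation tests:
# gene g1 on chr1 [100, 200) '+', exons [100,150) and [180,200),
# 5'UTR [100,110), CDS [110,150)+[180,190), 3'UTR [190,200),
# derived intron [150,180).
tiny_annotation <- function(strand = "+") {
  genes <- tibble::tibble(gene_id = "g1", seq_id = "chr1", start = 100L,
                          end = 200L, strand = strand)
  tx <- tibble::tibble(transcript_id = "t1", gene_id = "g1", seq_id = "chr1",
                       start = 100L, end = 200L, strand = strand)
  feats <- tibble::tibble(
    transcript_id = "t1", gene_id = "g1", seq_id = "chr1",
    start = c(100L, 180L, 110L, 180L, 100L, 190L),
    end = c(150L, 200L, 150L, 190L, 110L, 200L),
    strand = strand,
    type = c("exon", "exon", "CDS", "CDS", "5UTR", "3UTR"))
  gene_annotation(genes, tx, feats)
}

make_hit <- function(seq_id, start, end, strand = "+", motif = "m1",
                     score = 0) {
  tibble::tibble(motif = motif, seq_id = seq_id, start = as.integer(start),
                 end = as.integer(end), strand = strand, score = score)
}

# truth -> per-(gene, motif) expected class table, from planted region labels
truth_classes <- function(truth, ann, motifs) {
  sense <- truth[truth$sense, ]
  grid <- tidyr::expand_grid(gene_id = ann$genes$gene_id, motif = motifs)
  flags <- sense |>
    dplyr::group_by(gene_id, motif) |>
    dplyr::summarise(has_5UTR = any(region == "5UTR"),
                     has_3UTR = any(region == "3UTR"),
                     has_CDS = any(region == "CDS"),
                     has_intron = any(region == "intron"), .groups = "drop")
  grid |>
    dplyr::left_join(flags, by = c("gene_id", "motif")) |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("has_"),
                                ~ tidyr::replace_na(.x, FALSE))) |>
    dplyr::mutate(class = dplyr::case_when(
      (has_5UTR | has_3UTR) & has_CDS ~ "UTR_and_CDS",
      has_5UTR | has_3UTR ~ "UTR_only",
      has_CDS ~ "CDS_only",
      has_intron ~ "intron_only",
      .default = "none"))
}

# population of gene summaries with a known motif-bearing fraction
make_flag_summaries <- function(n_pop, n_with, motif = "m") {
  tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n_pop)), motif = motif,
    has_5UTR = FALSE, has_3UTR = FALSE,
    has_CDS = seq_len(n_pop) <= n_with,
    has_exon = seq_len(n_pop) <= n_with, has_intron = FALSE,
    class = ifelse(seq_len(n_pop) <= n_with, "CDS_only", "none"))
}

scan_motif_set <- function(seqs, motifs, both_strands = TRUE) {
  purrr::map(names(motifs), function(m) {
    scan_motifs(seqs, settings = scan_settings(
      "consensus", iupac = motifs[[m]]$consensus,
      both_strands = both_strands)) |>
      dplyr::mutate(motif = m)
  }) |> purrr::list_rbind()
}
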