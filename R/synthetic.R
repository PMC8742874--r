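# Seeded synthetic fixtures: annotated mini-genomes, sequences with motifs
# planted at controlled per-region rates and controlled A-B proximity,
# splice-junction tables with known usage proportions, and band-intensity
# tables with known fold changes. The generators emit ground-truth tables
# sufficient to score every downstream stage.

#' Specification of a synthetic mini-genome
#'
#' Describes a small annotated genome: genes with 2-6 exons on either
#' strand, each carrying a 5'-UTR, CDS and 3'-UTR, with derived introns.
#' Genes never overlap; they are laid left to right with random gaps.
#'
#' @param n_seqs Number of sequences (chromosome stand-ins).
#' @param seq_length Length of each sequence in bases (scalar or one per
#'   sequence).
#' @param n_genes Total number of genes, distributed over the sequences.
#' @param n_exons Range (min, max) of exons per gene.
#' @param exon_len,intron_len Ranges (min, max) of exon/intron lengths.
#' @param utr5_len,utr3_len Ranges of UTR lengths; UTRs sit inside the first
#'   and last exon (in transcription order) and are capped so at least 10
#'   coding bases remain in those exons.
#' @param gene_gap Range of intergenic gap lengths.
#' @param base_probs Background base composition (A, C, G, T); default
#'   uniform.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(n_seqs = 2, seq_length = 100000, n_genes = 30,
                        n_exons = c(2, 6), exon_len = c(80, 300),
                        intron_len = c(60, 200), utr5_len = c(30, 120),
                        utr3_len = c(60, 250), gene_gap = c(100, 400),
                        base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (abs(sum(base_probs) - 1) > 1e-6) abort("base_probs must sum to 1")
  if (exon_len[1] < 40) abort("minimum exon length must be >= 40")
  structure(list(n_seqs = n_seqs,
                 seq_length = rep_len(seq_length, n_seqs),
                 n_genes = n_genes, n_exons = n_exons, exon_len = exon_len,
                 intron_len = intron_len, utr5_len = utr5_len,
                 utr3_len = utr3_len, gene_gap = gene_gap,
                 base_probs = setNames(as.numeric(base_probs), BASES)),
            class = "genome_spec")
}

rint <- function(n, range) {
  if (range[2] < range[1]) abort("invalid range")
  as.integer(range[1] + floor(runif(n) * (range[2] - range[1] + 1)))
}

#' Generate a synthetic annotated mini-genome
#'
#' Draws random sequences and a gene annotation satisfying all annotation
#' invariants (exons within gene spans, strand-consistent children, introns
#' the exon-complement). With a fixed `seed` the output — including any
#' files written — is byte-identical across runs.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed (optional).
#' @param dir If given, the genome is also written to `genome.fa` and
#'   `annotation.gff3` in this directory.
#' @return A list with `sequences` (tibble `id`, `seq`, `length`),
#'   `annotation` (a [gene_annotation()]), and `files` (named paths when
#'   `dir` was given). An infeasible spec (genes do not fit) errors before
#'   writing anything.
#' @export
make_genome <- function(spec = genome_spec(), seed = NULL, dir = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  build <- function() {
    seq_ids <- sprintf("chrS%d", seq_len(spec$n_seqs))
    genes <- list(); txs <- list(); feats <- list()
    g <- 0L
    for (si in seq_len(spec$n_seqs)) {
      cursor <- rint(1, spec$gene_gap)
      while (g < spec$n_genes) {
        k <- rint(1, spec$n_exons)
        ex_len <- rint(k, spec$exon_len)
        in_len <- if (k > 1) rint(k - 1, spec$intron_len) else integer(0)
        span <- sum(ex_len) + sum(in_len)
        if (cursor + span > spec$seq_length[si]) break
        g <- g + 1L
        gid <- sprintf("g%03d", g)
        tid <- sprintf("t%03d", g)
        strand <- sample(c("+", "-"), 1)
        gs <- cursor; ge <- cursor + span
        ex_start <- gs + cumsum(c(0, head(ex_len, -1) + in_len))
        ex_end <- ex_start + ex_len
        # UTRs in transcription order: first/last exon in genome order for
        # '+', swapped for '-'
        first_len <- if (strand == "+") ex_len[1] else ex_len[k]
        last_len <- if (strand == "+") ex_len[k] else ex_len[1]
        u5 <- rint(1, c(min(spec$utr5_len[1], first_len - 10),
                        min(spec$utr5_len[2], first_len - 10)))
        u3 <- rint(1, c(min(spec$utr3_len[1], last_len - 10),
                        min(spec$utr3_len[2], last_len - 10)))
        if (strand == "+") {
          utr5 <- c(gs, gs + u5); utr3 <- c(ge - u3, ge)
          cds_span <- c(gs + u5, ge - u3)
        } else {
          utr5 <- c(ge - u5, ge); utr3 <- c(gs, gs + u3)
          cds_span <- c(gs + u3, ge - u5)
        }
        cds_s <- pmax(ex_start, cds_span[1]); cds_e <- pmin(ex_end, cds_span[2])
        keep <- cds_e > cds_s
        f <- bind_rows(
          tibble(type = "exon", start = ex_start, end = ex_end),
          tibble(type = "CDS", start = cds_s[keep], end = cds_e[keep]),
          tibble(type = "5UTR", start = utr5[1], end = utr5[2]),
          tibble(type = "3UTR", start = utr3[1], end = utr3[2])
        ) |>
          mutate(transcript_id = tid, gene_id = gid, seq_id = seq_ids[si],
                 strand = strand)
        genes[[g]] <- tibble(gene_id = gid, seq_id = seq_ids[si],
                             start = gs, end = ge, strand = strand)
        txs[[g]] <- tibble(transcript_id = tid, gene_id = gid,
                           seq_id = seq_ids[si], start = gs, end = ge,
                           strand = strand)
        feats[[g]] <- f
        cursor <- ge + rint(1, spec$gene_gap)
      }
    }
    if (g < spec$n_genes) {
      abort(sprintf(
        "infeasible genome spec: only %d of %d genes fit on %d sequence(s)",
        g, spec$n_genes, spec$n_seqs))
    }
    seqs <- tibble(
      id = seq_ids,
      seq = map_chr(spec$seq_length, function(L) {
        paste(sample(BASES, L, replace = TRUE, prob = spec$base_probs),
              collapse = "")
      })
    ) |> mutate(length = nchar(.data$seq))
    ann <- gene_annotation(list_rbind(genes), list_rbind(txs),
                           list_rbind(feats))
    list(sequences = seqs, annotation = ann)
  }
  out <- if (is.null(seed)) build() else with_seed(seed, build())
  out$files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    gff <- file.path(dir, "annotation.gff3")
    write_fasta(out$sequences, fa)
    write_gff3(out$annotation, gff)
    out$files <- c(fasta = fa, gff3 = gff)
  }
  out
}

#' Specification of motif planting
#'
#' Controls which motifs are planted where: per-region planting
#' probabilities (per gene), an optional A-B coupling rule, and an optional
#' antisense fraction used to exercise the transcribed-strand filter.
#'
#' @param motifs Named list; each element is a list with `consensus` (IUPAC
#'   string) and per-region probabilities `p_5UTR`, `p_3UTR`, `p_CDS`,
#'   `p_intron` — the probability that a given gene receives one instance in
#'   that region. Defaults plant an Rbfox1-style `TGCATG` element and a
#'   Bru1-style UGU-rich `TGTTGT` element at rates giving roughly a third of
#'   genes an instance of each.
#' @param coupling Optional list `(a, b, d_max, q)`: for each planted
#'   instance of motif `a`, with probability `q` an extra instance of motif
#'   `b` is planted within `d_max` bases (same feature interval).
#' @param antisense Fraction of planted instances written on the strand
#'   opposite the gene (default 0; they are recorded in the truth with
#'   their antisense strand).
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(motifs = list(
                         Rbfox1 = list(consensus = "TGCATG", p_5UTR = 0.10,
                                       p_3UTR = 0.30, p_CDS = 0.20,
                                       p_intron = 0.35),
                         Bru1 = list(consensus = "TGTTGT", p_5UTR = 0.05,
                                     p_3UTR = 0.30, p_CDS = 0.15,
                                     p_intron = 0.30)),
                       coupling = NULL, antisense = 0) {
  if (is.null(names(motifs)) || any(!nzchar(names(motifs)))) {
    abort("motifs must be a named list")
  }
  for (m in motifs) iupac_allowed(m$consensus) # validates
  if (!is.null(coupling)) {
    stopifnot(all(c("a", "b", "d_max", "q") %in% names(coupling)),
              all(c(coupling$a, coupling$b) %in% names(motifs)))
  }
  if (antisense < 0 || antisense > 1) abort("antisense must be in [0, 1]")
  structure(list(motifs = motifs, coupling = coupling, antisense = antisense),
            class = "plant_spec")
}

# sample a concrete realisation of an IUPAC consensus
concrete_consensus <- function(iupac) {
  allowed <- iupac_allowed(iupac)
  paste(apply(allowed, 2, function(a) {
    b <- BASES[a]
    if (length(b) == 1) b else sample(b, 1)
  }), collapse = "")
}

#' Plant motif instances into a synthetic genome
#'
#' Writes motif instances into the genome sequences wholly inside feature
#' intervals of the requested region types, on the transcribed strand
#' (except for the `antisense` fraction), and screens the background so
#' that after planting the only exact consensus matches on either strand
#' are the planted ones: a consensus-mode scan recovers exactly the truth
#' table. Planted instances never overlap each other (at least one free
#' base between any two), so spurious matches always retain a re-rollable
#' base.
#'
#' @param genome Output of [make_genome()] (a list with `sequences` and
#'   `annotation`).
#' @param spec A [plant_spec()].
#' @param seed Integer seed (optional).
#' @param max_iter Maximum background re-rolling sweeps.
#' @return A list: `sequences` (modified), `truth` (tibble `motif`,
#'   `seq_id`, `start`, `end`, `strand`, `score` (0), `gene_id`, `region`,
#'   `sense`), `annotation` (passed through) and `n_skipped` (placements
#'   abandoned because no interval could host them).
#' @export
plant_motifs <- function(genome, spec = plant_spec(), seed = NULL,
                         max_iter = 200) {
  stopifnot(inherits(spec, "plant_spec"))
  ann <- genome$annotation
  run <- function() {
    chars <- lapply(genome$sequences$seq, function(s) {
      strsplit(s, "", fixed = TRUE)[[1]]
    })
    names(chars) <- genome$sequences$id
    base_probs <- rep(0.25, 4)
    truth <- list(); n_skipped <- 0L
    lens <- vapply(spec$motifs, function(m) nchar(m$consensus), integer(1))

    # occupancy bitmap (1-based) over planted bases: a candidate conflicts
    # if any base in its interval expanded by 1 on each side is occupied,
    # guaranteeing >= 1 free base between plants
    occ <- lapply(chars, function(ch) logical(length(ch)))
    conflicts <- function(sid, s, e) {
      lo <- max(1L, s); hi <- min(length(occ[[sid]]), e + 1L)
      any(occ[[sid]][lo:hi])
    }
    gene_strand <- setNames(ann$genes$strand, ann$genes$gene_id)

    place <- function(motif, gid, region, ivs, near = NULL, d_max = NULL) {
      L <- nchar(spec$motifs[[motif]]$consensus)
      w <- ivs$end - ivs$start - L + 1
      ok <- w >= 1
      if (!any(ok)) return(FALSE)
      ivs <- ivs[ok, , drop = FALSE]; w <- w[ok]
      for (try in 1:30) {
        if (is.null(near)) {
          i <- sample.int(nrow(ivs), 1, prob = w)
          s <- as.integer(ivs$start[i] + floor(runif(1) * w[i]))
          sid <- ivs$seq_id[i]
        } else {
          # within d_max of the `near` instance, same feature interval
          i <- which(ivs$start <= near$start & ivs$end >= near$end)[1]
          if (is.na(i)) return(FALSE)
          lo <- max(ivs$start[i], near$start - d_max - L)
          hi <- min(ivs$end[i] - L, near$end + d_max)
          cand <- setdiff(seq2(lo, hi), seq2(near$start - L, near$end))
          cand <- cand[abs_gap(cand, cand + L, near$start, near$end) <= d_max &
                         abs_gap(cand, cand + L, near$start, near$end) >= 1]
          if (!length(cand)) return(FALSE)
          s <- as.integer(if (length(cand) == 1) cand else sample(cand, 1))
          sid <- near$seq_id
        }
        if (conflicts(sid, s, s + L)) next
        plant_strand <- gene_strand[[gid]]
        if (runif(1) < spec$antisense) {
          plant_strand <- if (plant_strand == "+") "-" else "+"
        }
        inst <- concrete_consensus(spec$motifs[[motif]]$consensus)
        written <- if (plant_strand == "+") inst else reverse_complement(inst)
        chars[[sid]][(s + 1):(s + L)] <<- strsplit(written, "", fixed = TRUE)[[1]]
        occ[[sid]][(s + 1):(s + L)] <<- TRUE
        truth[[length(truth) + 1]] <<- list(
          motif = motif, seq_id = sid, start = s, end = s + as.integer(L),
          strand = plant_strand, gene_id = gid, region = region,
          sense = plant_strand == gene_strand[[gid]])
        return(TRUE)
      }
      FALSE
    }

    # per-gene, per-region Bernoulli planting
    region_p <- c(`5UTR` = "p_5UTR", `3UTR` = "p_3UTR", CDS = "p_CDS",
                  intron = "p_intron")
    feat_by_gene_region <- split(
      ann$features,
      interaction(ann$features$gene_id, ann$features$type, drop = TRUE))
    lookup_feats <- function(gid, region) {
      feat_by_gene_region[[paste(gid, region, sep = ".")]] %||%
        ann$features[0, ]
    }
    for (motif in names(spec$motifs)) {
      for (gid in ann$genes$gene_id) {
        for (region in names(region_p)) {
          p <- spec$motifs[[motif]][[region_p[[region]]]] %||% 0
          if (p <= 0 || runif(1) >= p) next
          ivs <- lookup_feats(gid, region)
          if (!place(motif, gid, region, ivs)) n_skipped <- n_skipped + 1L
        }
      }
    }
    # coupling: plant B near planted A instances
    cp <- spec$coupling
    if (!is.null(cp) && cp$q > 0) {
      a_rows <- which(vapply(truth, function(t) t$motif == cp$a, logical(1)))
      for (ti in a_rows) {
        t <- truth[[ti]]
        if (runif(1) >= cp$q) next
        gf <- lookup_feats(t$gene_id, t$region)
        if (!place(cp$b, t$gene_id, t$region, gf, near = t,
                   d_max = cp$d_max)) {
          n_skipped <- n_skipped + 1L
        }
      }
    }
    truth_tbl <- if (length(truth) == 0) {
      tibble(motif = character(), seq_id = character(), start = integer(),
             end = integer(), strand = character(), score = numeric(),
             gene_id = character(), region = character(), sense = logical())
    } else {
      list_rbind(map(truth, as_tibble)) |>
        mutate(score = 0, .after = "strand") |>
        arrange(.data$motif, .data$seq_id, .data$start)
    }

    # screening: re-roll background bases until the only consensus matches
    # anywhere (either strand) are the planted ones
    protected <- logical_protection(chars, truth_tbl)
    for (iter in seq_len(max_iter)) {
      seqs_now <- tibble(id = names(chars),
                         seq = vapply(chars, paste, character(1), collapse = ""))
      spurious <- map(names(spec$motifs), function(m) {
        scan_motifs(seqs_now,
                    settings = scan_settings("consensus",
                                             iupac = spec$motifs[[m]]$consensus,
                                             both_strands = TRUE)) |>
          mutate(motif = m)
      }) |> list_rbind() |>
        anti_join(truth_tbl, by = c("motif", "seq_id", "start", "strand"))
      if (nrow(spurious) == 0) break
      if (iter == max_iter) {
        abort("could not screen background free of spurious consensus matches")
      }
      for (r in seq_len(nrow(spurious))) {
        pos <- (spurious$start[r] + 1):spurious$end[r]
        free <- pos[!protected[[spurious$seq_id[r]]][pos]]
        chars[[spurious$seq_id[r]]][free] <-
          sample(BASES, length(free), replace = TRUE, prob = base_probs)
      }
    }
    seqs_final <- genome$sequences |>
      mutate(seq = vapply(chars[.data$id], paste, character(1), collapse = ""))
    list(sequences = seqs_final,
         truth = select(truth_tbl, "motif", "seq_id", "start", "end",
                        "strand", "score", "gene_id", "region", "sense"),
         annotation = ann, n_skipped = n_skipped)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# gap between [s1,e1) and [s2,e2): 0 if overlapping/book-ended
abs_gap <- function(s1, e1, s2, e2) pmax(0, pmax(s2 - e1, s1 - e2))

logical_protection <- function(chars, truth) {
  prot <- lapply(chars, function(ch) logical(length(ch)))
  for (r in seq_len(nrow(truth))) {
    prot[[truth$seq_id[r]]][(truth$start[r] + 1):truth$end[r]] <- TRUE
  }
  prot
}

#' Generate synthetic splice-junction tables with known usage
#'
#' For each declared event, reads are drawn multinomially over the
#' alternatives at the stated depth, per sample; zero-read junction lines
#' are omitted (as an aligner would). The output parses through
#' [read_sj_tab()].
#'
#' @param events Event tibble as for [junction_events()] plus a `prob`
#'   column (true usage proportions, summing to 1 within each event).
#' @param depth Read depth per event (scalar or one per event, in event
#'   order).
#' @param n_samples Number of replicate samples to simulate.
#' @param seed Integer seed (optional).
#' @param dir If given, one `<sample>.SJ.out.tab` per sample is written
#'   there.
#' @return A list: `junctions` (tibble in [read_sj_tab()] shape),
#'   `truth` (tibble `event_id`, `partner_label`, `partner_coord`,
#'   `true_percent`), `events` (without `prob`, ready for
#'   [junction_usage()]), `files`.
#' @export
make_sj <- function(events, depth = 300, n_samples = 1, seed = NULL,
                    dir = NULL) {
  if (!"prob" %in% names(events)) abort("events needs a `prob` column")
  ev <- junction_events(select(events, -"prob")) |>
    mutate(prob = events$prob)
  chk <- ev |> group_by(.data$event_id) |> summarise(s = sum(.data$prob))
  if (any(abs(chk$s - 1) > 1e-6)) {
    abort(sprintf("probabilities of event '%s' do not sum to 1",
                  chk$event_id[which(abs(chk$s - 1) > 1e-6)[1]]))
  }
  eids <- unique(ev$event_id)
  depth <- rep_len(depth, length(eids))
  if (any(depth < 0)) abort("depth must be >= 0")
  run <- function() {
    map(seq_len(n_samples), function(si) {
      sm <- sprintf("sample_%d", si)
      map(seq_along(eids), function(ei) {
        rows <- filter(ev, .data$event_id == eids[ei])
        reads <- if (depth[ei] > 0) {
          as.integer(rmultinom(1, depth[ei], rows$prob))
        } else integer(nrow(rows))
        tibble(sample = sm,
               seq_id = rows$seq_id,
               donor_pos = pmin(rows$anchor_coord, rows$partner_coord) - 1L,
               acceptor_pos = pmax(rows$anchor_coord, rows$partner_coord),
               strand = rows$strand,
               unique_reads = reads, multi_reads = 0L,
               motif_code = 0L, annotated = 1L, max_overhang = 20L) |>
          filter(.data$unique_reads > 0)
      }) |> list_rbind()
    }) |> list_rbind()
  }
  jx <- if (is.null(seed)) run() else with_seed(seed, run())
  truth <- ev |>
    transmute(.data$event_id, .data$partner_label, .data$partner_coord,
              true_percent = 100 * .data$prob)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- map_chr(unique(jx$sample), function(sm) {
      path <- file.path(dir, paste0(sm, ".SJ.out.tab"))
      d <- filter(jx, .data$sample == sm)
      lines <- sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d",
                       d$seq_id, d$donor_pos + 1L, d$acceptor_pos,
                       match(d$strand, c(".", "+", "-")) - 1L,
                       d$motif_code, d$annotated, d$unique_reads,
                       d$multi_reads, d$max_overhang)
      writeLines(lines, path)
      path
    })
  }
  list(junctions = jx, truth = truth,
       events = select(ev, -"prob"), files = files)
}

#' Generate a synthetic band-intensity table with known fold changes
#'
#' Builds a densitometry table in which every (condition, target, replicate)
#' measurement is consistent with a declared true fold change relative to a
#' reference condition, after normalisation to a control gene. Per-replicate
#' scale factors are randomised (fold change is invariant to them);
#' optional multiplicative log-normal noise perturbs the measurements.
#'
#' @param true_fc Tibble with columns `condition`, `target`, `fc`: the true
#'   fold change of each non-reference condition/target pair.
#' @param reference_condition Label of the reference condition (fold change
#'   1 by construction).
#' @param control_gene Name of the normalisation control band.
#' @param replicates Number of replicates.
#' @param noise_sd Standard deviation of multiplicative log-normal noise
#'   (0 = exact).
#' @param seed Integer seed (optional).
#' @return A list: `bands` (tibble `condition`, `replicate`, `target`,
#'   `intensity`) and `truth` (`true_fc` passed through).
#' @export
make_bands <- function(true_fc, reference_condition = "control",
                       control_gene = "RpL32", replicates = 3,
                       noise_sd = 0, seed = NULL) {
  stopifnot(all(c("condition", "target", "fc") %in% names(true_fc)))
  if (reference_condition %in% true_fc$condition) {
    abort("true_fc must not contain the reference condition")
  }
  run <- function() {
    targets <- unique(true_fc$target)
    conds <- c(reference_condition, unique(true_fc$condition))
    grid <- expand_grid(condition = conds, replicate = seq_len(replicates))
    ctrl <- grid |>
      mutate(target = control_gene, intensity = runif(n(), 0.5, 2))
    ref_level <- expand_grid(target = targets,
                             replicate = seq_len(replicates)) |>
      mutate(ref_norm = runif(n(), 0.5, 2))
    meas <- expand_grid(condition = conds, replicate = seq_len(replicates),
                        target = targets) |>
      left_join(select(ctrl, "condition", "replicate",
                       ctrl_int = "intensity"),
                by = c("condition", "replicate")) |>
      left_join(ref_level, by = c("target", "replicate")) |>
      left_join(true_fc, by = c("condition", "target")) |>
      mutate(fc = replace_na(.data$fc, 1),
             noise = exp(stats::rnorm(n(), 0, noise_sd)),
             intensity = .data$ctrl_int * .data$ref_norm * .data$fc *
               .data$noise) |>
      select("condition", "replicate", "target", "intensity")
    list(bands = bind_rows(meas, select(ctrl, "condition", "replicate",
                                        "target", "intensity")),
         truth = true_fc)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
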