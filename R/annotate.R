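# Assignment of motif hits to genes and classification by gene feature
# (intron / exon / CDS / 5'-UTR / 3'-UTR), with transcribed-strand filtering.
# Overlap everywhere means >= 1 shared base under half-open coordinates: for
# 6-mer motifs any minimum-overlap fraction would silently drop boundary
# instances.

#' Assign motif hits to overlapping genes
#'
#' A hit is assigned to every gene whose span overlaps it (>= 1 shared base)
#' on the same sequence; hits overlapping no gene are dropped and their
#' count reported via a message and the `n_dropped` attribute.
#'
#' @param hits Hit tibble from [scan_motifs()] (or [read_bed()]).
#' @param ann A [gene_annotation()] object.
#' @return The hits joined to genes: one row per (hit, gene) with added
#'   columns `gene_id` and `gene_strand`; attribute `n_dropped` counts hits
#'   that overlapped no gene.
#' @export
assign_genes <- function(hits, ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  genes <- ann$genes |>
    select("gene_id", "seq_id", gene_start = "start", gene_end = "end",
           gene_strand = "strand")
  by_overlap <- join_by(seq_id, start < gene_end, end > gene_start)
  joined <- inner_join(hits, genes, by = by_overlap,
                       relationship = "many-to-many") |>
    select(-"gene_start", -"gene_end")
  # count dropped input rows (those with no gene overlap)
  dropped <- anti_join(hits, genes, by = by_overlap)
  if (nrow(dropped) > 0) {
    inform(sprintf("%d hit(s) overlapped no gene and were dropped", nrow(dropped)))
  }
  attr(joined, "n_dropped") <- nrow(dropped)
  joined
}

#' Keep hits on the transcribed strand
#'
#' Retains only hits whose strand equals the strand of the gene they were
#' assigned to, i.e. sequences present in the transcribed pre-mRNA.
#' Unstranded hits (`.`) are retained by default (and counted in a message).
#'
#' @param ahits Output of [assign_genes()].
#' @param keep_unstranded Keep hits with strand `.`? Default `TRUE`.
#' @return The filtered tibble.
#' @export
filter_transcribed_strand <- function(ahits, keep_unstranded = TRUE) {
  stopifnot(all(c("strand", "gene_strand") %in% names(ahits)))
  unstr <- ahits$strand == "."
  if (any(unstr)) {
    inform(sprintf("%d unstranded hit(s) %s", sum(unstr),
                   if (keep_unstranded) "retained" else "removed"))
  }
  keep <- ahits$strand == ahits$gene_strand | (unstr & keep_unstranded)
  ahits[keep, , drop = FALSE]
}

#' Classify assigned hits by gene feature
#'
#' For each (hit, gene) row, takes the union over the gene's transcripts of
#' the feature classes whose intervals the hit overlaps by at least one
#' base. A hit may carry several regions (a UTR hit is also exonic; a hit
#' can be intronic in one isoform and exonic in another). UTR or CDS
#' membership implies exon membership.
#'
#' @param ahits Output of [assign_genes()] (typically after
#'   [filter_transcribed_strand()]).
#' @param ann The [gene_annotation()] object used for assignment.
#' @return `ahits` with added columns `in_exon`, `in_CDS`, `in_5UTR`,
#'   `in_3UTR`, `in_intron` (logicals) and `regions`, a semicolon-joined
#'   string in canonical order (`exon;CDS;5UTR;3UTR;intron`). A gene with no
#'   transcript is an error.
#' @export
classify_regions <- function(ahits, ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  no_tx <- setdiff(unique(ahits$gene_id), ann$transcripts$gene_id)
  if (length(no_tx)) {
    abort(sprintf("gene '%s' has no transcript", no_tx[1]))
  }
  key <- ahits |> mutate(.hit = row_number())
  feats <- ann$features |>
    select("gene_id", "seq_id", f_start = "start", f_end = "end", "type")
  ov <- inner_join(
    key, feats,
    by = join_by(gene_id, seq_id, start < f_end, end > f_start),
    relationship = "many-to-many"
  ) |>
    distinct(.data$.hit, .data$type) |>
    mutate(flag = TRUE) |>
    pivot_wider(names_from = "type", values_from = "flag", values_fill = FALSE)
  for (r in REGIONS) if (!r %in% names(ov)) ov[[r]] <- logical(nrow(ov))
  ov <- select(ov, ".hit", all_of(REGIONS))
  out <- key |>
    left_join(ov, by = ".hit") |>
    mutate(across(all_of(REGIONS), ~ replace_na(.x, FALSE))) |>
    # containment: UTR/CDS sequence is exonic by definition
    mutate(exon = .data$exon | .data$CDS | .data$`5UTR` | .data$`3UTR`) |>
    select(-".hit")
  out |>
    mutate(regions = region_string(out)) |>
    rename(in_exon = "exon", in_CDS = "CDS", in_5UTR = "5UTR",
           in_3UTR = "3UTR", in_intron = "intron")
}

region_string <- function(d) {
  m <- as.matrix(d[, REGIONS])
  apply(m, 1, function(f) paste(REGIONS[f], collapse = ";"))
}

#' One-step hit annotation pipeline
#'
#' Convenience wrapper chaining [assign_genes()],
#' [filter_transcribed_strand()] and [classify_regions()].
#'
#' @inheritParams assign_genes
#' @inheritParams filter_transcribed_strand
#' @return The annotated, strand-filtered, region-classified hit tibble.
#' @export
annotate_hits <- function(hits, ann, keep_unstranded = TRUE) {
  hits |>
    assign_genes(ann) |>
    filter_transcribed_strand(keep_unstranded = keep_unstranded) |>
    classify_regions(ann)
}
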