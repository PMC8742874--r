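# Gene annotation container: three tibbles (genes, transcripts, features) in
# the internal 0-based half-open coordinate convention. Conversion to/from the
# 1-based closed GFF3 convention happens only in read_gff3()/write_gff3().

#' Construct a gene annotation object
#'
#' Bundles gene, transcript and feature tables into the container used by all
#' annotation-aware operations. Coordinates are 0-based half-open throughout.
#'
#' @param genes Tibble with columns `gene_id`, `seq_id`, `start`, `end`,
#'   `strand` (one of `+`, `-`, `.`).
#' @param transcripts Tibble with columns `transcript_id`, `gene_id`,
#'   `seq_id`, `start`, `end`, `strand`.
#' @param features Tibble with columns `transcript_id`, `gene_id`, `seq_id`,
#'   `start`, `end`, `strand`, `type` where `type` is one of `exon`, `CDS`,
#'   `5UTR`, `3UTR` (and optionally `intron`).
#' @param derive_introns If `TRUE` (default) intron features are (re)derived
#'   per transcript as the gaps between that transcript's sorted exons; any
#'   `intron` rows already present are discarded first.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, transcripts, features, derive_introns = TRUE) {
  genes <- as_tibble(genes)
  transcripts <- as_tibble(transcripts)
  features <- as_tibble(features)
  check_intervals(genes, "genes")
  check_intervals(transcripts, "transcripts")
  check_intervals(features, "features")
  bad_type <- setdiff(unique(features$type), REGIONS)
  if (length(bad_type)) {
    abort(sprintf("unknown feature type(s): %s", paste(bad_type, collapse = ", ")))
  }
  if (derive_introns) {
    features <- features |>
      filter(.data$type != "intron") |>
      bind_rows(derive_intron_features(filter(features, .data$type == "exon")))
  }
  # child strand must match gene strand
  chk <- features |>
    inner_join(select(genes, "gene_id", gene_strand = "strand"), by = "gene_id") |>
    filter(.data$strand != .data$gene_strand)
  if (nrow(chk) > 0) {
    abort(sprintf("feature strand differs from gene strand for gene '%s'",
                  chk$gene_id[1]))
  }
  features <- select(features, "transcript_id", "gene_id", "seq_id",
                     "start", "end", "strand", "type")
  structure(
    list(genes = genes, transcripts = transcripts,
         features = arrange(features, .data$seq_id, .data$start, .data$type)),
    class = "gene_annotation"
  )
}

check_intervals <- function(df, what) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0) || any(df$end <= df$start)) {
    abort(sprintf("invalid interval in %s: need 0 <= start < end", what))
  }
  invisible(df)
}

# gaps between sorted exons, per transcript
derive_intron_features <- function(exons) {
  if (nrow(exons) == 0) return(exons[0, ])
  exons |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id, .data$gene_id, .data$seq_id, .data$strand) |>
    reframe(istart = head(.data$end, -1), iend = tail(.data$start, -1)) |>
    filter(.data$iend > .data$istart) |>
    mutate(type = "intron") |>
    select("transcript_id", "gene_id", "seq_id", start = "istart",
           end = "iend", "strand", "type")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf(
    "<gene_annotation> %d gene(s), %d transcript(s), %d feature interval(s) on %d sequence(s)\n",
    nrow(x$genes), nrow(x$transcripts), nrow(x$features),
    length(unique(x$genes$seq_id))))
  invisible(x)
}

#' Read a GFF3 gene annotation
#'
#' Parses a GFF3 file carrying `gene`, `mRNA` (or `transcript`), `exon`,
#' `CDS`, `five_prime_UTR` and `three_prime_UTR` features, resolves
#' parent/child links through the `ID`/`Parent` attributes, converts the
#' 1-based closed GFF3 coordinates to the internal 0-based half-open
#' convention, and derives introns per transcript as the gaps between sorted
#' exons.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_annotation()] object.
#' @details A feature whose `end` precedes its `start` is a format error
#'   (reported with its line number). Child features whose `Parent` does not
#'   resolve to a known transcript are skipped with a warning; a feature with
#'   several parent transcripts is assigned to each of them.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tx\tgene\t101\t200\t.\t+\t.\tID=g1",
#'   "chr1\tx\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
#'   "chr1\tx\texon\t101\t150\t.\t+\t.\tParent=t1",
#'   "chr1\tx\texon\t181\t200\t.\t+\t.\tParent=t1"), gff)
#' read_gff3(gff)
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  # structural pre-validation with line numbers
  lines <- readLines(path, warn = FALSE)
  body <- which(nzchar(lines) & !startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      abort(sprintf("GFF3 format error at line %d: %d column(s), expected 9",
                    i, length(f)))
    }
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e)) {
      abort(sprintf("GFF3 format error at line %d: non-numeric coordinates", i))
    }
    if (e < s) {
      abort(sprintf("GFF3 format error at line %d: end (%s) < start (%s)",
                    i, f[5], f[4]))
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  d <- tibble(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = chartr("*", ".", as.character(GenomicRanges::strand(gr))),
    type = as.character(mc$type),
    id = if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_,
    parent = if ("Parent" %in% names(mc)) as.list(mc$Parent) else
      rep(list(character(0)), length(gr))
  )

  genes <- d |>
    filter(.data$type == "gene") |>
    transmute(gene_id = .data$id, .data$seq_id, .data$start, .data$end, .data$strand)
  if (any(is.na(genes$gene_id))) abort("gene feature without an ID attribute")

  tx <- d |>
    filter(.data$type %in% c("mRNA", "transcript")) |>
    mutate(gene_id = map_chr(.data$parent, ~ if (length(.x)) .x[[1]] else NA_character_)) |>
    transmute(transcript_id = .data$id, .data$gene_id, .data$seq_id,
              .data$start, .data$end, .data$strand)
  orphan_tx <- !tx$gene_id %in% genes$gene_id
  if (any(orphan_tx)) {
    warn(sprintf("skipping %d transcript(s) without a resolvable gene parent",
                 sum(orphan_tx)))
    tx <- tx[!orphan_tx, ]
  }

  type_map <- c(exon = "exon", CDS = "CDS",
                five_prime_UTR = "5UTR", three_prime_UTR = "3UTR")
  kids <- d |>
    filter(.data$type %in% names(type_map)) |>
    mutate(type = unname(type_map[.data$type])) |>
    select("seq_id", "start", "end", "strand", "type", "parent") |>
    unnest(cols = "parent", keep_empty = TRUE) |>
    rename(transcript_id = "parent")
  orphan <- is.na(kids$transcript_id) | !kids$transcript_id %in% tx$transcript_id
  if (any(orphan)) {
    warn(sprintf("skipping %d feature(s) without a resolvable transcript parent",
                 sum(orphan)))
    kids <- kids[!orphan, ]
  }
  features <- kids |>
    inner_join(select(tx, "transcript_id", "gene_id"), by = "transcript_id") |>
    select("transcript_id", "gene_id", "seq_id", "start", "end", "strand", "type")

  gene_annotation(genes, tx, features, derive_introns = TRUE)
}

#' Write a gene annotation to GFF3
#'
#' Inverse of [read_gff3()]: emits `gene`, `mRNA`, `exon`, `CDS`,
#' `five_prime_UTR` and `three_prime_UTR` lines (derived introns are not
#' written) converting internal 0-based half-open coordinates back to the
#' 1-based closed GFF3 convention.
#'
#' @param ann A [gene_annotation()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  rev_map <- c(exon = "exon", CDS = "CDS",
               `5UTR` = "five_prime_UTR", `3UTR` = "three_prime_UTR")
  gl <- ann$genes |>
    transmute(.data$seq_id, type = "gene", start1 = .data$start + 1L,
              end1 = .data$end, .data$strand,
              attr = sprintf("ID=%s", .data$gene_id))
  tl <- ann$transcripts |>
    transmute(.data$seq_id, type = "mRNA", start1 = .data$start + 1L,
              end1 = .data$end, .data$strand,
              attr = sprintf("ID=%s;Parent=%s", .data$transcript_id, .data$gene_id))
  fl <- ann$features |>
    filter(.data$type != "intron") |>
    transmute(.data$seq_id, type = unname(rev_map[.data$type]),
              start1 = .data$start + 1L, end1 = .data$end, .data$strand,
              attr = sprintf("Parent=%s", .data$transcript_id))
  all <- bind_rows(gl, tl, fl) |> arrange(.data$seq_id, .data$start1)
  phase <- ifelse(all$type == "CDS", "0", ".")
  out <- sprintf("%s\trbmotif\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                 all$seq_id, all$type, all$start1, all$end1, all$strand,
                 phase, all$attr)
  writeLines(c("##gff-version 3", out), path)
  invisible(path)
}
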