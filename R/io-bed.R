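#' Write motif hits to a BED6 file
#'
#' Emits one BED6 line per hit (chrom, 0-based start, exclusive end,
#' name = motif, score, strand), sorted by `(seq_id, start)`. No conversion
#' is needed: the internal convention and BED agree.
#'
#' @param hits A tibble of motif hits with columns `motif`, `seq_id`,
#'   `start`, `end`, `strand`, `score` (as produced by [scan_motifs()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_bed()]
#' @export
write_bed <- function(hits, path) {
  need <- c("motif", "seq_id", "start", "end", "strand", "score")
  stopifnot(all(need %in% names(hits)))
  bed <- hits |>
    arrange(.data$seq_id, .data$start) |>
    select("seq_id", "start", "end", "motif", "score", "strand")
  write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6 file of motif hits
#'
#' @param path Path to a BED6 file (chrom, start, end, name, score, strand).
#' @return A hit tibble with columns `motif`, `seq_id`, `start`, `end`,
#'   `strand`, `score` — the same shape [scan_motifs()] produces.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  d <- read_tsv(path,
                col_names = c("seq_id", "start", "end", "motif", "score", "strand"),
                col_types = "ciicdc", progress = FALSE)
  if (nrow(d) > 0 && (any(is.na(d$start)) || any(is.na(d$end)))) {
    abort(sprintf("BED format error in %s: non-integer coordinates", path))
  }
  select(d, "motif", "seq_id", "start", "end", "strand", "score")
}
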