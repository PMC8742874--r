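#' Read a FASTA file into a sequence tibble
#'
#' Reads a (multi-record) FASTA file and normalises it to the internal
#' convention: uppercase DNA with RNA `U` stored as `T`. Only the first
#' whitespace-delimited token of each header is kept as the record id.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `id`, `seq`
#'   (uppercase over A/C/G/T/N) and `length` (bases).
#' @details Structural problems are reported with the offending line number:
#'   an empty header, a record with no sequence, or a file that does not
#'   start with a `>` header are format errors; duplicated record ids are an
#'   error because downstream joins key on `id`.
#' @seealso [write_fasta()]
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "AUGCAUG"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, ">")
  nonblank <- nzchar(trimws(lines))
  if (!any(nonblank)) abort(sprintf("FASTA format error: %s is empty", path))
  first <- which(nonblank)[1]
  if (!is_hdr[first]) {
    abort(sprintf("FASTA format error at line %d: expected '>' header", first))
  }
  hdr_lines <- which(is_hdr)
  ids <- sub("\\s.*$", "", sub("^>\\s*", "", lines[hdr_lines]))
  empty_id <- !nzchar(ids)
  if (any(empty_id)) {
    abort(sprintf("FASTA format error at line %d: empty header",
                  hdr_lines[which(empty_id)[1]]))
  }
  # a header immediately followed by another header (or EOF) has no sequence
  next_content <- c(hdr_lines[-1] - 1L, length(lines))
  has_seq <- vapply(seq_along(hdr_lines), function(i) {
    span <- lines[seq2(hdr_lines[i] + 1L, next_content[i])]
    any(nzchar(trimws(span)))
  }, logical(1))
  if (any(!has_seq)) {
    abort(sprintf("FASTA format error at line %d: record '%s' has no sequence",
                  hdr_lines[which(!has_seq)[1]], ids[which(!has_seq)[1]]))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sequence id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- normalize_seq(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf("invalid nucleotide characters in record '%s'",
                  ids[which(bad)[1]]))
  }
  tibble(id = ids, seq = unname(seqs), length = nchar(unname(seqs)))
}

seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' Write a sequence tibble to FASTA
#'
#' @param seqs A tibble with columns `id` and `seq` (as from [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  set <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
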