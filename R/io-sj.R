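#' Read STAR SJ.out.tab splice-junction tables
#'
#' Parses the 9-column tab-separated splice-junction dialect written by the
#' STAR aligner: sequence name, intron start (1-based, first intronic base),
#' intron end (1-based, last intronic base), strand code (0 undefined, 1 `+`,
#' 2 `-`), intron motif code, annotated flag, uniquely-mapping read count,
#' multi-mapping read count, maximum overhang. Coordinates are converted to
#' the internal 0-based half-open intron interval: `donor_pos = start - 1`
#' (first intronic base) and `acceptor_pos = end` (one past the last intronic
#' base).
#'
#' @param path Character vector of one or more SJ.out.tab paths.
#' @param sample Sample label(s), one per path; defaults to the file
#'   basename without extension.
#' @return A tibble with columns `sample`, `seq_id`, `donor_pos`,
#'   `acceptor_pos`, `strand`, `unique_reads`, `multi_reads`, `motif_code`,
#'   `annotated`, `max_overhang`.
#' @examples
#' sj <- tempfile(fileext = ".tab")
#' writeLines("chr1\t151\t180\t1\t1\t1\t42\t3\t20", sj)
#' read_sj_tab(sj, sample = "ifm_1")
#' @export
read_sj_tab <- function(path, sample = NULL) {
  sample <- sample %||% sub("\\.[^.]*$", "", basename(path))
  stopifnot(length(sample) == length(path))
  map2(path, sample, read_sj_one) |> list_rbind()
}

read_sj_one <- function(path, sample) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(sample = character(), seq_id = character(),
                  donor_pos = integer(), acceptor_pos = integer(),
                  strand = character(), unique_reads = integer(),
                  multi_reads = integer(), motif_code = integer(),
                  annotated = integer(), max_overhang = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(f)
  if (any(nc < 9)) {
    abort(sprintf("SJ format error at line %d of %s: %d column(s), expected 9",
                  which(nc < 9)[1], path, nc[which(nc < 9)[1]]))
  }
  m <- do.call(rbind, lapply(f, `[`, 1:9))
  ints <- m[, c(2:9), drop = FALSE]
  bad <- !grepl("^[0-9]+$", ints)
  if (any(bad)) {
    abort(sprintf("SJ format error in %s: non-integer value '%s'",
                  path, ints[bad][1]))
  }
  start1 <- as.integer(m[, 2]); end1 <- as.integer(m[, 3])
  if (any(end1 < start1)) abort(sprintf("SJ format error in %s: intron end < start", path))
  code <- as.integer(m[, 4])
  if (any(!code %in% 0:2)) {
    abort(sprintf("SJ format error in %s: strand code must be 0, 1 or 2", path))
  }
  tibble(
    sample = sample,
    seq_id = m[, 1],
    donor_pos = start1 - 1L,
    acceptor_pos = end1,
    strand = c(".", "+", "-")[code + 1L],
    unique_reads = as.integer(m[, 7]),
    multi_reads = as.integer(m[, 8]),
    motif_code = as.integer(m[, 5]),
    annotated = as.integer(m[, 6]),
    max_overhang = as.integer(m[, 9])
  )
}
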