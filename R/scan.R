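#' Locate motif instances in sequences
#'
#' Slides a motif model along every sequence and reports each window at or
#' above threshold, once per strand scanned. In `pwm` mode windows are scored
#' by summed log-odds (bits, see [log_odds()]); in `consensus` mode a window
#' is a hit iff it matches the IUPAC consensus exactly, and its score is the
#' maximum score of the equivalent uniform-over-allowed-bases PWM. Windows
#' containing `N` are skipped. Reverse-strand hits (when
#' `settings$both_strands`) are matches of the reverse complement, reported
#' with forward coordinates and strand `-`. Overlapping hits are all
#' reported; downstream distance statistics need every instance.
#'
#' @param seqs Sequence tibble with columns `id` and `seq` (see
#'   [read_fasta()]).
#' @param motif A [pwm()] object; may be `NULL` in consensus mode.
#' @param settings A [scan_settings()] object.
#' @return A hit tibble with columns `motif`, `seq_id`, `start` (0-based),
#'   `end` (exclusive), `strand`, `score` (bits), sorted by
#'   `(seq_id, start, strand)`. Sequences shorter than the motif contribute
#'   no hits.
#' @examples
#' seqs <- tibble::tibble(id = "t1", seq = "AATGCATGAA")
#' scan_motifs(seqs, settings = scan_settings("consensus", iupac = "UGCAUG"))
#' @export
scan_motifs <- function(seqs, motif = NULL,
                        settings = scan_settings()) {
  stopifnot(inherits(settings, "scan_settings"))
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  if (settings$mode == "pwm") {
    if (!inherits(motif, "pwm")) abort("pwm mode needs a pwm object")
    lom <- log_odds(motif)
    thr <- resolve_threshold(motif, settings)
    name <- motif$name
    find_fwd <- function(codes) scan_one_strand(codes, lom, thr)
    lom_rc <- lom[rev(seq_len(nrow(lom))), c(4, 3, 2, 1), drop = FALSE]
    find_rev <- function(codes) scan_one_strand(codes, lom_rc, thr)
    L <- nrow(lom)
  } else {
    # consensus: exact IUPAC matching; score reported as the maximum score of
    # the equivalent uniform-over-allowed-bases PWM (pseudocount 0)
    cons <- pwm(motif$name %||% normalize_seq(settings$iupac),
                consensus_probs(settings$iupac), pseudocount = 0)
    name <- cons$name
    cons_score <- max_score(cons)
    allowed <- iupac_allowed(settings$iupac)
    allowed_rc <- iupac_allowed(reverse_complement(settings$iupac))
    find_fwd <- function(codes) match_consensus(codes, allowed, cons_score)
    find_rev <- function(codes) match_consensus(codes, allowed_rc, cons_score)
    L <- ncol(allowed)
  }
  out <- map(seq_len(nrow(seqs)), function(i) {
    codes <- encode_seq(seqs$seq[i])
    fwd <- find_fwd(codes)
    res <- list(tibble(seq_id = seqs$id[i], start = fwd$start,
                       end = fwd$start + L, strand = "+", score = fwd$score))
    if (isTRUE(settings$both_strands)) {
      # matches of revcomp(motif) on the forward sequence are motif matches
      # on the reverse strand, reported with forward coordinates
      rev_ <- find_rev(codes)
      res <- c(res, list(tibble(seq_id = seqs$id[i], start = rev_$start,
                                end = rev_$start + L, strand = "-",
                                score = rev_$score)))
    }
    list_rbind(res)
  }) |> list_rbind()
  out |>
    mutate(motif = name, .before = 1) |>
    arrange(.data$seq_id, .data$start, .data$strand)
}

# score every window of `codes` against the L x 4 score matrix; return
# starts (0-based) and scores of windows >= thr. Windows touching an N
# (NA code) score NA and are dropped.
scan_one_strand <- function(codes, lom, thr) {
  L <- nrow(lom)
  nw <- length(codes) - L + 1L
  if (nw < 1L) return(list(start = integer(0), score = numeric(0)))
  s <- numeric(nw)
  for (j in seq_len(L)) {
    row <- unname(lom[j, ])
    s <- s + row[codes[j:(j + nw - 1L)]]
  }
  keep <- unname(which(!is.na(s) & s >= thr))
  list(start = keep - 1L, score = unname(s[keep]))
}

# exact IUPAC consensus matching: window is a hit iff every base is allowed
# at its position (N in the sequence never matches)
match_consensus <- function(codes, allowed, score) {
  L <- ncol(allowed)
  nw <- length(codes) - L + 1L
  if (nw < 1L) return(list(start = integer(0), score = numeric(0)))
  ok <- rep(TRUE, nw)
  for (j in seq_len(L)) {
    a <- unname(allowed[, j])[codes[j:(j + nw - 1L)]]
    a[is.na(a)] <- FALSE
    ok <- ok & a
  }
  keep <- unname(which(ok))
  list(start = keep - 1L, score = rep(score, length(keep)))
}
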