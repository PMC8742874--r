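# Position weight matrices: probability matrices over A/C/G/T with a
# background composition and a pseudocount, scored as log2 odds (bits).

#' Construct a position weight matrix
#'
#' @param name Motif name (e.g. `"Rbfox1"`, `"Bru1"`).
#' @param probs Numeric matrix of base probabilities, one row per motif
#'   position, columns `A`, `C`, `G`, `T` (each row sums to 1).
#' @param background Background base probabilities (length 4, sums to 1).
#'   Default uniform.
#' @param pseudocount Small positive regulariser added as
#'   `pseudocount * background` to each probability before taking log-odds;
#'   avoids minus-infinity scores from zero cells in database matrices.
#'   Default 0.01; 0 is allowed.
#' @return An object of class `pwm`.
#' @examples
#' pwm("Rbfox1", consensus_probs("TGCATG"))
#' @export
pwm <- function(name, probs, background = rep(0.25, 4), pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) abort("probs must have 4 columns (A, C, G, T)")
  if (!is.null(colnames(probs))) {
    if (!setequal(colnames(probs), BASES)) abort("probs columns must be A, C, G, T")
    probs <- probs[, BASES, drop = FALSE]
  } else colnames(probs) <- BASES
  if (nrow(probs) < 1) abort("PWM must have at least one position")
  if (any(probs < 0) || any(background < 0)) abort("probabilities must be >= 0")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    abort("each PWM row must sum to 1")
  }
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1")
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  structure(list(name = name, probs = probs,
                 background = setNames(as.numeric(background), BASES),
                 pseudocount = pseudocount, length = nrow(probs)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s: %d positions, max score %.3f bits\n",
              x$name, x$length, max_score(x)))
  print(round(x$probs, 3))
  invisible(x)
}

#' Probability matrix of an IUPAC consensus
#'
#' Expands an IUPAC consensus string into the equivalent probability matrix:
#' uniform probability over the allowed bases at each position. Useful to
#' give consensus motifs a principled log-odds score scale.
#'
#' @param iupac IUPAC consensus string (RNA `U` accepted, treated as `T`).
#' @return A probability matrix suitable for [pwm()].
#' @export
consensus_probs <- function(iupac) {
  allowed <- iupac_allowed(iupac) # 4 x L logical
  t(apply(allowed, 2, function(a) a / sum(a)))
}

#' Read a PWM from a 4-column probability table
#'
#' The format is a tab-separated table with header columns `A`, `C`, `G`,
#' `T`, one row per motif position; lines starting with `#` are comments
#' (a `# name=<motif>` comment sets the motif name).
#'
#' @param path Path to the probability TSV.
#' @param name Motif name; defaults to a `# name=` comment or the file stem.
#' @inheritParams pwm
#' @return A [pwm()] object.
#' @export
read_pwm <- function(path, name = NULL, background = rep(0.25, 4),
                     pseudocount = 0.01) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#\\s*name\\s*=", lines, value = TRUE)
  if (is.null(name)) {
    name <- if (length(meta)) trimws(sub("^#\\s*name\\s*=", "", meta[1])) else
      sub("\\.[^.]*$", "", basename(path))
  }
  d <- read_tsv(I(lines[!startsWith(lines, "#")]), col_types = "dddd",
                progress = FALSE)
  if (!setequal(names(d), BASES)) {
    abort(sprintf("PWM file %s must have columns A, C, G, T", path))
  }
  pwm(name, as.matrix(d[, BASES]), background = background,
      pseudocount = pseudocount)
}

#' Log-odds score matrix of a PWM
#'
#' Entry `(i, b)` is
#' `log2((p[i,b] + c * bg[b]) / ((1 + c) * bg[b]))` where `c` is the
#' pseudocount; with `c = 0` this is the plain log-odds of the motif
#' probability against the background, and zero cells score minus infinity.
#'
#' @param x A [pwm()] object.
#' @return A numeric matrix (positions x 4) of scores in bits.
#' @examples
#' log_odds(pwm("ex", matrix(c(1, 0, 0, 0), 1), pseudocount = 0))
#' @export
log_odds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  if (any(x$background == 0)) abort("background probabilities must be non-zero")
  bg <- matrix(x$background, nrow = x$length, ncol = 4, byrow = TRUE)
  log2((x$probs + x$pseudocount * bg) / ((1 + x$pseudocount) * bg))
}

# maximum attainable log-odds score (sum of per-position maxima)
max_score <- function(x) sum(apply(log_odds(x), 1, max))

#' Scan settings
#'
#' Collects the knobs of [scan_motifs()]: scoring mode, threshold style and
#' strand behaviour.
#'
#' @param mode `"pwm"` (log-odds scoring) or `"consensus"` (exact IUPAC
#'   matching).
#' @param threshold_frac Fraction of the maximum attainable score in
#'   `(0, 1]`; the default 0.8 is a reproducible stand-in for database scan
#'   cutoffs. Exactly one of `threshold_frac`/`threshold_bits` may be given.
#' @param threshold_bits Absolute score threshold in bits.
#' @param both_strands Scan the reverse strand too (genome-style scans);
#'   transcript scans are forward-only. Default `FALSE`.
#' @param iupac IUPAC consensus string; required when `mode = "consensus"`.
#' @return An object of class `scan_settings`.
#' @export
scan_settings <- function(mode = c("pwm", "consensus"), threshold_frac = NULL,
                          threshold_bits = NULL, both_strands = FALSE,
                          iupac = NULL) {
  mode <- match.arg(mode)
  if (!is.null(threshold_frac) && !is.null(threshold_bits)) {
    abort("give exactly one of threshold_frac or threshold_bits")
  }
  if (is.null(threshold_frac) && is.null(threshold_bits)) threshold_frac <- 0.8
  if (!is.null(threshold_frac) &&
      (threshold_frac <= 0 || threshold_frac > 1)) {
    abort("threshold_frac must be in (0, 1]")
  }
  if (mode == "consensus" && (is.null(iupac) || !nzchar(iupac))) {
    abort("consensus mode needs a non-empty iupac string")
  }
  if (mode == "pwm" && !is.null(iupac)) {
    abort("iupac is only meaningful in consensus mode")
  }
  structure(list(mode = mode, threshold_frac = threshold_frac,
                 threshold_bits = threshold_bits, both_strands = both_strands,
                 iupac = iupac),
            class = "scan_settings")
}

#' Resolve a scan threshold to bits
#'
#' Fraction-of-maximum thresholds are multiplied by the PWM's maximum
#' attainable score; absolute thresholds pass through unchanged.
#'
#' @param x A [pwm()] object.
#' @param settings A [scan_settings()] object.
#' @return Threshold in bits.
#' @export
resolve_threshold <- function(x, settings) {
  stopifnot(inherits(settings, "scan_settings"))
  if (!is.null(settings$threshold_bits)) return(settings$threshold_bits)
  settings$threshold_frac * max_score(x)
}
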