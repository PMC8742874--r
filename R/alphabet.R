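# Nucleotide alphabet helpers. Everything internal works on uppercase DNA
# (A, C, G, T, N); RNA input (U) is converted to T at load time.

BASES <- c("A", "C", "G", "T")

# IUPAC degeneracy codes -> allowed DNA bases
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

normalize_seq <- function(x) chartr("U", "T", toupper(x))

#' Reverse-complement a DNA/IUPAC string
#'
#' Vectorised reverse complement over the full IUPAC alphabet (U is treated
#' as T).
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements, uppercase DNA.
#' @examples
#' reverse_complement(c("TGCATG", "AAUU"))
#' @export
reverse_complement <- function(x) {
  x <- normalize_seq(x)
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    bad <- !ch %in% names(IUPAC_COMPLEMENT)
    if (any(bad)) {
      abort(sprintf("invalid nucleotide character(s): %s",
                    paste(unique(ch[bad]), collapse = ", ")))
    }
    paste(rev(unname(IUPAC_COMPLEMENT[ch])), collapse = "")
  }, character(1))
}

# Integer encoding A=1 C=2 G=3 T=4, anything else (incl. N) -> NA
encode_seq <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], BASES)
}

# Per-position allowed-base logical matrix (4 x L) for an IUPAC consensus
iupac_allowed <- function(iupac) {
  ch <- strsplit(normalize_seq(iupac), "", fixed = TRUE)[[1]]
  bad <- !ch %in% names(IUPAC)
  if (length(ch) == 0L) abort("consensus string is empty")
  if (any(bad)) {
    abort(sprintf("invalid IUPAC character(s) in consensus: %s",
                  paste(unique(ch[bad]), collapse = ", ")))
  }
  vapply(ch, function(c1) BASES %in% IUPAC[[c1]], logical(4))
}
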