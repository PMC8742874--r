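# Distance from each A-motif instance to the nearest B-motif instance, and
# the Monte-Carlo null with B instances placed uniformly at random in exon
# space.
#
# Gap convention (fixed and used identically for observed and null, so any
# constant offset cancels in the comparison): 0 for overlapping or
# book-ended intervals, otherwise the number of bases strictly between them
# (later.start - earlier.end under half-open coordinates).

#' Distance from each A interval to the nearest B interval
#'
#' For every interval in `a`, the minimum gap to any interval in `b` on the
#' same sequence. `a` intervals on sequences with no `b` interval are
#' excluded and counted in the `n_dropped` attribute.
#'
#' @param a,b Interval tibbles with columns `seq_id`, `start`, `end`
#'   (0-based half-open), e.g. hit tibbles from [scan_motifs()].
#' @param scope Label recording how the inputs were restricted
#'   (`"genome_wide"` or `"gene_restricted"`); carried as an attribute.
#' @return A `distance_set`: the rows of `a` that had a same-sequence
#'   partner, with a `distance` column (integer bases >= 0); attributes
#'   `n_dropped`, `n_a_total`, `scope`.
#' @examples
#' a <- tibble::tibble(seq_id = "chr1", start = 100, end = 106)
#' b <- tibble::tibble(seq_id = "chr1", start = 200, end = 206)
#' nearest_distance(a, b)$distance  # 94
#' @export
nearest_distance <- function(a, b, scope = c("genome_wide", "gene_restricted")) {
  scope <- match.arg(scope)
  stopifnot(all(c("seq_id", "start", "end") %in% names(a)),
            all(c("seq_id", "start", "end") %in% names(b)))
  n_a_total <- nrow(a)
  if (nrow(a) == 0) {
    out <- mutate(a, distance = numeric(0))
    return(structure(out, n_dropped = 0L, n_a_total = 0L, scope = scope,
                     class = c("distance_set", class(out))))
  }
  keep <- a$seq_id %in% unique(b$seq_id)
  dropped <- sum(!keep)
  a2 <- a[keep, , drop = FALSE]
  dist <- numeric(nrow(a2))
  for (sid in unique(a2$seq_id)) {
    ia <- which(a2$seq_id == sid)
    bs <- b[b$seq_id == sid, , drop = FALSE]
    starts <- sort(bs$start)
    ends <- sort(bs$end)
    as_ <- a2$start[ia]; ae <- a2$end[ia]
    # right neighbour: smallest b.start >= a.end
    k_right <- findInterval(ae - 0.5, starts) + 1L
    right_gap <- ifelse(k_right <= length(starts),
                        starts[pmin(k_right, length(starts))] - ae, Inf)
    # left neighbour: largest b.end <= a.start
    k_left <- findInterval(as_ + 0.5, ends)
    left_gap <- ifelse(k_left >= 1L, as_ - ends[pmax(k_left, 1L)], Inf)
    # overlap iff more b start before a.end than end at/before a.start
    n_start_lt <- findInterval(ae - 0.5, starts)
    overlaps <- n_start_lt > k_left
    dist[ia] <- ifelse(overlaps, 0, pmin(right_gap, left_gap))
  }
  out <- mutate(a2, distance = dist)
  structure(out, n_dropped = dropped, n_a_total = n_a_total, scope = scope,
            class = c("distance_set", class(out)))
}

#' @exportS3Method generics::tidy
tidy.distance_set <- function(x, ...) as_tibble(unclass(x))

#' @exportS3Method generics::glance
glance.distance_set <- function(x, ...) {
  tibble(n_a = nrow(x), n_dropped = attr(x, "n_dropped"),
         median_distance = if (nrow(x)) median(x$distance) else NA_real_,
         mean_distance = if (nrow(x)) mean(x$distance) else NA_real_,
         scope = attr(x, "scope"))
}

#' Null distribution of nearest distances under uniform placement in exons
#'
#' Repeats `n_sims` times: place `n_b` intervals of length `motif_len_b`
#' uniformly at random over the annotation's exon space (an exon is chosen
#' with probability proportional to its number of valid start positions,
#' `exon_len - motif_len_b + 1`, and the start is uniform within the exon),
#' then compute [nearest_distance()] from the fixed `a` set to the simulated
#' B set. Simulated intervals may overlap one another and `a`. Duplicate
#' exon intervals shared by several transcripts are used once.
#'
#' @param ann A [gene_annotation()] object supplying exon space.
#' @param a The observed A-motif intervals (tibble with `seq_id`, `start`,
#'   `end`).
#' @param n_b Number of B intervals per simulation; defaults to the observed
#'   B count, so pass `nrow(b_hits)`.
#' @param motif_len_b Length (bases) of the simulated B intervals.
#' @param n_sims Number of simulations; default 50.
#' @param seed Integer seed (optional, reproducible when given).
#' @inheritParams nearest_distance
#' @return A `null_distance` object: `$distances` (tibble `sim`,
#'   `distance`, pooled across simulations), `$medians` (tibble `sim`,
#'   `median`, `n`, `n_dropped`), plus `n_sims`, `n_b`, `motif_len_b`,
#'   `seed`, `n_a_total`, `scope`.
#' @export
simulate_null <- function(ann, a, n_b, motif_len_b, n_sims = 50, seed = NULL,
                          scope = c("genome_wide", "gene_restricted")) {
  scope <- match.arg(scope)
  stopifnot(inherits(ann, "gene_annotation"))
  if (n_sims < 1) abort("n_sims must be >= 1")
  if (n_b < 1) abort("n_b must be >= 1")
  exons <- ann$features |>
    filter(.data$type == "exon") |>
    distinct(.data$seq_id, .data$start, .data$end) |>
    mutate(w = .data$end - .data$start - motif_len_b + 1) |>
    filter(.data$w >= 1)
  if (nrow(exons) == 0) {
    abort("no exon is long enough for the simulated motif length")
  }
  run <- function() {
    map(seq_len(n_sims), function(s) {
      i <- sample.int(nrow(exons), n_b, replace = TRUE, prob = exons$w)
      off <- floor(runif(n_b) * exons$w[i])
      bsim <- tibble(seq_id = exons$seq_id[i],
                     start = exons$start[i] + off,
                     end = exons$start[i] + off + motif_len_b)
      ds <- nearest_distance(a, bsim, scope = scope)
      list(dist = tibble(sim = s, distance = ds$distance),
           med = tibble(sim = s,
                        median = if (nrow(ds)) median(ds$distance) else NA_real_,
                        n = nrow(ds), n_dropped = attr(ds, "n_dropped")))
    })
  }
  sims <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(
    distances = list_rbind(map(sims, "dist")),
    medians = list_rbind(map(sims, "med")),
    n_sims = n_sims, n_b = n_b, motif_len_b = motif_len_b, seed = seed,
    n_a_total = nrow(a), scope = scope
  ), class = "null_distance")
}

#' @export
print.null_distance <- function(x, ...) {
  cat(sprintf(
    "<null_distance> %d sim(s) of %d interval(s) (len %d) in exon space; median of per-sim medians: %.1f\n",
    x$n_sims, x$n_b, x$motif_len_b, median(x$medians$median, na.rm = TRUE)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.null_distance <- function(x, ...) x$medians

#' @exportS3Method generics::glance
glance.null_distance <- function(x, ...) {
  tibble(n_sims = x$n_sims, n_b = x$n_b, motif_len_b = x$motif_len_b,
         null_median_mean = mean(x$medians$median, na.rm = TRUE),
         null_median_sd = sd(x$medians$median),
         seed = x$seed %||% NA_integer_, scope = x$scope)
}

#' Compare observed nearest distances with the uniform-placement null
#'
#' Summarises an observed [nearest_distance()] result against a
#' [simulate_null()] run over the same A set: observed median, null median
#' mean ± sd over simulations, the empirical p (fraction of simulations
#' whose median is at most the observed median — small when the observed
#' motifs are closer together than random placement explains), and binned
#' density curves for plotting.
#'
#' @param observed A `distance_set` from [nearest_distance()].
#' @param null A `null_distance` from [simulate_null()] computed over the
#'   same A set (mismatched A counts are an error).
#' @param bins Number of histogram bins for the density curves.
#' @return A `distance_comparison` object; see [tidy()]/[autoplot()]
#'   methods.
#' @export
compare_to_null <- function(observed, null, bins = 30) {
  stopifnot(inherits(observed, "distance_set"), inherits(null, "null_distance"))
  if (attr(observed, "n_a_total") != null$n_a_total) {
    abort(sprintf("A-set mismatch: observed has %d intervals, null was built for %d",
                  attr(observed, "n_a_total"), null$n_a_total))
  }
  if (nrow(observed) == 0) abort("observed distance set is empty")
  obs_med <- median(observed$distance)
  meds <- null$medians$median
  n_le <- sum(meds <= obs_med, na.rm = TRUE)
  emp_p <- n_le / null$n_sims
  p_label <- if (n_le == 0) sprintf("< %.3g", 1 / null$n_sims) else
    sprintf("%.3g", emp_p)
  all_d <- c(observed$distance, null$distances$distance)
  breaks <- seq(0, max(all_d) + 1, length.out = bins + 1)
  dens <- bind_rows(
    bin_density(observed$distance, breaks, "observed"),
    bin_density(null$distances$distance, breaks, "null")
  )
  structure(list(
    observed_median = obs_med,
    null_median_mean = mean(meds, na.rm = TRUE),
    null_median_sd = sd(meds),
    empirical_p = emp_p, p_label = p_label, n_sims = null$n_sims,
    n_a = nrow(observed), density = dens
  ), class = "distance_comparison")
}

bin_density <- function(x, breaks, group) {
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  tibble(group = group, mid = h$mids, density = h$density)
}

#' @export
print.distance_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<distance_comparison> observed median %.1f nt vs null %.1f ",
           "± %.1f nt (%d sims); empirical p %s\n"),
    x$observed_median, x$null_median_mean, x$null_median_sd, x$n_sims,
    x$p_label))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.distance_comparison <- function(x, ...) {
  tibble(observed_median = x$observed_median,
         null_median_mean = x$null_median_mean,
         null_median_sd = x$null_median_sd,
         empirical_p = x$empirical_p, p_label = x$p_label,
         n_sims = x$n_sims, n_a = x$n_a)
}

#' @exportS3Method generics::glance
glance.distance_comparison <- function(x, ...) tidy(x)

#' @exportS3Method ggplot2::autoplot
autoplot.distance_comparison <- function(object, ...) {
  ggplot(object$density, aes(x = .data$mid, y = .data$density,
                             colour = .data$group)) +
    geom_line() +
    geom_vline(xintercept = object$observed_median, linetype = 2) +
    labs(x = "distance to nearest B motif (nt)", y = "density",
         colour = NULL,
         title = "Observed vs expected nearest-motif distances",
         subtitle = sprintf("observed median %.0f nt; empirical p %s",
                            object$observed_median, object$p_label)) +
    theme_minimal()
}
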