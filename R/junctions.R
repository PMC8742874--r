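# Percent usage of splice junctions sharing a donor (or acceptor):
# usage(x) = 100 * reads(D1 Ax) / (reads(D1 A1) + ... + reads(D1 An)),
# and with donor/acceptor roles swapped for acceptor-anchored events.

#' Declare junction-usage events
#'
#' Builds the event table consumed by [junction_usage()]. Events are
#' user-declared (hand-selected) alternative junction choices: one anchor
#' coordinate (a shared donor or acceptor) with two or more partner
#' coordinates. Coordinates are 1-based intron boundary positions as in the
#' STAR SJ.out.tab dialect (first/last intronic base).
#'
#' @param events A tibble (or data frame) with columns `event_id`,
#'   `anchor_type` (`"donor"` or `"acceptor"`), `seq_id`, `anchor_coord`,
#'   `partner_coord`, `partner_label`, `strand` — one row per alternative.
#' @return The validated event tibble.
#' @details For a stranded event the anchor role fixes its side of the
#'   intron: a donor lies at the intron start on `+` and at the intron end
#'   on `-` (and conversely for acceptors); rows violating this are an
#'   error. Partners must be distinct within an event.
#' @export
junction_events <- function(events) {
  events <- as_tibble(events)
  need <- c("event_id", "anchor_type", "seq_id", "anchor_coord",
            "partner_coord", "partner_label", "strand")
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    abort(sprintf("events table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!all(events$anchor_type %in% c("donor", "acceptor"))) {
    abort("anchor_type must be 'donor' or 'acceptor'")
  }
  dup <- events |> count(.data$event_id, .data$partner_coord) |> filter(n > 1)
  if (nrow(dup)) {
    abort(sprintf("event '%s' lists partner %d more than once",
                  dup$event_id[1], dup$partner_coord[1]))
  }
  multi_anchor <- events |>
    group_by(.data$event_id) |>
    summarise(k = n_distinct(.data$anchor_coord, .data$anchor_type,
                             .data$seq_id, .data$strand), .groups = "drop") |>
    filter(.data$k > 1)
  if (nrow(multi_anchor)) {
    abort(sprintf("event '%s' has inconsistent anchors", multi_anchor$event_id[1]))
  }
  # role/strand geometry: donor at intron start on '+', at intron end on '-'
  anchor_is_left <- (events$anchor_type == "donor") == (events$strand != "-")
  bad <- (events$strand %in% c("+", "-")) &
    ((anchor_is_left & events$anchor_coord >= events$partner_coord) |
       (!anchor_is_left & events$anchor_coord <= events$partner_coord))
  if (any(bad)) {
    abort(sprintf(
      "event '%s': anchor %d cannot be the %s of partner %d on strand %s",
      events$event_id[which(bad)[1]], events$anchor_coord[which(bad)[1]],
      events$anchor_type[which(bad)[1]], events$partner_coord[which(bad)[1]],
      events$strand[which(bad)[1]]))
  }
  events
}

#' Percent usage of alternative splice junctions
#'
#' For each declared event, matches its alternative junctions against the
#' junction table (exact coordinates after dialect conversion) and computes
#' per-alternative usage as `100 * reads / total reads of the event`.
#' Alternatives with no matching junction record count zero reads. Events
#' whose total is zero are flagged `undefined` and their percents reported
#' as missing (`NA`), not 0. Results are emitted per sample and, when
#' several samples are present, additionally pooled across samples
#' (`sample = "pooled"`).
#'
#' @param events Event tibble (see [junction_events()]; plain tibbles are
#'   validated on the way in).
#' @param junctions Junction tibble from [read_sj_tab()] (or
#'   [make_sj()]).
#' @param reads Which counts to use: `"unique"` (uniquely-mapping reads
#'   only, the default) or `"both"` (unique + multi-mapping).
#' @param pooled Add pooled-across-samples rows when there are several
#'   samples? Default `TRUE`.
#' @return A tibble with one row per (event, sample, alternative):
#'   `event_id`, `sample`, `partner_label`, `partner_coord`, `reads`,
#'   `total_reads`, `percent`, `undefined`. Percents within an event and
#'   sample sum to 100 (up to floating error) whenever `total_reads > 0`.
#' @details A matched junction record whose strand is defined and
#'   contradicts the event strand is an error (the anchor role would be
#'   inconsistent); unstranded records (code 0) match either strand.
#' @export
junction_usage <- function(events, junctions, reads = c("unique", "both"),
                           pooled = TRUE) {
  reads <- match.arg(reads)
  events <- junction_events(events)
  if (!"sample" %in% names(junctions)) junctions$sample <- "sample_1"
  samples <- unique(junctions$sample)
  jx <- junctions |>
    mutate(start1 = .data$donor_pos + 1L, end1 = .data$acceptor_pos,
           n_reads = if (reads == "unique") .data$unique_reads
                     else .data$unique_reads + .data$multi_reads)
  ev <- events |>
    mutate(start1 = pmin(.data$anchor_coord, .data$partner_coord),
           end1 = pmax(.data$anchor_coord, .data$partner_coord))
  hit <- ev |>
    inner_join(select(jx, "sample", "seq_id", "start1", "end1",
                      j_strand = "strand", "n_reads"),
               by = c("seq_id", "start1", "end1"),
               relationship = "many-to-many")
  conflict <- hit |>
    filter(.data$j_strand != ".", .data$strand != ".",
           .data$j_strand != .data$strand)
  if (nrow(conflict)) {
    abort(sprintf(
      "event '%s': matched junction %s:%d-%d is on strand %s, event declares %s",
      conflict$event_id[1], conflict$seq_id[1], conflict$start1[1],
      conflict$end1[1], conflict$j_strand[1], conflict$strand[1]))
  }
  per_sample <- expand_grid(
    distinct(ev, .data$event_id, .data$partner_label, .data$partner_coord),
    sample = samples
  ) |>
    left_join(hit |>
                group_by(.data$event_id, .data$partner_coord, .data$sample) |>
                summarise(reads = sum(.data$n_reads), .groups = "drop"),
              by = c("event_id", "partner_coord", "sample")) |>
    mutate(reads = replace_na(.data$reads, 0L))
  if (pooled && length(samples) > 1) {
    per_sample <- bind_rows(
      per_sample,
      per_sample |>
        group_by(.data$event_id, .data$partner_label, .data$partner_coord) |>
        summarise(reads = sum(.data$reads), .groups = "drop") |>
        mutate(sample = "pooled"))
  }
  per_sample |>
    group_by(.data$event_id, .data$sample) |>
    mutate(total_reads = sum(.data$reads),
           undefined = .data$total_reads == 0,
           percent = ifelse(.data$undefined, NA_real_,
                            100 * .data$reads / .data$total_reads)) |>
    ungroup() |>
    arrange(.data$event_id, .data$sample, .data$partner_coord)
}

#' List junctions sharing an anchor coordinate
#'
#' Helper for defining events: all junction records whose donor (or
#' acceptor) side sits at a given 1-based coordinate.
#'
#' @param junctions Junction tibble from [read_sj_tab()].
#' @param seq_id Sequence name.
#' @param coord 1-based intron boundary coordinate (as in the SJ dialect).
#' @param side Which intron side the coordinate refers to: `"start"` (first
#'   intronic base) or `"end"` (last intronic base).
#' @return The matching junction rows.
#' @export
list_anchor_junctions <- function(junctions, seq_id, coord,
                                  side = c("start", "end")) {
  side <- match.arg(side)
  if (side == "start") {
    filter(junctions, .data$seq_id == !!seq_id, .data$donor_pos + 1L == coord)
  } else {
    filter(junctions, .data$seq_id == !!seq_id, .data$acceptor_pos == coord)
  }
}

#' Stacked-bar plot of junction usage percentages
#'
#' One stacked bar per sample, one panel per event; undefined (zero-read)
#' event/sample combinations are omitted.
#'
#' @param usage Output of [junction_usage()].
#' @return A ggplot object.
#' @export
plot_junction_usage <- function(usage) {
  stopifnot(all(c("event_id", "sample", "percent") %in% names(usage)))
  ggplot(filter(usage, !.data$undefined),
         aes(x = .data$sample, y = .data$percent,
             fill = .data$partner_label)) +
    geom_col(position = position_stack()) +
    facet_wrap(~event_id) +
    labs(x = NULL, y = "% of junction reads", fill = "alternative") +
    theme_minimal()
}
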