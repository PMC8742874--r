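# Gel-band quantification: percent of signal within a lane / primer pair,
# and fold change normalised to a control gene and a control condition.

#' Percent of signal per band
#'
#' Within each group (lane / primer pair), each band's intensity as a
#' percentage of the summed intensity of all bands in the group:
#' `100 * intensity / sum(intensity)`. Groups whose intensities are all zero
#' are flagged `undefined` and get `NA` percents (never 0/0 -> 0).
#'
#' @param bands A tibble of band measurements.
#' @param intensity Column holding band intensities (tidy-eval; default
#'   `intensity`).
#' @param by Character vector of grouping columns defining "all bands
#'   generated by the same primer pair" (e.g. `c("sample_id", "target")`);
#'   `NULL` treats the whole table as one group.
#' @return `bands` with added columns `percent` and `undefined`. Percents
#'   sum to 100 within each defined group.
#' @examples
#' percent_of_signal(tibble::tibble(intensity = c(3, 6, 1)))
#' @export
percent_of_signal <- function(bands, intensity = intensity, by = NULL) {
  iq <- enquo(intensity)
  x <- eval_tidy(iq, bands)
  if (is.null(x)) abort("intensity column not found")
  if (any(x < 0)) abort("intensities must be >= 0")
  bands <- mutate(bands, .x = !!iq)
  grouped <- if (is.null(by)) bands else group_by(bands, across(all_of(by)))
  out <- grouped |>
    mutate(.tot = sum(.data$.x),
           undefined = .data$.tot == 0,
           percent = ifelse(.data$undefined, NA_real_,
                            100 * .data$.x / .data$.tot)) |>
    ungroup() |>
    select(-".x", -".tot")
  out
}

#' Normalised fold change from four intensities
#'
#' The elementary ratio-of-ratios:
#' `(sample_target / sample_control_gene) / (ref_target / ref_control_gene)`.
#' All inputs are recycled; any zero denominator is an error naming the
#' offending measurement.
#'
#' @param sample_target,sample_control_gene Target-band and
#'   control-gene-band intensities in the sample of interest.
#' @param ref_target,ref_control_gene The same two intensities in the
#'   reference (control) sample of the same replicate.
#' @return Numeric fold change(s).
#' @examples
#' fold_change_ratio(0.5, 1, 1, 1)  # 0.5
#' @export
fold_change_ratio <- function(sample_target, sample_control_gene,
                              ref_target, ref_control_gene) {
  if (any(sample_control_gene == 0)) abort("zero sample control-gene intensity")
  if (any(ref_control_gene == 0)) abort("zero reference control-gene intensity")
  if (any(ref_target == 0)) abort("zero reference target intensity")
  (sample_target / sample_control_gene) / (ref_target / ref_control_gene)
}

#' Fold change of band intensities against a control condition
#'
#' For each (replicate, condition, target) measurement, the target intensity
#' is first normalised to the control gene measured in the same condition
#' and replicate, then divided by the equally normalised intensity of the
#' reference condition *run in the same replicate*. Pairing within a
#' replicate is mandatory: a replicate lacking the reference condition or a
#' control-gene band is an error, never silently paired across replicates.
#'
#' @param bands Tibble with columns `condition`, `replicate`, `target`,
#'   `intensity` (one row per band).
#' @param reference_condition Condition label of the control samples.
#' @param control_gene Target label of the normalisation control band;
#'   default `"RpL32"`.
#' @return A tibble with one row per (replicate, non-reference condition,
#'   non-control target): `replicate`, `condition`, `target`,
#'   `fold_change`.
#' @export
fold_change <- function(bands, reference_condition, control_gene = "RpL32") {
  need <- c("condition", "replicate", "target", "intensity")
  miss <- setdiff(need, names(bands))
  if (length(miss)) {
    abort(sprintf("bands table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!reference_condition %in% bands$condition) {
    abort(sprintf("reference condition '%s' not present", reference_condition))
  }
  ctrl <- bands |>
    filter(.data$target == control_gene) |>
    select("condition", "replicate", control_intensity = "intensity")
  if (nrow(ctrl) == 0) {
    abort(sprintf("no '%s' control-gene bands found", control_gene))
  }
  norm <- bands |>
    filter(.data$target != control_gene) |>
    left_join(ctrl, by = c("condition", "replicate"))
  no_ctrl <- filter(norm, is.na(.data$control_intensity))
  if (nrow(no_ctrl)) {
    abort(sprintf("no %s measurement for condition '%s', replicate '%s'",
                  control_gene, no_ctrl$condition[1], no_ctrl$replicate[1]))
  }
  zero_ctrl <- filter(norm, .data$control_intensity == 0)
  if (nrow(zero_ctrl)) {
    abort(sprintf("zero %s intensity in condition '%s', replicate '%s'",
                  control_gene, zero_ctrl$condition[1], zero_ctrl$replicate[1]))
  }
  norm <- mutate(norm, norm_intensity = .data$intensity / .data$control_intensity)
  ref <- norm |>
    filter(.data$condition == reference_condition) |>
    select("replicate", "target", ref_norm = "norm_intensity")
  out <- norm |>
    filter(.data$condition != reference_condition) |>
    left_join(ref, by = c("replicate", "target"))
  no_ref <- filter(out, is.na(.data$ref_norm))
  if (nrow(no_ref)) {
    abort(sprintf(
      "no reference ('%s') measurement of target '%s' in replicate '%s'",
      reference_condition, no_ref$target[1], no_ref$replicate[1]))
  }
  zero_ref <- filter(out, .data$ref_norm == 0)
  if (nrow(zero_ref)) {
    abort(sprintf("zero reference intensity for target '%s', replicate '%s'",
                  zero_ref$target[1], zero_ref$replicate[1]))
  }
  out |>
    transmute(.data$replicate, .data$condition, .data$target,
              fold_change = .data$norm_intensity / .data$ref_norm)
}
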