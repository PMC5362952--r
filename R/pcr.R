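# PCR probe-panel LOY caller: per-probe normalization against normal
# samples, per-sample median amplification, mixture null fitted on normals
# only, and per-locus tumor/normal relative amplification.

#' Normalize a probe panel against the normal samples
#'
#' Divides every probe value by the median amplification of that probe
#' across the designated normal samples; an intact chromosome Y then sits
#' at 1.0 on every probe. Probes whose median over normals is zero are
#' dropped with a warning.
#'
#' @param panel Long tibble `probe_id`, `locus`, `sample_id`, `value`
#'   (control-primer-normalized amplification, non-negative).
#' @param normal_ids Sample ids of the reference normals (at least 2).
#' @return The panel with `value` replaced by the normalized amplification.
#' @export
normalize_probe_panel <- function(panel, normal_ids) {
  stopifnot(all(c("probe_id", "sample_id", "value") %in% names(panel)))
  if (any(panel$value < 0, na.rm = TRUE)) abort("negative probe values.")
  normal_ids <- intersect(normal_ids, unique(panel$sample_id))
  if (length(normal_ids) < 2) {
    abort("at least 2 normal samples are required for probe normalization.")
  }
  ref <- panel |>
    dplyr::filter(.data$sample_id %in% normal_ids) |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(ref = median(.data$value), .groups = "drop")
  dead <- ref$probe_id[ref$ref == 0]
  if (length(dead)) {
    warn(paste0("probe(s) with zero median across normals dropped: ",
                paste(dead, collapse = ", ")))
  }
  panel |>
    dplyr::inner_join(dplyr::filter(ref, .data$ref > 0), by = "probe_id") |>
    dplyr::mutate(value = .data$value / .data$ref) |>
    dplyr::select(-"ref")
}

#' Per-sample median normalized amplification
#'
#' The median across retained probes summarizes the overall amplification
#' of chromosome Y in each sample (1.0 for an intact Y).
#'
#' @param panel Normalized panel from [normalize_probe_panel()].
#' @return Tibble `sample_id`, `amplification`.
#' @export
probe_summaries <- function(panel) {
  if (!nrow(panel)) abort("no probes retained.")
  panel |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(amplification = median(.data$value), .groups = "drop")
}

#' Call LOY from probe-panel summaries
#'
#' Fits the Gaussian mixture null to the normal samples' summaries only,
#' derives two-sided p-values for every sample, estimates the affected cell
#' fraction as `1 - amplification` (expected amplification is 1 for an
#' intact single-copy Y after normalization), and flags samples with
#' `p < alpha` and fraction strictly above `min_fraction`.
#'
#' @param summaries Tibble from [probe_summaries()].
#' @param normal_ids Sample ids of the reference normals.
#' @param alpha Raw p-value threshold (default 0.01; no multiplicity
#'   correction, matching the assay's per-sample decision rule).
#' @param min_fraction Minimum affected fraction (default 0.10).
#' @param strict Require fraction strictly above the threshold (default
#'   `TRUE` for the PCR assay).
#' @param min_separation Passed to [fit_mixture_null()]; defaults to the
#'   amplification shift at the minimum callable fraction.
#' @param ... Passed to [fit_mixture_null()].
#' @return Tibble `sample_id`, `amplification`, `p`, `fraction`, `flagged`,
#'   with the fitted null attached as attribute `"null"`.
#' @export
call_pcr_loy <- function(summaries, normal_ids, alpha = 0.01,
                         min_fraction = 0.10, strict = TRUE,
                         min_separation = min_fraction, ...) {
  ref <- summaries$amplification[summaries$sample_id %in% normal_ids]
  if (!length(ref)) abort("no normal samples among the summaries.")
  fit <- fit_mixture_null(ref, baseline = 1,
                          min_separation = min_separation, ...)
  out <- summaries |>
    dplyr::mutate(
      p = null_pvalue(.data$amplification, fit),
      fraction = pmin(pmax(1 - .data$amplification, 0), 1),
      flagged = .data$p < alpha &
        (if (strict) .data$fraction > min_fraction
         else .data$fraction >= min_fraction)
    )
  attr(out, "null") <- fit
  out
}

#' Per-locus tumor/normal relative amplification
#'
#' For each patient with both a tumor and a matched normal in the panel,
#' the ratio of tumor to normal amplification per locus (the per-locus
#' verification figure analogue). Loci with zero normal amplification are
#' skipped with a warning.
#'
#' @param panel Probe panel (raw or normalized), long format.
#' @param samples Sample sheet with `sample_id`, `patient_id`, `tissue`.
#' @return Tibble `patient_id`, `probe_id`, `locus`, `ratio`.
#' @export
relative_amplification <- function(panel, samples) {
  df <- panel |>
    dplyr::inner_join(
      dplyr::select(samples, "sample_id", "patient_id", "tissue"),
      by = "sample_id"
    ) |>
    dplyr::filter(.data$tissue %in% c("tumor", "normal")) |>
    dplyr::select(-"sample_id") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "value") |>
    dplyr::filter(!is.na(.data$tumor), !is.na(.data$normal))
  if (!nrow(df)) abort("no matched tumor/normal pairs in the panel.")
  zero <- df$normal == 0
  if (any(zero)) {
    warn(paste0(sum(zero), " locus/patient pair(s) with zero normal ",
                "amplification skipped."))
  }
  df |>
    dplyr::filter(.data$normal > 0) |>
    dplyr::mutate(ratio = .data$tumor / .data$normal) |>
    dplyr::select("patient_id", "probe_id", "locus", "ratio")
}

#' Group summary of relative amplification by LOY status
#'
#' Mean and range of the per-locus tumor/normal ratios across patients,
#' split into LOY and non-LOY groups.
#'
#' @param rel Output of [relative_amplification()].
#' @param loy_patients Patient ids affected by somatic LOY.
#' @return Tibble `probe_id`, `locus`, `group`, `mean_ratio`, `min_ratio`,
#'   `max_ratio`, `n`.
#' @export
locus_amplification_summary <- function(rel, loy_patients) {
  rel |>
    dplyr::mutate(group = ifelse(.data$patient_id %in% loy_patients,
                                 "LOY", "no LOY")) |>
    dplyr::group_by(.data$probe_id, .data$locus, .data$group) |>
    dplyr::summarise(
      mean_ratio = mean(.data$ratio),
      min_ratio = min(.data$ratio),
      max_ratio = max(.data$ratio),
      n = dplyr::n(),
      .groups = "drop"
    )
}
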