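# Arm-level aneuploidy calling: mixture null per arm unit, Bonferroni
# correction, minimum-cell-fraction filter, and cell-fraction estimation.

#' Estimate the aberrant cell fraction from normalized coverage
#'
#' The fraction of cells carrying a one-copy change is the missing (or
#' excess) coverage divided by the per-copy coverage step. Single-copy
#' units (baseline 0.5, i.e. male X or Y) lose their only copy, so
#' `f = (0.5 - cov) / 0.5` for a loss; two-copy units (baseline 1.0)
#' change one of two copies, so `f = (1 - cov) / 0.5` for a loss and
#' `f = (cov - 1) / 0.5` for a gain. Results are clipped to `[0, 1]`.
#'
#' @param coverage Normalized arm-median coverage (non-negative).
#' @param baseline Expected coverage, 0.5 or 1.0 (recycled).
#' @param direction `"loss"` or `"gain"` (recycled).
#' @return Estimated cell fraction in `[0, 1]`.
#' @export
#' @examples
#' estimate_cell_fraction(0.125, 0.5, "loss") # 0.75
estimate_cell_fraction <- function(coverage, baseline, direction = "loss") {
  n <- max(length(coverage), length(baseline), length(direction))
  coverage <- rep_len(coverage, n)
  baseline <- rep_len(baseline, n)
  direction <- rep_len(direction, n)
  if (any(coverage < 0, na.rm = TRUE)) abort("negative coverage.")
  if (!all(baseline %in% c(0.5, 1))) abort("baseline must be 0.5 or 1.0.")
  if (!all(direction %in% c("loss", "gain"))) {
    abort("direction must be \"loss\" or \"gain\".")
  }
  copies <- ifelse(baseline == 0.5, 1, 2)
  step <- baseline / copies # coverage change per fully-affected cohort
  f <- ifelse(direction == "loss",
              (baseline - coverage) / step,
              (coverage - baseline) / step)
  pmin(pmax(f, 0), 1)
}

#' Call chromosome-arm aneuploidies across a cohort
#'
#' For each arm unit, fits the Gaussian mixture null to the arm-median
#' coverage across all samples (sex-stratified for sex-chromosome arms,
#' whose baselines differ between sexes), derives two-sided p-values from
#' the null component, applies a Bonferroni correction over all tests
#' performed, estimates the aberrant cell fraction, and flags calls with
#' adjusted p below `alpha` and fraction at least `min_fraction`.
#'
#' @param armcov Long tibble `sample_id`, `arm`, `coverage` from
#'   [arm_coverage()].
#' @param samples Sample sheet (`sample_id`, `tissue`, `sex`, ...).
#' @param genome A `genome_model`.
#' @param alpha Significance level on the Bonferroni-adjusted p (default 0.01).
#' @param min_fraction Minimum aberrant cell fraction (default 0.10).
#' @param strict If `TRUE` require fraction strictly above `min_fraction`;
#'   default `FALSE` (at least `min_fraction`).
#' @param bonferroni_m Multiplicity; defaults to the number of
#'   (sample, arm) tests performed.
#' @param min_separation Passed to [fit_mixture_null()]; defaults to the
#'   coverage shift produced by a one-copy change in `min_fraction` of
#'   cells (`min_fraction * 0.5` on both one- and two-copy units).
#' @param by_tissue Additionally stratify the mixture fit by tissue
#'   (default `FALSE`: tumors and normals share the null, which keeps the
#'   null anchored at the baseline even for near-ubiquitous tumor events
#'   such as 3p loss).
#' @param ... Passed to [fit_mixture_null()].
#' @return Tibble with one row per test: `sample_id`, `arm`, `tissue`,
#'   `sex`, `coverage`, `baseline`, `direction`, `p`, `p_adj`, `fraction`,
#'   `flagged`. The fitted nulls are attached as attribute `"nulls"`.
#' @export
call_aneuploidy <- function(armcov, samples, genome, alpha = 0.01,
                            min_fraction = 0.10, strict = FALSE,
                            bonferroni_m = NULL, by_tissue = FALSE,
                            min_separation = min_fraction * 0.5, ...) {
  stopifnot(inherits(genome, "genome_model"))
  df <- armcov |>
    dplyr::inner_join(
      dplyr::select(samples, "sample_id", "tissue", "sex"),
      by = "sample_id"
    ) |>
    dplyr::filter(is.finite(.data$coverage))
  if (!nrow(df)) abort("no finite coverage values to test.")
  sex_chrom <- genome$arms$arm[genome$arms$chrom %in% c("chrX", "chrY")]
  df <- df |>
    dplyr::mutate(
      baseline = arm_baseline(genome, .data$arm, .data$sex),
      .group = paste(.data$arm,
                     ifelse(.data$arm %in% sex_chrom, .data$sex, "all"),
                     if (by_tissue) .data$tissue else "", sep = "/")
    )
  m <- bonferroni_m %||% nrow(df)

  fits <- list()
  out <- df |>
    dplyr::group_by(.data$.group) |>
    dplyr::group_modify(function(g, key) {
      fit <- fit_mixture_null(g$coverage, baseline = g$baseline[1],
                              min_separation = min_separation, ...)
      fits[[key$.group[1]]] <<- fit
      mu0 <- fit$mu[fit$null]
      g |>
        dplyr::mutate(
          direction = ifelse(.data$coverage < mu0, "loss", "gain"),
          p = null_pvalue(.data$coverage, fit),
          p_adj = pmin(1, m * .data$p),
          fraction = estimate_cell_fraction(.data$coverage, .data$baseline,
                                            .data$direction)
        )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      flagged = .data$p_adj < alpha &
        (if (strict) .data$fraction > min_fraction
         else .data$fraction >= min_fraction)
    ) |>
    dplyr::select("sample_id", "arm", "tissue", "sex", "coverage",
                  "baseline", "direction", "p", "p_adj", "fraction",
                  "flagged") |>
    dplyr::arrange(.data$sample_id, .data$arm)

  nulls <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(group = nm, n = f$n, k = f$k,
                   null_mean = f$mu[f$null], null_sd = f$sigma[f$null],
                   null_weight = f$weight[f$null], fallback = f$fallback)
  })
  attr(out, "nulls") <- nulls
  out
}

#' Flagged-aneuploidy frequency by arm, sex and direction
#'
#' Cohort summary of the calls (the frequency-by-arm bar-chart analogue):
#' per arm, sex, tissue and direction, the number and percentage of tested
#' samples flagged.
#'
#' @param calls Output of [call_aneuploidy()].
#' @return Tibble `arm`, `tissue`, `sex`, `direction`, `n_flagged`,
#'   `n_tested`, `percent`.
#' @export
aneuploidy_frequency <- function(calls) {
  calls |>
    dplyr::group_by(.data$arm, .data$tissue, .data$sex, .data$direction) |>
    dplyr::summarise(
      n_flagged = sum(.data$flagged),
      n_tested = dplyr::n_distinct(.data$sample_id),
      .groups = "drop_last"
    ) |>
    dplyr::mutate(n_tested = sum(.data$n_tested)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_flagged > 0) |>
    dplyr::mutate(percent = 100 * .data$n_flagged / .data$n_tested)
}

#' Samples with a whole-chromosome loss
#'
#' A multi-arm chromosome counts as lost in a sample only when every one of
#' its arm units is flagged as a loss (the whole-chromosome criterion used
#' for loss of X); for chrY the single unit decides.
#'
#' @param calls Output of [call_aneuploidy()].
#' @param genome A `genome_model`.
#' @param chrom Chromosome name, e.g. `"chrX"`.
#' @return Tibble `sample_id`, `tissue`, `sex`, `n_arms`, `n_flagged_loss`,
#'   `whole_loss`, `fraction` (mean estimated fraction over flagged arms,
#'   `NA` if none).
#' @export
whole_chromosome_losses <- function(calls, genome, chrom = "chrX") {
  arms <- genome$arms$arm[genome$arms$chrom == chrom]
  if (!length(arms)) abort(paste0("unknown chromosome: ", chrom))
  calls |>
    dplyr::filter(.data$arm %in% arms) |>
    dplyr::group_by(.data$sample_id, .data$tissue, .data$sex) |>
    dplyr::summarise(
      n_arms = dplyr::n(),
      n_flagged_loss = sum(.data$flagged & .data$direction == "loss"),
      whole_loss = .data$n_arms == length(arms) &
        .data$n_flagged_loss == length(arms),
      fraction = ifelse(.data$n_flagged_loss > 0,
                        mean(.data$fraction[.data$flagged &
                                              .data$direction == "loss"]),
                        NA_real_),
      .groups = "drop"
    )
}

#' Tumor-versus-blood chromosome-Y status per patient
#'
#' The per-patient scatter analogue: chrY arm-median coverage in the tumor
#' against the matched normal, with the LOY flag of each.
#'
#' @param calls Output of [call_aneuploidy()].
#' @param samples Sample sheet with `patient_id`.
#' @return Tibble `patient_id`, `tumor_coverage`, `normal_coverage`,
#'   `tumor_loy`, `normal_loy`.
#' @export
y_status_table <- function(calls, samples) {
  calls |>
    dplyr::filter(.data$arm == "chrY") |>
    dplyr::inner_join(dplyr::select(samples, "sample_id", "patient_id"),
                      by = "sample_id") |>
    dplyr::mutate(loy = .data$flagged & .data$direction == "loss") |>
    dplyr::select("patient_id", "tissue", "coverage", "loy") |>
    tidyr::pivot_wider(names_from = "tissue",
                       values_from = c("coverage", "loy")) |>
    dplyr::rename(tumor_coverage = "coverage_tumor",
                  normal_coverage = "coverage_normal",
                  tumor_loy = "loy_tumor", normal_loy = "loy_normal")
}
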