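# ggplot2 summaries of the main result types.

#' Plot flagged-aneuploidy frequency by arm and sex
#'
#' Bar chart of the percentage of samples flagged per arm unit, faceted by
#' sex, losses downward and gains upward.
#'
#' @param freq Output of [aneuploidy_frequency()].
#' @param tissue Tissue to display (default `"tumor"`).
#' @return A ggplot object.
#' @export
plot_arm_frequency <- function(freq, tissue = "tumor") {
  df <- freq |>
    dplyr::filter(.data$tissue == !!tissue) |>
    dplyr::mutate(
      signed = ifelse(.data$direction == "loss", -.data$percent,
                      .data$percent)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$signed,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~sex, ncol = 1) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "chromosome arm", y = "% of samples flagged",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot tumor-versus-blood chromosome-Y coverage
#'
#' Per-patient scatter of chrY arm-median coverage in tumor against matched
#' normal, colored by LOY status; the dashed lines mark the intact
#' single-copy expectation of 0.5.
#'
#' @param ystatus Output of [y_status_table()].
#' @return A ggplot object.
#' @export
plot_y_status <- function(ystatus) {
  df <- ystatus |>
    dplyr::mutate(status = dplyr::case_when(
      .data$tumor_loy & .data$normal_loy ~ "tumor + blood LOY",
      .data$tumor_loy ~ "somatic LOY",
      .data$normal_loy ~ "mosaic blood LOY",
      TRUE ~ "no LOY"
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$normal_coverage,
                                   y = .data$tumor_coverage,
                                   color = .data$status)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "chrY coverage, blood", y = "chrY coverage, tumor",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-locus tumor/normal relative amplification by LOY group
#'
#' @param summary Output of [locus_amplification_summary()].
#' @return A ggplot object.
#' @export
plot_locus_amplification <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$locus, y = .data$mean_ratio,
                               color = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$min_ratio,
                                          ymax = .data$max_ratio),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "Y locus", y = "tumor / normal amplification",
                  color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot gene expression against the LOY cell fraction
#'
#' One panel per gene: per-sample expression (RPKM) against the estimated
#' proportion of cells with LOY, with the least-squares line.
#'
#' @param expr Expression tibble (`gene_id`, `chrom`, sample columns).
#' @param fractions Named numeric vector of LOY fractions by sample id.
#' @param genes Gene ids to display (default: chrY genes in `expr`).
#' @return A ggplot object.
#' @export
plot_expression_vs_fraction <- function(expr, fractions, genes = NULL) {
  genes <- genes %||% expr$gene_id[expr$chrom == "chrY"]
  df <- expr |>
    dplyr::filter(.data$gene_id %in% genes) |>
    tidyr::pivot_longer(-c("gene_id", "chrom"), names_to = "sample_id",
                        values_to = "rpkm") |>
    dplyr::filter(.data$sample_id %in% names(fractions)) |>
    dplyr::mutate(fraction = fractions[.data$sample_id])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$rpkm)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~gene_id, scales = "free_y") +
    ggplot2::labs(x = "proportion of cells with LOY", y = "RPKM") +
    ggplot2::theme_minimal()
}
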