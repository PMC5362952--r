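# Coverage normalization: per-sample autosomal-median scaling, sex-aware
# stable-bin selection in normal samples, and per-arm median coverage.

#' Normalize binned counts by the autosomal median
#'
#' Divides every bin count of a sample by that sample's median count over
#' all autosomal bins, so diploid autosomes sit at 1.0 and a single-copy
#' sex chromosome at 0.5 regardless of sequencing depth. Sex plays no role
#' in the normalization itself.
#'
#' @param counts Bin table (`chrom`, `start`, `end`, `arm` + one column per
#'   sample) on the genome's bin grid.
#' @param genome A `genome_model`.
#' @return Tibble of the same shape with normalized (dimensionless) values.
#' @export
normalize_coverage <- function(counts, genome) {
  stopifnot(inherits(genome, "genome_model"))
  check_bin_grid(counts, genome)
  ids <- bin_sample_cols(counts)
  if (!length(ids)) abort("no sample columns in `counts`.")
  m <- as.matrix(counts[ids])
  if (any(m < 0, na.rm = TRUE)) abort("negative counts.")
  auto <- genome$bins$arm %in% autosomal_arms(genome)
  med <- apply(m[auto, , drop = FALSE], 2, median)
  if (any(med == 0)) {
    abort(paste0("autosomal median coverage is zero for sample(s): ",
                 paste(ids[med == 0], collapse = ", "),
                 " - sample unusable."))
  }
  norm <- sweep(m, 2, med, "/")
  dplyr::bind_cols(genome$bins, tibble::as_tibble(norm))
}

#' Select stable bins per arm from normal samples
#'
#' For each bin, computes the median over usable normal samples of the
#' absolute divergence between normalized coverage and the sex-aware
#' expected baseline of the bin's arm, then keeps the `k` bins per arm with
#' the lowest median divergence (ties broken by genomic position, leftmost
#' first). Bins of the Y chromosome use male normals only; female samples
#' never contribute to (or receive) chrY values. Bins with zero coverage in
#' at least half of the usable normals are excluded before ranking.
#'
#' @param normalized Normalized bin table from [normalize_coverage()].
#' @param samples Sample sheet; rows with `tissue == "normal"` define the
#'   reference set.
#' @param genome A `genome_model`.
#' @param k Bins kept per arm (default 1000, clamped to the arm size).
#' @param max_zero_frac Exclusion threshold on the fraction of usable
#'   normals with zero coverage in a bin (default 0.5).
#' @return Tibble `chrom`, `start`, `end`, `arm`, `divergence`, ordered by
#'   increasing divergence within arm.
#' @export
select_stable_bins <- function(normalized, samples, genome, k = 1000,
                               max_zero_frac = 0.5) {
  stopifnot(inherits(genome, "genome_model"))
  if (k < 1) abort("`k` must be at least 1.")
  normals <- samples[samples$tissue == "normal", ]
  ids <- intersect(normals$sample_id, bin_sample_cols(normalized))
  if (!length(ids)) abort("no normal samples available for bin selection.")
  v <- as.matrix(normalized[ids])
  sex <- normals$sex[match(ids, normals$sample_id)]

  arm_idx <- match(genome$bins$arm, genome$arms$arm)
  bl <- vapply(seq_along(ids), function(j) {
    if (sex[j] == "male") genome$arms$baseline_male[arm_idx]
    else genome$arms$baseline_female[arm_idx]
  }, numeric(nrow(genome$bins)))

  dev <- abs(v - bl) # NA where the arm is absent in that sex
  usable <- !is.na(bl)
  n_usable <- rowSums(usable)
  div <- rep(NA_real_, nrow(dev))
  ok <- n_usable > 0
  div[ok] <- apply(dev[ok, , drop = FALSE], 1, median, na.rm = TRUE)
  zero_frac <- rowSums((v == 0) & usable) / pmax(n_usable, 1)

  dropped_arms <- unique(genome$bins$arm[!ok])
  if (length(dropped_arms)) {
    warn(paste0("arm(s) without usable normals dropped: ",
                paste(dropped_arms, collapse = ", ")))
  }

  tibble::tibble(genome$bins, divergence = div, zero_frac = zero_frac) |>
    dplyr::filter(!is.na(.data$divergence),
                  .data$zero_frac < max_zero_frac) |>
    dplyr::group_by(.data$arm) |>
    dplyr::arrange(.data$divergence, .data$start, .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup() |>
    dplyr::select("chrom", "start", "end", "arm", "divergence")
}

#' Per-sample median normalized coverage by arm unit
#'
#' For every sample and arm unit, the median normalized coverage over that
#' arm's selected stable bins. Chromosome Y is a single unit and is not
#' reported for female samples.
#'
#' @param normalized Normalized bin table.
#' @param selection Stable-bin selection from [select_stable_bins()].
#' @param samples Sample sheet (used for sex; all of its samples present in
#'   `normalized` are reported).
#' @param genome A `genome_model`.
#' @return Long tibble `sample_id`, `arm`, `coverage`.
#' @export
arm_coverage <- function(normalized, selection, samples, genome) {
  stopifnot(inherits(genome, "genome_model"))
  ids <- intersect(samples$sample_id, bin_sample_cols(normalized))
  if (!length(ids)) abort("no overlap between `samples` and `normalized`.")
  key <- paste(normalized$chrom, normalized$start)
  sel_rows <- split(match(paste(selection$chrom, selection$start), key),
                    selection$arm)
  if (anyNA(unlist(sel_rows))) {
    abort("selection refers to bins absent from `normalized`.")
  }
  v <- as.matrix(normalized[ids])
  sex <- samples$sex[match(ids, samples$sample_id)]
  arms <- genome$arms$arm[genome$arms$arm %in% names(sel_rows)]

  out <- tidyr::expand_grid(sample_id = ids, arm = arms)
  out$coverage <- purrr::map2_dbl(out$sample_id, out$arm, function(s, a) {
    median(v[sel_rows[[a]], match(s, ids)])
  })
  # chrY does not exist in females: never report it
  female_ids <- ids[sex == "female"]
  out |>
    dplyr::filter(!(.data$arm == "chrY" & .data$sample_id %in% female_ids))
}
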