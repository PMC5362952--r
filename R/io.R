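# Readers/writers for the TSV interchange formats (BED-style bin counts,
# sample sheets, arm-coverage, probe panels, expression matrices) and the
# end-to-end pipeline driver. All files are tab-delimited UTF-8 with `.`
# decimals; coordinates are 0-based half-open.

#' Read per-sample bin counts from a BED-style TSV
#'
#' Four tab-separated columns (chrom, start, end, count), optional
#' `#`-prefixed header, 0-based half-open coordinates. Rows are sorted into
#' genome order on load, validated against the genome bin grid, and checked
#' for negative or non-integer counts.
#'
#' @param path File path.
#' @param genome A `genome_model`.
#' @return Tibble `chrom`, `start`, `end`, `arm`, `count` in grid order.
#' @export
read_bed_counts <- function(path, genome) {
  stopifnot(inherits(genome, "genome_model"))
  raw <- readr::read_tsv(
    path, comment = "#",
    col_names = c("chrom", "start", "end", "count"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), count = readr::col_double()
    ),
    progress = FALSE
  )
  bad <- which(is.na(raw$start) | is.na(raw$end) | is.na(raw$count) |
                 raw$count < 0 | raw$count != floor(raw$count))
  if (length(bad)) {
    abort(paste0("malformed or negative count at line ", bad[1],
                 " of ", path))
  }
  chrom_levels <- unique(genome$bins$chrom)
  if (!all(raw$chrom %in% chrom_levels)) {
    abort(paste0("unknown chromosome in ", path, ": ",
                 setdiff(raw$chrom, chrom_levels)[1]))
  }
  raw <- raw[order(match(raw$chrom, chrom_levels), raw$start), ]
  key_g <- paste(genome$bins$chrom, genome$bins$start, genome$bins$end)
  key_r <- paste(raw$chrom, raw$start, raw$end)
  if (!identical(key_g, key_r)) {
    miss <- setdiff(key_g, key_r)
    extra <- setdiff(key_r, key_g)
    off <- if (length(miss)) paste0("missing bin ", miss[1])
           else if (length(extra)) paste0("unexpected bin ", extra[1])
           else "duplicated bins"
    abort(paste0(path, " does not match the genome bin grid: ", off))
  }
  dplyr::bind_cols(genome$bins, count = as.integer(raw$count))
}

#' Write per-sample bin counts as BED-style TSVs
#'
#' One 4-column file per sample column, named `<sample_id>.bed`.
#'
#' @param counts Bin table (`chrom`, `start`, `end`, `arm` + sample columns).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_bin_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- bin_sample_cols(counts)
  paths <- purrr::map_chr(ids, function(s) {
    p <- file.path(dir, paste0(s, ".bed"))
    readr::write_tsv(counts[c("chrom", "start", "end", s)], p,
                     col_names = FALSE, progress = FALSE)
    p
  })
  invisible(paths)
}

#' Read a combined bin-count matrix TSV
#'
#' Bin rows with three leading coordinate columns (`chrom`, `start`, `end`)
#' followed by one column per sample; validated against the genome grid.
#'
#' @param path File path.
#' @param genome A `genome_model`.
#' @return Bin table `chrom`, `start`, `end`, `arm` + sample columns.
#' @export
read_count_matrix <- function(path, genome) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(raw)))
  raw <- raw[order(match(raw$chrom, unique(genome$bins$chrom)), raw$start), ]
  check_bin_grid(raw, genome, what = basename(path))
  dplyr::bind_cols(genome$bins,
                   raw[setdiff(names(raw), c("chrom", "start", "end", "arm"))])
}

#' Write/read the long arm-coverage table as a samples-by-arms TSV
#' @param armcov Long tibble from [arm_coverage()].
#' @param path File path.
#' @return `write_arm_coverage`: the path, invisibly. `read_arm_coverage`:
#'   the long tibble.
#' @export
write_arm_coverage <- function(armcov, path) {
  wide <- tidyr::pivot_wider(armcov, names_from = "arm",
                             values_from = "coverage")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_arm_coverage
#' @export
read_arm_coverage <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    tidyr::pivot_longer(-"sample_id", names_to = "arm",
                        values_to = "coverage") |>
    dplyr::filter(!is.na(.data$coverage))
}

#' Read a sample sheet TSV
#' @param path File path (columns `sample_id`, `patient_id`, `tissue`,
#'   `sex`, plus optional covariates).
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  s <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("sample_id", "tissue", "sex") %in% names(s)))
  s
}

#' Read a probe panel TSV (wide: probe_id, locus, one column per sample)
#' @param path File path.
#' @return Long tibble `probe_id`, `locus`, `sample_id`, `value`.
#' @export
read_probe_panel <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    tidyr::pivot_longer(-c("probe_id", "locus"), names_to = "sample_id",
                        values_to = "value")
}

#' Write a probe panel TSV (wide format)
#' @param panel Long tibble `probe_id`, `locus`, `sample_id`, `value`.
#' @param path File path.
#' @export
write_probe_panel <- function(panel, path) {
  tidyr::pivot_wider(panel, names_from = "sample_id",
                     values_from = "value") |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Read an expression matrix TSV (gene_id, chrom, one column per sample)
#' @param path File path.
#' @return Tibble.
#' @export
read_expression_matrix <- function(path) {
  e <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("gene_id", "chrom") %in% names(e)))
  e
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulate -> normalize -> stable bins -> arm medians -> aneuploidy calls
#' -> PCR calls -> association statistics, writing every table plus a
#' machine-readable manifest (thresholds, seed, fitted null parameters)
#' into `out_dir`. Deterministic given `seed`.
#'
#' @param config Cohort configuration from [cohort_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param k Stable bins per arm (default 1000).
#' @param alpha Bonferroni-adjusted significance level (default 0.01).
#' @param min_fraction Minimum aberrant cell fraction (default 0.10).
#' @param fdr Differential-expression FDR threshold (default 0.01).
#' @return Invisibly, a list with the main result tables.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1, out_dir,
                         k = 1000, alpha = 0.01, min_fraction = 0.10,
                         fdr = 0.01) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) inform(paste0("[armloy] ", ...))

  cohort <- simulate_cohort(config, seed = seed)
  log_line("simulated cohort: ", nrow(cohort$samples), " samples, ",
           nrow(cohort$truth), " planted event rows")
  readr::write_tsv(cohort$samples, file.path(out_dir, "samples.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth, file.path(out_dir, "truth.tsv"),
                   progress = FALSE)

  norm <- normalize_coverage(cohort$counts, cohort$genome)
  sel <- select_stable_bins(norm, cohort$samples, cohort$genome, k = k)
  log_line("selected ", nrow(sel), " stable bins over ",
           dplyr::n_distinct(sel$arm), " arm units")
  readr::write_tsv(sel, file.path(out_dir, "stable_bins.bed"),
                   col_names = FALSE, progress = FALSE)

  armcov <- arm_coverage(norm, sel, cohort$samples, cohort$genome)
  write_arm_coverage(armcov, file.path(out_dir, "arm_coverage.tsv"))

  calls <- call_aneuploidy(armcov, cohort$samples, cohort$genome,
                           alpha = alpha, min_fraction = min_fraction)
  readr::write_tsv(calls, file.path(out_dir, "calls.tsv"), progress = FALSE)
  freq <- aneuploidy_frequency(calls)
  readr::write_tsv(freq, file.path(out_dir, "frequency.tsv"),
                   progress = FALSE)
  nulls <- attr(calls, "nulls")
  log_line("flagged ", sum(calls$flagged), " of ", nrow(calls),
           " sample-arm tests")

  pcr <- NULL
  if (!is.null(cohort$probes)) {
    normal_ids <- cohort$samples$sample_id[
      cohort$samples$tissue == "normal" & cohort$samples$sex == "male"]
    npanel <- normalize_probe_panel(cohort$probes, normal_ids)
    pcr <- call_pcr_loy(probe_summaries(npanel), normal_ids)
    readr::write_tsv(pcr, file.path(out_dir, "pcr_calls.tsv"),
                     progress = FALSE)
  }

  de <- NULL
  if (!is.null(cohort$expression)) {
    loy_tumors <- calls$sample_id[calls$arm == "chrY" & calls$flagged &
                                    calls$direction == "loss" &
                                    calls$tissue == "tumor"]
    expr_ids <- setdiff(names(cohort$expression), c("gene_id", "chrom"))
    if (length(intersect(expr_ids, loy_tumors)) >= 2) {
      de <- de_by_loy(cohort$expression, loy_tumors, fdr = fdr)
      readr::write_tsv(de, file.path(out_dir, "de_by_loy.tsv"),
                       progress = FALSE)
      log_line(sum(de$significant), " differentially expressed gene(s) at ",
               "FDR < ", fdr)
    }
  }

  blood <- cohort$samples[cohort$samples$tissue == "normal" &
                            cohort$samples$sex == "male", ]
  age_fit <- NULL
  blood_calls <- calls[calls$sample_id %in% blood$sample_id &
                         calls$arm == "chrY", ]
  loy_flag <- blood_calls$flagged[match(blood$sample_id,
                                        blood_calls$sample_id)] &
    blood_calls$direction[match(blood$sample_id,
                                blood_calls$sample_id)] == "loss"
  if ("age" %in% names(blood) && length(unique(loy_flag)) == 2) {
    age_fit <- loy_age_logistic(loy_flag, blood$age)
    readr::write_tsv(age_fit, file.path(out_dir, "loy_age.tsv"),
                     progress = FALSE)
  }

  manifest <- list(
    package = "armloy",
    version = as.character(packageVersion("armloy")),
    seed = seed,
    thresholds = list(k = k, alpha = alpha, min_fraction = min_fraction,
                      fdr = fdr),
    nulls = nulls
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  yaml::write_yaml(list(n_male = config$n_male, n_female = config$n_female,
                        mean_reads = config$mean_reads,
                        bias_sdlog = config$bias_sdlog, seed = seed),
                   file.path(out_dir, "config.yaml"))

  invisible(list(samples = cohort$samples, truth = cohort$truth,
                 armcov = armcov, calls = calls, frequency = freq,
                 pcr = pcr, de = de, age = age_fit, nulls = nulls))
}
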