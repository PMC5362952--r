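# Genome model: bin grid, arm units and sex-aware coverage baselines.
#
# Arm units are the test units of the caller: "1p", "1q", ..., "Xp", "Xq",
# and "chrY" (chromosome Y is a single whole-chromosome unit because its
# short arm is too small and repeat-rich to test separately).

#' Default miniature genome configuration
#'
#' A human-like karyotype (22 autosomes, X and Y) with chromosome lengths
#' and centromere positions scaled down from GRCh38/GRCh37 arm proportions
#' so that a full synthetic cohort runs in seconds while every arm keeps
#' enough 5 kbp bins for a stable median (roughly 50--1000 bins per arm).
#' Chromosome Y is kept at 5 Mbp (1000 bins) so the whole-chromosome Y unit
#' can supply the full default stable-bin capacity (`k = 1000`) of the
#' coverage pipeline.
#'
#' @param scale Integer divisor applied to the human chromosome lengths and
#'   centromere positions (default 50).
#' @param chr_y_length Length of the Y chromosome in bp (default 5e6,
#'   i.e. 1000 bins of 5 kbp).
#' @return A tibble with columns `chrom`, `length`, `centromere`
#'   (`NA` for chrY, which is one unit).
#' @export
#' @examples
#' default_genome_config()
default_genome_config <- function(scale = 50, chr_y_length = 5e6) {
  # GRCh37 chromosome lengths and (approximate) centromere midpoints, Mbp
  len_mb <- c(249.25, 243.20, 198.02, 191.15, 180.92, 171.12, 159.14,
              146.36, 141.21, 135.53, 135.01, 133.85, 115.17, 107.35,
              102.53, 90.35, 81.20, 78.08, 59.13, 63.03, 48.13, 51.30,
              155.27)
  cen_mb <- c(125.0, 93.3, 91.0, 50.4, 48.4, 61.0, 59.9, 45.6, 49.0,
              40.2, 53.7, 35.8, 17.9, 17.6, 19.0, 36.6, 24.0, 17.2,
              26.5, 27.5, 13.2, 14.7, 60.6)
  chroms <- c(paste0("chr", 1:22), "chrX")
  tibble::tibble(
    chrom = c(chroms, "chrY"),
    length = c(round(len_mb * 1e6 / scale / 1000) * 1000, chr_y_length),
    centromere = c(round(cen_mb * 1e6 / scale / 1000) * 1000, NA_real_)
  )
}

#' Build a genome model with its bin grid and arm baselines
#'
#' Tiles every chromosome with fixed-size, 0-based half-open bins (a trailing
#' partial bin is dropped), assigns each bin to exactly one arm unit, and
#' records the expected normalized-coverage baseline of each arm by sex:
#' 1.0 for autosomes in both sexes, 1.0/0.5 for X in females/males, 0.5 for
#' Y in males and absent in females.
#'
#' @param config Tibble with columns `chrom`, `length`, `centromere`
#'   (see [default_genome_config()]). `centromere` must be `NA` for chrY.
#' @param bin_size Bin width in bp (default 5000).
#' @return An object of class `genome_model`: a list with `bins` (tibble
#'   `chrom`, `start`, `end`, `arm`), `arms` (tibble `arm`, `chrom`,
#'   `baseline_male`, `baseline_female`), `bin_size` and `config`.
#' @export
#' @examples
#' g <- build_genome(default_genome_config())
#' g$arms
build_genome <- function(config = default_genome_config(), bin_size = 5000) {
  stopifnot(is.data.frame(config),
            all(c("chrom", "length", "centromere") %in% names(config)))
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0) {
    abort("`bin_size` must be a single positive number.")
  }
  if (any(config$length < 2 * bin_size)) {
    abort("every chromosome must be at least 2 bins long.")
  }
  bad_cen <- !is.na(config$centromere) &
    (config$centromere <= 0 | config$centromere >= config$length)
  if (any(bad_cen)) {
    abort(paste0("centromere outside chromosome for: ",
                 paste(config$chrom[bad_cen], collapse = ", ")))
  }
  if (anyDuplicated(config$chrom)) abort("duplicated chromosome names.")

  bins <- purrr::pmap_dfr(config, function(chrom, length, centromere) {
    n <- floor(length / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    end <- start + bin_size
    if (chrom == "chrY") {
      arm <- rep("chrY", n)
    } else {
      stub <- sub("^chr", "", chrom)
      # a bin straddling the centromere belongs to p iff it ends at/before it
      arm <- paste0(stub, ifelse(end <= centromere, "p", "q"))
    }
    tibble::tibble(chrom = chrom, start = start, end = end, arm = arm)
  })

  arms <- bins |>
    dplyr::distinct(.data$arm, .data$chrom) |>
    dplyr::mutate(
      baseline_male = dplyr::case_when(
        .data$chrom == "chrY" ~ 0.5,
        .data$chrom == "chrX" ~ 0.5,
        TRUE ~ 1.0
      ),
      baseline_female = dplyr::case_when(
        .data$chrom == "chrY" ~ NA_real_,
        TRUE ~ 1.0
      )
    )

  structure(
    list(bins = bins, arms = arms, bin_size = bin_size,
         config = tibble::as_tibble(config)),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x$config), " chromosomes, ",
      nrow(x$arms), " arm units, ", nrow(x$bins), " bins of ",
      x$bin_size, " bp\n", sep = "")
  invisible(x)
}

#' Expected normalized-coverage baseline of arms by sex
#'
#' @param genome A `genome_model`.
#' @param arm Character vector of arm units.
#' @param sex Character vector (`"male"`/`"female"`), recycled against `arm`.
#' @return Numeric vector of baselines; `NA` where the arm does not exist in
#'   that sex (chrY in females).
#' @export
arm_baseline <- function(genome, arm, sex) {
  stopifnot(inherits(genome, "genome_model"))
  n <- max(length(arm), length(sex))
  arm <- rep_len(arm, n)
  sex <- rep_len(sex, n)
  if (!all(sex %in% c("male", "female"))) {
    abort("`sex` must be \"male\" or \"female\".")
  }
  i <- match(arm, genome$arms$arm)
  if (anyNA(i)) {
    abort(paste0("unknown arm unit(s): ",
                 paste(unique(arm[is.na(i)]), collapse = ", ")))
  }
  ifelse(sex == "male",
         genome$arms$baseline_male[i],
         genome$arms$baseline_female[i])
}

#' Arm units of the autosomes
#' @param genome A `genome_model`.
#' @return Character vector of autosomal arm units.
#' @export
autosomal_arms <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  genome$arms$arm[!genome$arms$chrom %in% c("chrX", "chrY")]
}

# internal: sample columns of a bin table (everything beyond coordinates)
bin_sample_cols <- function(tbl) {
  setdiff(names(tbl), c("chrom", "start", "end", "arm"))
}

# internal: check that a bin table matches the genome grid
check_bin_grid <- function(tbl, genome, what = "counts") {
  gb <- genome$bins
  if (nrow(tbl) != nrow(gb) ||
      !identical(tbl$chrom, gb$chrom) || !identical(as.numeric(tbl$start),
                                                    as.numeric(gb$start))) {
    key_g <- paste(gb$chrom, gb$start)
    key_t <- paste(tbl$chrom, tbl$start)
    miss <- setdiff(key_g, key_t)
    extra <- setdiff(key_t, key_g)
    off <- c(miss, extra)[1]
    abort(paste0(what, " do not match the genome bin grid; first offending bin: ",
                 off %||% "(row order)"))
  }
  invisible(TRUE)
}
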