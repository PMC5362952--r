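# Shared fixtures: a small genome for fast unit tests, and a one-call
# WGS pipeline runner used by the caller and acceptance tests.

tiny_genome <- function() {
  build_genome(tibble::tibble(
    chrom = c("chr1", "chr2", "chrX", "chrY"),
    length = c(1500000, 1200000, 1000000, 500000),
    centromere = c(700000, 500000, 400000, NA)
  ))
}

# a single-arm genome (chrY only) for hand-constructed bin examples
one_arm_genome <- function(n_bins = 5) {
  build_genome(tibble::tibble(chrom = "chrY",
                              length = n_bins * 5000,
                              centromere = NA_real_))
}

run_wgs <- function(samples, truth, genome = build_genome(), seed,
                    k = 1000, ...) {
  counts <- simulate_bin_counts(truth, samples, genome, seed = seed)
  norm <- normalize_coverage(counts, genome)
  sel <- suppressWarnings(select_stable_bins(norm, samples, genome, k = k))
  ac <- arm_coverage(norm, sel, samples, genome)
  calls <- suppressWarnings(call_aneuploidy(ac, samples, genome, ...))
  list(counts = counts, norm = norm, sel = sel, armcov = ac, calls = calls)
}

no_events <- function() {
  tibble::tibble(sample_id = character(), unit = character(),
                 arm = character(), kind = character(), fraction = numeric())
}
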