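test_that("plant_events gives exact carrier counts and is deterministic", {
  g <- tiny_genome()
  samples <- make_sample_sheet(52, 0)
  ev <- tibble::tibble(unit = "chrY", kind = "loss", tissue = "tumor",
                       n = 19L, f_min = 0.2, f_max = 0.75)
  truth <- plant_events(samples, ev, g, seed = 42)
  expect_equal(dplyr::n_distinct(truth$sample_id), 19)
  expect_true(all(truth$arm == "chrY"))
  expect_true(all(truth$fraction >= 0.2 & truth$fraction <= 0.75))
  # byte-identical regeneration under the same seed
  expect_identical(truth, plant_events(samples, ev, g, seed = 42))
  expect_false(identical(truth, plant_events(samples, ev, g, seed = 43)))
})

test_that("planted fractions respect their range and whole-X expands to both arms", {
  g <- tiny_genome()
  samples <- make_sample_sheet(0, 41)
  ev <- tibble::tibble(unit = "chrX", kind = "loss", tissue = "tumor",
                       n = 7L, f_min = 0.2, f_max = 0.7)
  truth <- plant_events(samples, ev, g, seed = 4)
  expect_equal(dplyr::n_distinct(truth$sample_id), 7)
  expect_true(all(truth$fraction >= 0.2 & truth$fraction <= 0.7))
  # one shared fraction across the two X arms of each carrier
  per <- dplyr::summarise(dplyr::group_by(truth, sample_id),
                          arms = dplyr::n_distinct(arm),
                          nf = dplyr::n_distinct(fraction))
  expect_true(all(per$arms == 2))
  expect_true(all(per$nf == 1))
})

test_that("karyotype validity is enforced when planting", {
  g <- tiny_genome()
  males <- make_sample_sheet(5, 0)
  females <- make_sample_sheet(0, 5)
  # LOY cannot be planted in an all-female cohort
  expect_error(plant_events(females,
                            tibble::tibble(unit = "chrY", kind = "loss",
                                           tissue = "tumor", n = 1L,
                                           f_min = 0.3, f_max = 0.5),
                            g, seed = 1),
               "eligible")
  # LOX cannot be planted in male tumors
  expect_error(plant_events(males,
                            tibble::tibble(unit = "chrX", kind = "loss",
                                           tissue = "tumor", n = 1L,
                                           f_min = 0.3, f_max = 0.5),
                            g, seed = 1),
               "eligible")
})

test_that("bin counts follow the dosage model in expectation", {
  # 3p loss at f = 0.5 in a female: expected normalized coverage 0.75,
  # checked against the Monte-Carlo mean over ten thousand bins
  g <- build_genome(tibble::tibble(
    chrom = c("chr3", "chr4"),
    length = c(90e6, 100e6),
    centromere = c(50e6, 50e6)
  ))
  samples <- make_sample_sheet(0, 1, tissues = "tumor")
  truth <- tibble::tibble(sample_id = samples$sample_id, unit = "3p",
                          arm = "3p", kind = "loss", fraction = 0.5)
  counts <- simulate_bin_counts(truth, samples, g, seed = 9)
  a <- counts[[samples$sample_id]][counts$arm == "3p"]
  b <- counts[[samples$sample_id]][counts$chrom == "chr4"]
  expect_gt(length(a), 9999)
  # dosage ratio lost/intact = 0.75, free of the integer normalizer
  r <- mean(a) / mean(b)
  se_r <- r * sqrt(var(a) / (mean(a)^2 * length(a)) +
                     var(b) / (mean(b)^2 * length(b)))
  expect_lt(abs(r - 0.75), 3 * se_r)

  # intact male Y sits at half the autosomal coverage
  samples2 <- make_sample_sheet(1, 0, tissues = "normal")
  counts2 <- simulate_bin_counts(no_events(), samples2, build_genome(),
                                 seed = 10)
  norm2 <- normalize_coverage(counts2, build_genome())
  y <- norm2[[samples2$sample_id]][norm2$arm == "chrY"]
  expect_lt(abs(mean(y) - 0.5), 3 * sd(y) / sqrt(length(y)))
})

test_that("bin-count generation is deterministic and respects lambda > 0", {
  g <- tiny_genome()
  samples <- make_sample_sheet(2, 1)
  c1 <- simulate_bin_counts(no_events(), samples, g, seed = 3)
  c2 <- simulate_bin_counts(no_events(), samples, g, seed = 3)
  expect_identical(c1, c2)
  expect_error(simulate_bin_counts(no_events(), samples, g, mean_reads = 0,
                                   seed = 1),
               "positive")
  # female chrY bins carry no reads
  fem <- samples$sample_id[samples$sex == "female"][1]
  expect_true(all(c1[[fem]][c1$arm == "chrY"] == 0))
})

test_that("expression scales Y genes by 1 - f and leaves the rest alone", {
  samples <- make_sample_sheet(20, 0, tissues = "tumor")
  # null case: no LOY, Y-gene group means agree between arbitrary halves
  e0 <- simulate_expression(no_events(), samples, seed = 2,
                            n_background = 50)
  m <- as.matrix(e0[e0$chrom == "chrY", -(1:2)])
  g1 <- rowMeans(log2(m[, 1:10] + 1))
  g2 <- rowMeans(log2(m[, 11:20] + 1))
  expect_lt(max(abs(g1 - g2)), 0.5)

  # complete loss: Y genes at the noise floor
  truth <- tibble::tibble(sample_id = samples$sample_id[1], unit = "chrY",
                          arm = "chrY", kind = "loss", fraction = 1)
  e1 <- simulate_expression(truth, samples, seed = 2, n_background = 10)
  lost <- e1[[samples$sample_id[1]]][e1$chrom == "chrY"]
  expect_true(all(lost < 0.5))

  # planted inverse relation recovered by least squares within 2 s.e.
  truth2 <- plant_events(samples,
                         tibble::tibble(unit = "chrY", kind = "loss",
                                        tissue = "tumor", n = 12L,
                                        f_min = 0.1, f_max = 0.9),
                         build_genome(), seed = 6)
  e2 <- simulate_expression(truth2, samples, seed = 6, n_background = 10,
                            noise_sd = 0.1)
  fr <- setNames(rep(0, nrow(samples)), samples$sample_id)
  tr <- dplyr::distinct(truth2, sample_id, fraction)
  fr[tr$sample_id] <- tr$fraction
  reg <- expr_fraction_regression(e2, fr, genes = "KDM5D")
  expect_lt(reg$slope, 0)
  # mean RPKM = base * (1 - f), so slope = -base = -intercept
  expect_lt(abs(reg$slope + reg$intercept), 2 * reg$se)
})

test_that("probe panel is proportional to Y dosage with a female floor", {
  samples <- make_sample_sheet(6, 1)
  truth <- tibble::tibble(sample_id = "P001_tumor", unit = "chrY",
                          arm = "chrY", kind = "loss", fraction = 0.5)
  panel <- simulate_probe_panel(truth, samples, seed = 8)
  expect_equal(nrow(panel), 20 * nrow(samples))
  nids <- samples$sample_id[samples$tissue == "normal" &
                              samples$sex == "male"]
  np <- normalize_probe_panel(panel, nids)
  s <- probe_summaries(np)
  # intact male samples center on 1, the f = 0.5 tumor on 0.5
  intact <- s$amplification[s$sample_id %in%
                              setdiff(samples$sample_id[samples$sex == "male"],
                                      "P001_tumor")]
  expect_true(all(abs(intact - 1) < 0.15))
  expect_lt(abs(s$amplification[s$sample_id == "P001_tumor"] - 0.5), 0.1)
  # female control below detection on every probe
  fem <- samples$sample_id[samples$sex == "female"]
  expect_true(all(panel$value[panel$sample_id == fem] < 0.05))
  expect_error(simulate_probe_panel(truth, samples, seed = 1, n_probes = 0),
               "n_probes")
})

test_that("ages shift for blood mosaic-LOY carriers and truth round-trips", {
  g <- tiny_genome()
  samples <- make_sample_sheet(40, 0)
  ev <- tibble::tibble(unit = "chrY", kind = "loss", tissue = "normal",
                       n = 12L, f_min = 0.2, f_max = 0.6)
  truth <- plant_events(samples, ev, g, seed = 21)
  aged <- assign_ages(samples, truth, seed = 21)
  carrier_pat <- unique(aged$patient_id[aged$sample_id %in% truth$sample_id])
  a_car <- aged$age[aged$patient_id %in% carrier_pat & aged$tissue == "normal"]
  a_non <- aged$age[!aged$patient_id %in% carrier_pat & aged$tissue == "normal"]
  expect_gt(mean(a_car), mean(a_non))
  # truth TSV round-trip preserves every planted (sample, arm, fraction)
  p <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(truth, p)
  back <- readr::read_tsv(p, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(truth))
})
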