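# Synthetic-cohort generator: sample sheets, planted arm-level events at
# known cell fractions, Poisson bin counts with shared per-bin bias,
# Y-gene expression scaled by (1 - LOY fraction), and PCR probe panels
# proportional to Y dosage. Everything is deterministic given a seed, so
# every downstream stage can be tested against planted truth.

# run code under a given seed without clobbering the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build a tumor/normal sample sheet
#'
#' One patient per subject, one sample per requested tissue. Sample ids are
#' `<patient>_<tissue>`.
#'
#' @param n_male,n_female Numbers of male and female patients.
#' @param tissues Tissues per patient (default tumor and matched normal).
#' @return Tibble with columns `sample_id`, `patient_id`, `tissue`, `sex`.
#' @export
#' @examples
#' make_sample_sheet(2, 1)
make_sample_sheet <- function(n_male = 52, n_female = 41,
                              tissues = c("tumor", "normal")) {
  stopifnot(n_male >= 0, n_female >= 0, n_male + n_female > 0,
            length(tissues) >= 1)
  patients <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n_male + n_female)),
    sex = rep(c("male", "female"), c(n_male, n_female))
  )
  tidyr::expand_grid(patients, tissue = tissues) |>
    dplyr::mutate(sample_id = paste(.data$patient_id, .data$tissue, sep = "_")) |>
    dplyr::select("sample_id", "patient_id", "tissue", "sex")
}

# expand an event unit ("3p", "chrX", "chr7", "chrY") into arm units
expand_unit <- function(unit, genome) {
  if (unit %in% genome$arms$arm) return(unit)
  if (unit %in% genome$arms$chrom) {
    return(genome$arms$arm[genome$arms$chrom == unit])
  }
  abort(paste0("unknown event unit: ", unit))
}

#' Plant arm-level copy-number events into a cohort
#'
#' Assigns each requested event to an exact number of randomly chosen
#' eligible samples (exact counts, not binomial draws) and draws a cell
#' fraction per carrier, either uniformly from `[f_min, f_max]` or from an
#' explicit `fractions` vector. Whole-chromosome units (e.g. `"chrX"`) are
#' expanded to their arms with one shared fraction per carrier. Karyotype
#' validity is enforced: chromosome-Y events require male samples, and loss
#' of X is restricted to females (males have a single X whose loss is not
#' modelled here).
#'
#' @param samples Sample sheet from [make_sample_sheet()].
#' @param events Tibble with columns `unit`, `kind` (`"loss"`/`"gain"`),
#'   `tissue`, and either `n` with `f_min`,`f_max`, or a list-column
#'   `fractions` of explicit per-carrier fractions.
#' @param genome A `genome_model`.
#' @param seed Integer seed; fully determines the output.
#' @return Truth tibble: `sample_id`, `unit`, `arm`, `kind`, `fraction`.
#' @export
plant_events <- function(samples, events, genome, seed) {
  stopifnot(is.data.frame(samples), is.data.frame(events),
            inherits(genome, "genome_model"))
  if (!"fractions" %in% names(events)) events$fractions <- list(NULL)
  if (!"f_min" %in% names(events)) events$f_min <- NA_real_
  if (!"f_max" %in% names(events)) events$f_max <- NA_real_
  if (!"n" %in% names(events)) events$n <- NA_integer_

  with_local_seed(seed, {
    truth <- list()
    taken <- character(0) # "sample|arm" keys already carrying an event
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      arms <- expand_unit(ev$unit, genome)
      chroms <- unique(genome$arms$chrom[genome$arms$arm %in% arms])
      need_sex <- NULL
      if ("chrY" %in% chroms) need_sex <- "male"
      if ("chrX" %in% chroms && ev$kind == "loss") {
        if (!is.null(need_sex)) abort("event spans X and Y units.")
        need_sex <- "female"
      }
      pool <- samples[samples$tissue == ev$tissue, ]
      if (!is.null(need_sex)) pool <- pool[pool$sex == need_sex, ]
      keys <- outer(pool$sample_id, arms, paste, sep = "|")
      pool <- pool[rowSums(matrix(keys %in% taken, nrow = nrow(pool))) == 0, ]
      fr <- ev$fractions[[1]]
      n <- if (!is.null(fr)) length(fr) else ev$n
      if (is.na(n) || n < 0) abort("event needs `n` or explicit `fractions`.")
      if (n > nrow(pool)) {
        abort(paste0("event ", ev$unit, "/", ev$tissue, ": requested ", n,
                     " carriers but only ", nrow(pool), " eligible samples ",
                     "(karyotype and tissue constraints)."))
      }
      carriers <- sort(sample(pool$sample_id, n))
      if (is.null(fr)) {
        if (is.na(ev$f_min) || is.na(ev$f_max) || ev$f_min <= 0 ||
            ev$f_max > 1 || ev$f_min > ev$f_max) {
          abort("fraction range must satisfy 0 < f_min <= f_max <= 1.")
        }
        fr <- runif(n, ev$f_min, ev$f_max)
      } else if (any(fr <= 0 | fr > 1)) {
        abort("explicit fractions must lie in (0, 1].")
      }
      truth[[i]] <- tidyr::expand_grid(
        tibble::tibble(sample_id = carriers, fraction = fr),
        arm = arms
      ) |>
        dplyr::mutate(unit = ev$unit, kind = ev$kind) |>
        dplyr::select("sample_id", "unit", "arm", "kind", "fraction")
      taken <- c(taken, paste(rep(carriers, each = length(arms)),
                              arms, sep = "|"))
    }
    dplyr::bind_rows(truth)
  })
}

#' Assign patient ages, older for blood mosaic-LOY carriers
#'
#' Ages are drawn once per patient (shared by tumor and normal samples):
#' normal(58.8, 8) years for non-carriers and normal(68.9, 8) for patients
#' whose blood (normal tissue) carries a planted chrY loss, reproducing the
#' age shift expected for mosaic LOY.
#'
#' @param samples Sample sheet.
#' @param truth Truth tibble from [plant_events()].
#' @param seed Integer seed.
#' @param mean_age,mean_age_loy,sd_age Age model parameters in years.
#' @return `samples` with an added integer `age` column.
#' @export
assign_ages <- function(samples, truth, seed,
                        mean_age = 58.8, mean_age_loy = 68.9, sd_age = 8) {
  blood_loy <- truth$sample_id[truth$arm == "chrY" & truth$kind == "loss"]
  carrier_pat <- unique(samples$patient_id[
    samples$sample_id %in% blood_loy & samples$tissue == "normal"])
  pats <- unique(samples$patient_id)
  with_local_seed(seed, {
    mu <- ifelse(pats %in% carrier_pat, mean_age_loy, mean_age)
    age <- round(rnorm(length(pats), mu, sd_age))
    dplyr::left_join(samples, tibble::tibble(patient_id = pats, age = age),
                     by = "patient_id")
  })
}

# per-cell copy change: single-copy units (baseline 0.5) carry 1 copy,
# two-copy units (baseline 1.0) carry 2
dosage_factor <- function(baseline, kind, fraction) {
  copies <- ifelse(baseline == 0.5, 1, 2)
  delta <- fraction / copies
  ifelse(kind == "loss", 1 - delta, 1 + delta)
}

# bins x samples expected-dosage matrix (normalized-coverage scale)
dosage_matrix <- function(truth, samples, genome) {
  arm_idx <- match(genome$bins$arm, genome$arms$arm)
  base_m <- genome$arms$baseline_male[arm_idx]
  base_f <- genome$arms$baseline_female[arm_idx]
  base_f[is.na(base_f)] <- 0 # chrY absent in females
  d <- vapply(seq_len(nrow(samples)), function(j) {
    s <- samples[j, ]
    base <- if (s$sex == "male") base_m else base_f
    ev <- truth[truth$sample_id == s$sample_id, ]
    if (nrow(ev)) {
      for (k in seq_len(nrow(ev))) {
        sel <- genome$bins$arm == ev$arm[k]
        base[sel] <- base[sel] *
          dosage_factor(base[sel], ev$kind[k], ev$fraction[k])
      }
    }
    base
  }, numeric(nrow(genome$bins)))
  colnames(d) <- samples$sample_id
  d
}

#' Simulate binned read counts for a cohort
#'
#' Counts for sample s in bin b are Poisson with mean
#' `mean_reads * bias_b * dosage(s, arm(b))`, where the per-bin bias is a
#' lognormal multiplier shared across all samples (a static mappability-like
#' bias) and the dosage is the sex baseline scaled by the planted events:
#' loss of the only copy gives `baseline * (1 - f)`, loss of one of two
#' copies `baseline * (1 - f/2)`, gain of one copy `baseline * (1 + f/copies)`.
#'
#' @param truth Truth tibble from [plant_events()].
#' @param samples Sample sheet.
#' @param genome A `genome_model`.
#' @param mean_reads Mean reads per diploid bin (Poisson lambda, default 30).
#' @param bias_sdlog Lognormal sd (log scale) of the shared per-bin bias.
#' @param seed Integer seed.
#' @return Tibble `chrom`, `start`, `end`, `arm` plus one integer column per
#'   sample.
#' @export
simulate_bin_counts <- function(truth, samples, genome, mean_reads = 30,
                                bias_sdlog = 0.1, seed = 1) {
  stopifnot(inherits(genome, "genome_model"))
  if (mean_reads <= 0) abort("`mean_reads` must be positive.")
  nb <- nrow(genome$bins)
  with_local_seed(seed, {
    # mean-one bias so the expected normalized coverage equals the dosage
    bias <- rlnorm(nb, meanlog = -bias_sdlog^2 / 2, sdlog = bias_sdlog)
    d <- dosage_matrix(truth, samples, genome)
    mu <- d * (mean_reads * bias) # bias recycles down columns
    counts <- matrix(rpois(length(mu), mu), nrow = nb,
                     dimnames = list(NULL, colnames(d)))
    dplyr::bind_cols(genome$bins, tibble::as_tibble(counts))
  })
}

# the 11 Y-linked genes expressed in normal kidney that go down under LOY
y_gene_names <- function() {
  c("RPS4Y1", "ZFY", "USP9Y", "DDX3Y", "UTY", "TMSB4Y",
    "NLGN4Y", "KDM5D", "EIF1AY", "RPS4Y2", "PRKY")
}

#' Simulate an RPKM expression matrix with LOY-scaled Y genes
#'
#' Y-linked genes in male samples have mean RPKM `base * (1 - f)` where `f`
#' is the sample's planted chrY-loss fraction (0 if none); all other genes
#' are unaffected. Noise is multiplicative lognormal with the given sd on
#' the log2 scale. In female samples (and at complete loss) Y genes sit at
#' a small noise floor.
#'
#' @param truth Truth tibble.
#' @param samples Sample sheet rows to generate expression for.
#' @param seed Integer seed.
#' @param n_background Number of autosomal background genes (default 1000).
#' @param noise_sd Noise sd on the log2 scale (default 0.3).
#' @param y_base_meanlog,y_base_sdlog Lognormal parameters of Y-gene base
#'   RPKM (natural-log scale).
#' @param bg_meanlog,bg_sdlog Lognormal parameters of background base RPKM.
#' @param floor_rpkm Noise floor in RPKM for absent transcripts.
#' @return Tibble `gene_id`, `chrom` plus one numeric column per sample.
#' @export
simulate_expression <- function(truth, samples, seed, n_background = 1000,
                                noise_sd = 0.3,
                                y_base_meanlog = log(30), y_base_sdlog = 0.4,
                                bg_meanlog = log(20), bg_sdlog = 1,
                                floor_rpkm = 0.05) {
  y_genes <- y_gene_names()
  with_local_seed(seed, {
    base_y <- rlnorm(length(y_genes), y_base_meanlog, y_base_sdlog)
    base_bg <- rlnorm(n_background, bg_meanlog, bg_sdlog)
    genes <- tibble::tibble(
      gene_id = c(y_genes, sprintf("GENE%04d", seq_len(n_background))),
      chrom = c(rep("chrY", length(y_genes)),
                paste0("chr", rep_len(1:22, n_background))),
      base = c(base_y, base_bg)
    )
    loy <- truth[truth$arm == "chrY" & truth$kind == "loss", ]
    f <- setNames(rep(0, nrow(samples)), samples$sample_id)
    f[loy$sample_id[loy$sample_id %in% names(f)]] <-
      loy$fraction[loy$sample_id %in% names(f)]
    vals <- vapply(seq_len(nrow(samples)), function(j) {
      s <- samples[j, ]
      mu <- genes$base
      isy <- genes$chrom == "chrY"
      if (s$sex == "male") {
        mu[isy] <- pmax(mu[isy] * (1 - f[[s$sample_id]]), floor_rpkm)
      } else {
        mu[isy] <- floor_rpkm
      }
      mu * 2^rnorm(nrow(genes), 0, noise_sd)
    }, numeric(nrow(genes)))
    colnames(vals) <- samples$sample_id
    dplyr::bind_cols(genes[c("gene_id", "chrom")], tibble::as_tibble(vals))
  })
}

#' Simulate a Y-chromosome PCR probe panel
#'
#' Each probe's amplification is proportional to the sample's chromosome-Y
#' dosage (1 - f for planted chrY-loss carriers, ~0 for female controls),
#' times a probe-specific efficiency shared across samples, times lognormal
#' noise. Mirrors a 20-locus Y deletion-detection assay whose control-primer
#' normalization has already been applied upstream.
#'
#' @param truth Truth tibble.
#' @param samples Sample sheet rows to include in the panel (male samples
#'   plus any female assay controls).
#' @param seed Integer seed.
#' @param n_probes Number of Y loci (default 20).
#' @param noise_sdlog Lognormal measurement noise sd (log scale).
#' @param efficiency_sdlog Lognormal spread of per-probe efficiency.
#' @param female_floor Residual amplification for samples without a Y.
#' @return Long tibble `probe_id`, `locus`, `sample_id`, `value`.
#' @export
simulate_probe_panel <- function(truth, samples, seed, n_probes = 20,
                                 noise_sdlog = 0.1, efficiency_sdlog = 0.3,
                                 female_floor = 0.005) {
  if (n_probes < 1) abort("`n_probes` must be at least 1.")
  loci <- c("SRY", "ZFY", "sY84", "sY86", "sY105", "sY121", "sY127",
            "sY134", "sY142", "sY145", "sY147", "sY152", "sY153", "sY157",
            "sY160", "sY254", "sY255", "DYZ1", "RBMY1", "DAZ")
  loci <- rep_len(loci, n_probes)
  loci <- make.unique(loci, sep = ".")
  with_local_seed(seed, {
    eff <- rlnorm(n_probes, 0, efficiency_sdlog)
    loy <- truth[truth$arm == "chrY" & truth$kind == "loss", ]
    f <- setNames(rep(0, nrow(samples)), samples$sample_id)
    f[loy$sample_id[loy$sample_id %in% names(f)]] <-
      loy$fraction[loy$sample_id %in% names(f)]
    dos <- ifelse(samples$sex == "male", 1 - f[samples$sample_id],
                  female_floor)
    vals <- outer(eff, dos) * rlnorm(n_probes * nrow(samples), 0, noise_sdlog)
    tibble::tibble(
      probe_id = rep(sprintf("probe%02d", seq_len(n_probes)), nrow(samples)),
      locus = rep(loci, nrow(samples)),
      sample_id = rep(samples$sample_id, each = n_probes),
      value = as.vector(vals)
    )
  })
}

#' Plant KDM5C-style covariates (mutations and focal deletions)
#'
#' Adds boolean `kdm5c_mut` and `focal_del` columns to the sample sheet,
#' tied to planted X-loss carriers the way the co-occurrence analysis
#' expects: among females, mutations fall inside the X-loss carrier set and
#' focal deletions outside it; among males a few mutations are scattered.
#'
#' @param samples Sample sheet.
#' @param truth Truth tibble.
#' @param seed Integer seed.
#' @param n_mut_female,n_focal_female,n_mut_male Counts of planted flags
#'   (tumor samples).
#' @return `samples` with added logical columns.
#' @export
plant_covariates <- function(samples, truth, seed, n_mut_female = 3,
                             n_focal_female = 2, n_mut_male = 3) {
  lox <- unique(truth$sample_id[truth$kind == "loss" &
                                  truth$unit %in% c("chrX", "Xp", "Xq")])
  ft <- samples$sample_id[samples$sex == "female" & samples$tissue == "tumor"]
  mt <- samples$sample_id[samples$sex == "male" & samples$tissue == "tumor"]
  with_local_seed(seed, {
    lox_t <- intersect(ft, lox)
    mut_f <- sample(lox_t, min(n_mut_female, length(lox_t)))
    nonlox <- setdiff(ft, lox_t)
    focal_f <- sample(nonlox, min(n_focal_female, length(nonlox)))
    mut_m <- sample(mt, min(n_mut_male, length(mt)))
    samples |>
      dplyr::mutate(
        kdm5c_mut = .data$sample_id %in% c(mut_f, mut_m),
        focal_del = .data$sample_id %in% focal_f
      )
  })
}

#' Default cohort configuration matching the study design
#'
#' 52 male and 41 female tumor/normal pairs; somatic chrY loss in 19 male
#' tumors at cell fractions 0.2--0.75; mosaic chrY loss in 5 male blood
#' samples at fractions 0.15--0.55; whole-X loss in 7 female tumors at
#' 0.2--0.7; 3p loss in 85 tumors at 0.3--0.9. Poisson bin counts with mean
#' 30 reads per 5 kbp bin and a shared lognormal per-bin bias (sd 0.1).
#'
#' @param ... Named overrides merged into the default list.
#' @return A named list accepted by [simulate_cohort()].
#' @export
cohort_config <- function(...) {
  overrides <- list(...)
  cfg <- list(
    n_male = 52,
    n_female = 41,
    mean_reads = 30,
    bias_sdlog = 0.1,
    events = tibble::tibble(
      unit = c("chrY", "chrY", "chrX", "3p"),
      kind = "loss",
      tissue = c("tumor", "normal", "tumor", "tumor"),
      n = c(19L, 5L, 7L, 85L),
      f_min = c(0.2, NA, 0.2, 0.3),
      f_max = c(0.75, NA, 0.7, 0.9),
      fractions = list(NULL, c(0.15, 0.25, 0.35, 0.45, 0.55), NULL, NULL)
    ),
    expression = list(enable = TRUE, n_background = 1000, noise_sd = 0.3),
    probes = list(enable = TRUE, n_probes = 20)
  )
  # shallow merge: an override replaces the whole element (modifyList would
  # recurse into the events tibble and mangle it)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}

#' Generate a full synthetic cohort
#'
#' Runs the whole generator under one seed: genome, sample sheet, planted
#' events, ages, covariate flags, bin counts, expression for male tumors,
#' and a probe panel for male samples plus one female assay control.
#'
#' @param config List from [cohort_config()].
#' @param seed Integer seed; sub-stages use fixed offsets of it.
#' @return List with elements `genome`, `samples`, `truth`, `counts`,
#'   `expression` (or NULL), `probes` (or NULL), `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  genome <- build_genome()
  samples <- make_sample_sheet(config$n_male, config$n_female)
  truth <- plant_events(samples, config$events, genome, seed = seed)
  samples <- assign_ages(samples, truth, seed = seed + 1)
  has_lox <- any(truth$unit %in% c("chrX", "Xp", "Xq") & truth$kind == "loss")
  if (has_lox && config$n_female > 0) {
    samples <- plant_covariates(samples, truth, seed = seed + 2)
  }
  counts <- simulate_bin_counts(truth, samples, genome,
                                mean_reads = config$mean_reads,
                                bias_sdlog = config$bias_sdlog,
                                seed = seed + 3)
  expression <- NULL
  if (isTRUE(config$expression$enable)) {
    male_tumors <- samples[samples$sex == "male" & samples$tissue == "tumor", ]
    expression <- simulate_expression(
      truth, male_tumors, seed = seed + 4,
      n_background = config$expression$n_background,
      noise_sd = config$expression$noise_sd
    )
  }
  probes <- NULL
  if (isTRUE(config$probes$enable)) {
    males <- samples[samples$sex == "male", ]
    ctrl <- samples[samples$sex == "female" & samples$tissue == "normal", ]
    panel_samples <- dplyr::bind_rows(males, head(ctrl, 1))
    probes <- simulate_probe_panel(truth, panel_samples, seed = seed + 5,
                                   n_probes = config$probes$n_probes)
  }
  list(genome = genome, samples = samples, truth = truth, counts = counts,
       expression = expression, probes = probes, config = config, seed = seed)
}
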