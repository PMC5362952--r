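# armloy

Chromosome-arm aneuploidy and mosaic loss-of-Y calling from binned
whole-genome sequencing coverage, with an orthogonal PCR probe-panel
caller, downstream association statistics, and a synthetic-cohort
generator for end-to-end validation.

## Who this is for

Cancer-genomics analysts who have per-sample read counts in fixed genomic
bins (5 kbp BED-style tables) for a cohort of tumor and matched normal
samples and want to know, per sample and chromosome arm: is the arm lost
or gained, how confidently, and in what fraction of cells? The motivating
application is mosaic loss of chromosome Y (LOY) — common in male tumors
and detectable at low cell fractions in blood — alongside loss of X in
females and the classic arm-level events of renal cancer such as 3p loss.

## The method

For sample *s* and bin *b*, counts are modelled as
C<sub>s,b</sub> ~ Poisson(λ · β<sub>b</sub> · d<sub>s,a(b)</sub>) with a
shared per-bin bias β and arm dosage d. The pipeline:

1. normalize each sample by its median autosomal bin count
   (diploid arms → 1.0, single-copy male X/Y → 0.5);
2. per arm, keep the k = 1000 bins with the lowest median divergence from
   the sex-aware baseline across normal samples (a mappability filter that
   needs no annotation);
3. summarise each sample × arm by the median normalized coverage over the
   selected bins (chromosome Y is one whole-chromosome unit);
4. across samples, fit a two-component Gaussian mixture per arm; the
   component representing the unaffected cluster is the null, giving
   two-sided p = 2·Φ(−|cov − μ₀|/σ₀);
5. flag a call when the Bonferroni-adjusted p < 0.01 **and** the
   estimated aberrant cell fraction is ≥ 0.10, with
   f = (0.5 − cov)/0.5 for a single-copy loss (LOY) and
   f = (1 − cov)/0.5, (cov − 1)/0.5 for two-copy losses and gains.

A PCR companion caller applies the same logic to a 20-locus Y probe panel
(normals-based probe normalization, per-sample median amplification,
normals-only mixture null, raw p < 0.01 and f > 0.10). Association helpers
cover Y-gene differential expression by LOY status (pooled t-test on
log2 RPKM, BH FDR < 0.01), expression-versus-fraction regression, LOY–age
logistic regression, Fisher co-occurrence tests and aberration-union
summaries. See `vignettes/armloy-methods.Rmd` for the full model, the
numerical choices and their rationale.

## Worked example

Simulate the default cohort (52 male and 41 female tumor/normal pairs with
LOY, LOX, mosaic blood LOY and 3p losses planted at known cell fractions)
and run the caller:

```r
library(armloy)
library(dplyr)

cohort <- simulate_cohort(cohort_config(), seed = 42)
norm   <- normalize_coverage(cohort$counts, cohort$genome)
sel    <- select_stable_bins(norm, cohort$samples, cohort$genome)
armcov <- arm_coverage(norm, sel, cohort$samples, cohort$genome)
calls  <- call_aneuploidy(armcov, cohort$samples, cohort$genome)

aneuploidy_frequency(calls) |> filter(tissue == "tumor", percent > 10)
#> # A tibble: 5 × 7
#>   arm   tissue sex    direction n_flagged n_tested percent
#>   <chr> <chr>  <chr>  <chr>         <int>    <int>   <dbl>
#> 1 3p    tumor  female loss             38       41    92.7
#> 2 3p    tumor  male   loss             47       52    90.4
#> 3 Xp    tumor  female loss              5       41    12.2
#> 4 Xq    tumor  female loss              7       41    17.1
#> 5 chrY  tumor  male   loss             19       52    36.5
```

All 19 planted somatic-LOY tumors are flagged (36.5% of males), with the
estimated cell fractions tracking the planted dosage:

```r
filter(calls, arm == "chrY", tissue == "tumor", flagged) |>
  select(sample_id, coverage, p_adj, fraction) |> head(4)
#> # A tibble: 4 × 4
#>   sample_id  coverage     p_adj fraction
#>   <chr>         <dbl>     <dbl>    <dbl>
#> 1 P001_tumor    0.2   0            0.6
#> 2 P003_tumor    0.167 0            0.667
#> 3 P005_tumor    0.310 2.55e-226    0.379
#> 4 P007_tumor    0.2   0            0.6
```

A normalized chrY coverage of 0.2 means 60% of cells have lost their Y
((0.5 − 0.2)/0.5). The 5 planted mosaic blood-LOY samples are recovered
too (9.6% of males), and their carriers' planted older ages show up in the
logistic regression:

```r
blood <- filter(cohort$samples, tissue == "normal", sex == "male")
loy   <- filter(calls, arm == "chrY", tissue == "normal", flagged)
loy_age_logistic(blood$sample_id %in% loy$sample_id, blood$age)
#> # A tibble: 1 × 6
#>   beta_age     se      p odds_ratio     n separation
#>      <dbl>  <dbl>  <dbl>      <dbl> <int> <lgl>
#> 1    0.164 0.0704 0.0201       1.18    52 FALSE
```

`run_pipeline(cohort_config(), seed = 42, out_dir = "run1")` performs the
whole loop — simulation, normalization, WGS and PCR calls, differential
expression, age regression — and writes every table plus a manifest of the
thresholds and fitted null parameters. `inst/scripts/armloy.R` exposes the
same steps as shell commands, and `plot_arm_frequency()`,
`plot_y_status()`, `plot_locus_amplification()` and
`plot_expression_vs_fraction()` draw the standard summary figures.

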