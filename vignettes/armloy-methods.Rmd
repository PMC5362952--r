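---
title: "Calling chromosome-arm aneuploidy and mosaic loss of Y from binned coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling chromosome-arm aneuploidy and mosaic loss of Y from binned coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armloy)
library(dplyr)
```

## The problem

Whole-chromosome and arm-level copy-number changes are among the most
common somatic events in tumors, and some — loss of chromosome Y (LOY) in
males, loss of X (LOX) in females, loss of 3p in clear cell renal cell
carcinoma — affect only a fraction of the cells in a sample. armloy detects
such events from whole-genome sequencing read depth summarised in
fixed-size bins, quantifies the fraction of affected cells, reproduces the
same decision with an orthogonal PCR probe panel, and provides the
downstream statistics that connect the calls to gene expression, age and
co-occurring mutations.

## The coverage model

Read counts are taken in fixed bins of `bin_size` bp (default 5 kbp,
0-based half-open, BED convention). For sample $s$ and bin $b$ the model
behind both the caller and the generator is

$$ C_{s,b} \sim \mathrm{Poisson}(\lambda \, \beta_b \, d_{s,a(b)}), $$

where $\lambda$ is the mean reads per diploid-equivalent bin, $\beta_b$ a
bin-specific bias shared by all samples (mappability and similar static
effects), and $d_{s,a}$ the dosage of arm $a$: the sex baseline (1.0 for
autosomes; X 1.0 in females, 0.5 in males; Y 0.5 in males) scaled by any
aberration. A one-copy change in a fraction $f$ of cells moves the dosage
by $f/c$ of the baseline, where $c$ is the copy number of the unit
($c = 1$ for male X/Y, $c = 2$ otherwise), so

$$ d = b_a \left(1 \pm f/c\right). $$

Inverting this is the cell-fraction estimator used on every call:
for a single-copy unit a loss gives $f = (0.5 - \mathrm{cov})/0.5$, for a
two-copy unit $f = (1 - \mathrm{cov})/0.5$ (loss) or
$f = (\mathrm{cov} - 1)/0.5$ (gain), clipped to $[0, 1]$.

## The calling procedure

1. **Normalization.** Each sample's bin counts are divided by the sample's
   median autosomal bin count, removing depth differences. Diploid arms
   then sit at 1.0 and a single-copy sex chromosome at 0.5.
2. **Stable bins.** For each bin, the median over normal samples of
   $|\mathrm{cov} - \mathrm{baseline}|$ is computed against the sex-aware
   baseline (chrY bins use male normals only). Per arm the `k` bins with
   the lowest median divergence are kept (default `k = 1000`, clamped to
   the arm size; ties resolved leftmost), which suppresses mappability
   artifacts without any external annotation. Bins with zero coverage in
   at least half the usable normals are excluded first.
3. **Arm medians.** Per sample and arm unit, the median normalized
   coverage over the selected bins. Chromosome Y is one unit; its
   per-sample median is never computed for females.
4. **Mixture null.** Across samples, each arm's medians form a tight
   cluster of unaffected samples plus possible outliers. A two-component
   Gaussian mixture is fitted by EM and the component representing the
   unaffected cluster is the null distribution; two-sided p-values follow
   from its mean and sd.
5. **Decision.** P-values are Bonferroni-corrected over all
   (sample, arm) tests performed and a call is flagged when the adjusted
   p-value is below `alpha = 0.01` *and* the estimated cell fraction is at
   least `min_fraction = 0.10`. The fraction filter is essential: at high
   bin counts tiny coverage wobbles can be nominally significant while
   being biologically meaningless.

### Which samples enter the mixture?

The null is fitted per arm unit across **all** samples jointly — tumors and
normals — stratified by sex for the sex chromosomes (male and female X
baselines differ, and pooling them would manufacture a bimodal
distribution). The alternative of fitting tumors and normals separately
fails for near-ubiquitous events: with 3p lost in ~90% of tumors, the
dominant component of a tumors-only fit *is* the aberrant cluster, and the
method would call the few intact samples instead. Including the matched
normals anchors the heavier component at the baseline. `by_tissue = TRUE`
restores the stratified variant for cohorts where tissues should not share
a null.

### Numerical guards on the EM fit

The EM uses a deterministic 2-means initialization, a log-likelihood
tolerance of `1e-8`, at most 500 iterations, and a component-sd floor of
`1e-4`. Three further guards matter in practice, all motivated by the
lattice structure of medians of integer counts (at $\lambda = 30$ an arm
median can only take values on a $1/60$ grid):

* **Model selection by BIC.** A one-component fit is computed alongside
  and kept when BIC prefers it. Forcing two components onto a cohort with
  no aberrant cluster otherwise splits the single mode, biasing the null
  mean and shrinking its sd.
* **Rounding-aware sd floor.** The sd floor is raised to
  $h/\sqrt{12}$ — the sd of the rounding error implied by the smallest gap
  $h$ between distinct values — so exact ties cannot collapse a component
  into a zero-width spike.
* **Minimum separation and baseline compatibility.** A two-component
  solution whose means are closer than the coverage shift at the minimum
  callable fraction (`min_fraction * 0.5 = 0.05`) cannot represent a
  callable aberrant cluster and is rejected for the single Gaussian; and
  when one component lies within that shift of the known baseline while
  the heavier one does not, the baseline-compatible component is the null.
  Without this, the fit can lock onto a spike at one lattice point and
  treat neighbouring lattice points — ordinary sampling noise — as the
  "aberrant" cluster.

With fewer than 8 values, or constant input, the fit falls back to a
single Gaussian with a warning; downstream p-values are then conservative.

### Multiplicity

The Bonferroni factor defaults to the number of (sample, arm) tests
actually performed in the cohort (≈ 47 arm units × samples). The exact
denominator is configurable (`bonferroni_m`); with the fraction filter in
place the calls are insensitive to reasonable alternatives, because a
flagged call requires a coverage shift of at least 0.05, many times the
null sd of a well-covered arm.

## The PCR probe caller

The orthogonal assay measures amplification of 20 Y-chromosome loci.
Probes are normalized by their median across designated normal samples,
each sample is summarised by its median normalized amplification
(1.0 for an intact Y), and the mixture null is fitted **on the normal
samples only** — the assay's reference set. A sample is flagged when its
raw p-value is below 0.01 and the estimated fraction
$f = 1 - \mathrm{amplification}$ exceeds 0.10 (strictly, matching the
assay's decision rule; the WGS caller uses a non-strict threshold).
Per-locus tumor/normal ratios within patients provide the locus-level
verification view.

## The synthetic cohort generator

No public, machine-readable cohort accompanies the study design this
package targets, so the generator is a first-class module: it plants
events with known cell fractions and every downstream stage is validated
against that truth.

* **Genome**: a human-like karyotype at 1/50 scale with the original
  5 kbp bins, giving roughly 50–1000 bins per arm; chromosome Y is kept at
  5 Mbp (1000 bins) so the whole-chromosome unit can supply the full
  `k = 1000` stable-bin capacity. Keeping the real bin size makes the
  normalization and selection code scale-free.
* **Depth**: `mean_reads = 30` per bin by default. The source study does
  not state its depth; 30 is deliberately conservative — it produces the
  coarsest arm-median lattice the caller should be expected to tolerate.
* **Bias**: static per-bin lognormal with `sdlog = 0.1`, mean exactly 1 so
  expected normalized coverage equals the dosage. No GC model.
* **Events**: exact planted counts (not binomial draws); fractions uniform
  in a stated range or given explicitly; whole-chromosome units share one
  fraction across arms; karyotype validity enforced (no LOY in females, no
  LOX in males). Default cohort: 52 male + 41 female tumor/normal pairs
  with somatic LOY in 19 male tumors at $f \in [0.2, 0.75]$, mosaic blood
  LOY in 5 males at $f \in \{0.15, \dots, 0.55\}$, LOX in 7 female tumors
  at $f \in [0.2, 0.7]$, and 3p loss in 85 tumors at $f \in [0.3, 0.9]$.
* **Expression**: 11 expressed Y-linked genes (RPS4Y1, ZFY, USP9Y, DDX3Y,
  UTY, TMSB4Y, NLGN4Y, KDM5D, EIF1AY, RPS4Y2, PRKY) whose mean RPKM scales
  by $(1-f)$ in LOY carriers, a configurable number of unaffected
  autosomal background genes, and multiplicative lognormal noise
  (default sd 0.3 on the log2 scale).
* **Probes**: amplification proportional to Y dosage times a probe
  efficiency shared across samples, lognormal noise, and a near-zero
  female floor.
* **Covariates**: patient ages at 58.8 ± 8 years, shifted to 68.9 for
  blood mosaic-LOY carriers; mutation and focal-deletion flags placed to
  exercise the co-occurrence statistics.

What the generator does **not** emulate: GC-content waves, replication
timing, batch effects between sequencing runs, subclonal structure beyond
a single event fraction, focal CNVs, read-level artifacts, and
copy-neutral LOH. Green tests therefore demonstrate correctness of the
inference given the stated noise model, not robustness to every artifact
of real WGS data; on real cohorts the stable-bin filter carries more of
the burden, and `k`, `alpha` and `min_fraction` may need adjustment.

```{r quick-example}
cohort <- simulate_cohort(
  cohort_config(n_male = 12, n_female = 0,
                events = tibble::tibble(unit = "chrY", kind = "loss",
                                        tissue = "tumor", n = 4L,
                                        f_min = 0.3, f_max = 0.7,
                                        fractions = list(NULL)),
                expression = list(enable = FALSE),
                probes = list(enable = FALSE)),
  seed = 1
)
norm <- normalize_coverage(cohort$counts, cohort$genome)
sel <- select_stable_bins(norm, cohort$samples, cohort$genome)
armcov <- arm_coverage(norm, sel, cohort$samples, cohort$genome)
calls <- call_aneuploidy(armcov, cohort$samples, cohort$genome)
filter(calls, arm == "chrY", flagged)
```

## Association statistics

* **Differential expression** between LOY and non-LOY tumors uses a
  pooled-variance Student's t-test on `log2(RPKM + 1)` (the pseudocount
  handles zeros; Welch is available via `var_equal = FALSE`), BH
  correction, and an FDR threshold of 0.01. Genes are pre-filtered to mean
  RPKM above 1; genes with zero variance in both groups get p = 1.
* **Expression vs fraction**: ordinary least squares of RPKM on the
  estimated fraction of cells with LOY, gene by gene; downregulation in
  proportion to dosage appears as slope ≈ −intercept.
* **LOY vs age**: maximum-likelihood logistic regression with a Wald
  two-sided p; complete separation is reported, not silently trusted.
* **Co-occurrence**: two-sided Fisher's exact test (probability-mass
  rule); a zero margin returns p = 1 by convention.
* **Aberration union**: the share of samples per sex carrying any of a
  set of boolean aberration flags, rounded to integer percent.

## Problem sizes and determinism

The default cohorts (up to 93 tumor/normal pairs × ~13,000 bins) run the
full simulate–normalize–call loop in a few seconds on one CPU; the
package's own validation suite regenerates every cohort it tests from
seeds at run time. All randomness flows through explicit seeds, each
generator stage restores the caller's RNG state, and identical
configuration plus seed yields byte-identical outputs.

## Known limitations

* Sub-arm (focal) events are out of scope; the arm median dilutes them.
* The fraction estimator assumes a single one-copy event per arm;
  multi-copy losses or mixed subclones bias $\hat f$ toward an effective
  average.
* At depth 30 the arm-median lattice limits resolution to roughly
  $f \approx 0.05$–0.1 on well-covered arms; the `min_fraction` threshold
  sits deliberately above it.
* The mixture null assumes most samples are unaffected per unit (after
  pooling tissues); an aberration present in nearly all samples *and* all
  normals would be absorbed into the null.
* Tumor purity is not modelled separately: the estimated fraction refers
  to cells in the sequenced material, not to cancer cells.
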