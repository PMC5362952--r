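Package: armloy
Title: Chromosome-Arm Aneuploidy and Mosaic Loss of Chromosome Y Calling
    from Binned Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects chromosome-arm aneuploidy and loss of chromosome Y (LOY)
    from whole-genome sequencing read depth summarised in fixed-size bins.
    Per-sample coverage is normalised by the autosomal median, stable bins
    are selected against sex-aware baselines in normal samples, per-arm
    median coverage is tested against a Gaussian mixture null with
    Bonferroni correction, and the affected cell fraction is estimated from
    the missing or excess coverage. Also implements a PCR probe-panel LOY
    caller, downstream association statistics (Y-gene differential
    expression, expression versus cell-fraction regression, age logistic
    regression, mutation co-occurrence tests), and a synthetic-cohort
    generator with planted events at known cell fractions for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
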