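# Downstream association statistics: Y-gene differential expression by LOY
# status, expression versus cell-fraction regression, LOY-age logistic
# regression, mutation co-occurrence, and the aberration-union summary.

expr_matrix <- function(expr) {
  ids <- setdiff(names(expr), c("gene_id", "chrom"))
  m <- as.matrix(expr[ids])
  rownames(m) <- expr$gene_id
  m
}

#' Differential expression between LOY and non-LOY samples
#'
#' Gene-wise two-sample Student's t-test (pooled variance by default) on
#' log2-transformed expression, with Benjamini-Hochberg correction across
#' the tested genes. RPKM input is transformed as `log2(RPKM + pseudocount)`
#' after an expression filter (mean RPKM above `min_mean`); log2-scale input
#' is used as is and unfiltered. Genes with zero variance in both groups
#' get `p = 1`.
#'
#' @param expr Expression tibble: `gene_id`, `chrom`, one column per sample.
#' @param loy_samples Sample ids of the LOY group; remaining sample columns
#'   form the comparison group.
#' @param scale `"rpkm"` (default) or `"log2"`.
#' @param pseudocount Added before the log2 transform of RPKM (default 1).
#' @param min_mean Expression filter on mean RPKM (default 1; RPKM scale
#'   only).
#' @param var_equal Pooled-variance Student's t (default `TRUE`); `FALSE`
#'   gives Welch.
#' @param fdr Significance threshold on the BH-adjusted p (default 0.01).
#' @return Tibble `gene_id`, `chrom`, `mean_loy`, `mean_other` (log2 scale),
#'   `t`, `df`, `p`, `fdr`, `significant`.
#' @export
de_by_loy <- function(expr, loy_samples, scale = c("rpkm", "log2"),
                      pseudocount = 1, min_mean = 1, var_equal = TRUE,
                      fdr = 0.01) {
  scale <- match.arg(scale)
  m <- expr_matrix(expr)
  loy <- intersect(colnames(m), loy_samples)
  other <- setdiff(colnames(m), loy)
  if (length(loy) < 2 || length(other) < 2) {
    abort("need at least 2 samples per group.")
  }
  keep <- rep(TRUE, nrow(m))
  if (scale == "rpkm") {
    if (any(m < 0)) abort("RPKM values must be non-negative.")
    keep <- rowMeans(m) > min_mean
    m <- log2(m + pseudocount)
  }
  x <- m[keep, loy, drop = FALSE]
  y <- m[keep, other, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, var); v2 <- apply(y, 1, var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    dfree <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    dfree <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / se
  p <- 2 * pt(-abs(tt), dfree)
  zerovar <- v1 == 0 & v2 == 0
  tt[zerovar] <- 0
  p[zerovar] <- 1
  q <- p.adjust(p, method = "BH")
  sig <- q < fdr
  tibble::tibble(
    gene_id = rownames(m)[keep],
    chrom = expr$chrom[match(rownames(m)[keep], expr$gene_id)],
    mean_loy = unname(m1), mean_other = unname(m2),
    t = unname(tt), df = unname(dfree), p = unname(p), fdr = unname(q),
    significant = unname(sig)
  ) |>
    dplyr::arrange(.data$p)
}

#' Regress gene expression on the LOY cell fraction
#'
#' Ordinary least squares of per-sample expression (RPKM scale, as
#' measured) on the estimated proportion of cells with LOY, gene by gene,
#' with the two-sided p-value for the slope. Downregulation in proportion
#' to the affected fraction shows up as a negative slope.
#'
#' @param expr Expression tibble (`gene_id`, `chrom`, sample columns).
#' @param fractions Named numeric vector of LOY cell fractions, names are
#'   sample ids; samples absent from it are dropped.
#' @param genes Optional subset of gene ids (default: all).
#' @return Tibble `gene_id`, `slope`, `se`, `intercept`, `r`, `p`, `n`.
#' @export
expr_fraction_regression <- function(expr, fractions, genes = NULL) {
  m <- expr_matrix(expr)
  if (!is.null(genes)) m <- m[rownames(m) %in% genes, , drop = FALSE]
  ids <- intersect(colnames(m), names(fractions))
  if (length(ids) < 3) abort("need at least 3 samples with a fraction.")
  f <- fractions[ids]
  if (any(f < 0 | f > 1)) abort("fractions must lie in [0, 1].")
  if (var(f) == 0) abort("zero variance in fractions; regression undefined.")
  purrr::map_dfr(rownames(m), function(g) {
    y <- m[g, ids]
    fit <- lm(y ~ f)
    s <- summary(fit)
    tibble::tibble(
      gene_id = g,
      slope = coef(fit)[["f"]],
      se = s$coefficients["f", "Std. Error"],
      intercept = coef(fit)[["(Intercept)"]],
      r = sign(coef(fit)[["f"]]) * sqrt(s$r.squared),
      p = s$coefficients["f", "Pr(>|t|)"],
      n = length(ids)
    )
  })
}

#' Logistic regression of LOY status on age
#'
#' Maximum-likelihood logistic fit of the (blood mosaic) LOY flag on age in
#' years, with the Wald two-sided p-value and the per-year odds ratio.
#' Complete or quasi-complete separation is reported with a warning and
#' flagged in the result rather than trusted as a finite estimate.
#'
#' @param loy Logical vector of LOY flags (both classes must occur).
#' @param age Numeric ages in years, same length.
#' @return One-row tibble `beta_age`, `se`, `p`, `odds_ratio`, `n`,
#'   `separation`.
#' @export
loy_age_logistic <- function(loy, age) {
  stopifnot(length(loy) == length(age))
  ok <- complete.cases(loy, age)
  loy <- as.logical(loy[ok]); age <- age[ok]
  if (length(unique(loy)) < 2) {
    abort("both LOY classes must be present for the logistic regression.")
  }
  w <- withCallingHandlers(
    {
      fit <- glm(loy ~ age, family = binomial())
      FALSE
    },
    warning = function(cond) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(cond))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- summary(fit)
  eps <- 1e-8
  separation <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) ||
    !fit$converged
  if (separation) warn("possible separation in the LOY~age logistic fit.")
  tibble::tibble(
    beta_age = coef(fit)[["age"]],
    se = s$coefficients["age", "Std. Error"],
    p = s$coefficients["age", "Pr(>|z|)"],
    odds_ratio = exp(coef(fit)[["age"]]),
    n = length(loy),
    separation = separation
  )
}

#' Fisher's exact test of event co-occurrence
#'
#' Two-sided Fisher's exact test (probability-mass rule) on a 2x2 table,
#' either given directly or built from two logical vectors. A table with a
#' zero margin returns `p = 1` by convention.
#'
#' @param a Either a 2x2 integer matrix, or a logical vector (feature A).
#' @param b Logical vector (feature B) when `a` is a vector.
#' @return One-row tibble `p`, `odds_ratio`, and the four cell counts
#'   `n11`, `n10`, `n01`, `n00`.
#' @export
#' @examples
#' # 3 mutated samples all within the 7 X-loss carriers among 41 patients
#' loy_fisher_test(matrix(c(3, 4, 0, 34), nrow = 2))
loy_fisher_test <- function(a, b = NULL) {
  if (is.matrix(a)) {
    tab <- a
    if (!all(dim(tab) == c(2, 2))) abort("table must be 2x2.")
  } else {
    stopifnot(!is.null(b), length(a) == length(b))
    tab <- table(factor(as.logical(a), levels = c(TRUE, FALSE)),
                 factor(as.logical(b), levels = c(TRUE, FALSE)))
    tab <- matrix(as.integer(tab), 2, 2)
  }
  if (any(tab < 0) || sum(tab) == 0) abort("invalid contingency table.")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    p <- 1
    orat <- NA_real_
  } else {
    ft <- fisher.test(tab)
    p <- ft$p.value
    orat <- unname(ft$estimate)
  }
  tibble::tibble(p = p, odds_ratio = orat,
                 n11 = tab[1, 1], n10 = tab[1, 2],
                 n01 = tab[2, 1], n00 = tab[2, 2])
}

#' Union of genomic aberrations per sex group
#'
#' Counts samples affected by any of the given boolean aberration columns
#' (e.g. whole-chromosome loss, focal deletion, point mutation) and reports
#' the percentage of each sex group, rounded to the nearest integer.
#'
#' @param data Tibble with a `sex` column and logical aberration columns.
#' @param cols Character vector of the aberration column names.
#' @return Tibble `sex`, `n_affected`, `n_total`, `percent`.
#' @export
#' @examples
#' df <- tibble::tibble(sex = rep("female", 4),
#'                      lox = c(TRUE, TRUE, FALSE, FALSE),
#'                      mut = c(TRUE, FALSE, FALSE, FALSE))
#' aberration_union(df, c("lox", "mut"))
aberration_union <- function(data, cols) {
  stopifnot("sex" %in% names(data), all(cols %in% names(data)))
  if (!all(data$sex %in% c("male", "female"))) {
    abort("unknown sex label; expected \"male\"/\"female\".")
  }
  flags <- as.matrix(data[cols])
  if (!is.logical(flags)) abort("aberration columns must be logical.")
  data |>
    dplyr::mutate(.any = rowSums(flags, na.rm = TRUE) > 0) |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(
      n_affected = sum(.data$.any),
      n_total = dplyr::n(),
      percent = round(100 * sum(.data$.any) / dplyr::n()),
      .groups = "drop"
    )
}
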