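log2_expr <- function(values, chrom = "chr1") {
  # values: named list group -> matrix genes x samples (log2 scale)
  m <- do.call(cbind, values)
  tibble::tibble(gene_id = paste0("g", seq_len(nrow(m))), chrom = chrom) |>
    dplyr::bind_cols(tibble::as_tibble(m))
}

test_that("the pooled t-test matches hand and t.test computations", {
  e <- log2_expr(list(matrix(c(1, 2, 3), 1,
                             dimnames = list(NULL, c("a1", "a2", "a3"))),
                      matrix(c(3, 4, 5), 1,
                             dimnames = list(NULL, c("b1", "b2", "b3")))))
  de <- de_by_loy(e, c("a1", "a2", "a3"), scale = "log2")
  expect_equal(de$t, -2.449, tolerance = 1e-3)
  expect_equal(de$df, 4)
  expect_equal(de$p, 0.0705, tolerance = 1e-3)

  # random genes agree with stats::t.test as the independent oracle
  withr::with_seed(10, m <- matrix(rnorm(80), 10, 8,
                                   dimnames = list(NULL, paste0("s", 1:8))))
  e2 <- log2_expr(list(m))
  de2 <- de_by_loy(e2, paste0("s", 1:4), scale = "log2")
  for (i in 1:10) {
    tt <- t.test(m[i, 1:4], m[i, 5:8], var.equal = TRUE)
    j <- which(de2$gene_id == paste0("g", i))
    expect_equal(de2$t[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de2$p[j], tt$p.value, tolerance = 1e-10)
  }
  # swapping group labels negates t and keeps p
  de2b <- de_by_loy(e2, paste0("s", 5:8), scale = "log2")
  ord <- match(de2$gene_id, de2b$gene_id)
  expect_equal(de2$t, -de2b$t[ord])
  expect_equal(de2$p, de2b$p[ord])
})

test_that("identical groups and zero-variance genes are null results", {
  # 2 genes x 4 samples, all constant per gene
  e <- log2_expr(list(matrix(rep(c(2, 5), 4), 2,
                             dimnames = list(NULL, paste0("s", 1:4)))))
  de <- de_by_loy(e, c("s1", "s2"), scale = "log2")
  expect_equal(de$t, c(0, 0))
  expect_equal(de$p, c(1, 1))
  expect_error(de_by_loy(e, character(0), scale = "log2"), "2 samples")
})

test_that("planted Y-gene downregulation is detected and nothing else", {
  g <- build_genome()
  samples <- make_sample_sheet(34, 0, tissues = "tumor")
  truth <- plant_events(samples,
                        tibble::tibble(unit = "chrY", kind = "loss",
                                       tissue = "tumor", n = 13L,
                                       f_min = 0.2, f_max = 0.75),
                        g, seed = 11)
  expr <- simulate_expression(truth, samples, seed = 11,
                              n_background = 1000, noise_sd = 0.3)
  de <- de_by_loy(expr, unique(truth$sample_id))
  sig <- de[de$significant, ]
  expect_true(all(sig$chrom == "chrY"))
  expect_gte(nrow(sig), 10)
  expect_true(all(sig$t < 0)) # downregulated in the LOY group
})

test_that("non-Y genes stay clean across repeated null cohorts", {
  g <- build_genome()
  for (s in 1:5) {
    samples <- make_sample_sheet(20, 0, tissues = "tumor")
    truth <- plant_events(samples,
                          tibble::tibble(unit = "chrY", kind = "loss",
                                         tissue = "tumor", n = 8L,
                                         f_min = 0.3, f_max = 0.7),
                          g, seed = 400 + s)
    expr <- simulate_expression(truth, samples, seed = 400 + s,
                                n_background = 300, noise_sd = 0.3)
    de <- de_by_loy(expr, unique(truth$sample_id))
    expect_equal(sum(de$significant & de$chrom != "chrY"), 0)
  }
})

test_that("BH at FDR 0.01 yields no discoveries under the global null", {
  withr::with_seed(12, m <- matrix(2^rnorm(10000 * 12, 5, 1), 10000, 12,
                                   dimnames = list(NULL, paste0("s", 1:12))))
  e <- tibble::tibble(gene_id = paste0("g", 1:10000), chrom = "chr1") |>
    dplyr::bind_cols(tibble::as_tibble(m))
  de <- de_by_loy(e, paste0("s", 1:6))
  expect_lte(sum(de$significant), 10000 * 0.001)
})

test_that("expression-fraction regression recovers exact lines and rejects flat designs", {
  f <- c(0, 0.2, 0.4, 0.6, 0.8)
  e <- tibble::tibble(gene_id = "g1", chrom = "chrY") |>
    dplyr::bind_cols(tibble::as_tibble(
      matrix(10 - 8 * f, 1, dimnames = list(NULL, paste0("s", 1:5)))))
  # an exact line triggers R's perfect-fit note in summary.lm
  fit <- suppressWarnings(
    expr_fraction_regression(e, setNames(f, paste0("s", 1:5)))
  )
  expect_equal(fit$slope, -8)
  expect_equal(fit$intercept, 10)
  expect_equal(fit$r, -1)
  expect_error(
    expr_fraction_regression(e, setNames(rep(0.3, 5), paste0("s", 1:5))),
    "variance"
  )
})

test_that("the age logistic regression behaves under null and planted effects", {
  # permuted ages give a uniform p: at most ~10% below 0.05
  withr::with_seed(13, {
    flags <- c(rep(TRUE, 8), rep(FALSE, 44))
    hits <- 0
    for (i in 1:200) {
      ages <- sample(round(rnorm(52, 60, 8)))
      fit <- suppressWarnings(loy_age_logistic(flags, ages))
      hits <- hits + (fit$p < 0.05)
    }
    expect_lte(hits / 200, 0.10)
  })
  # planted age shift gives a positive coefficient nearly always
  withr::with_seed(14, {
    pos <- 0
    for (i in 1:100) {
      flags <- c(rep(TRUE, 5), rep(FALSE, 47))
      ages <- round(c(rnorm(5, 68.9, 8), rnorm(47, 58.8, 8)))
      fit <- suppressWarnings(loy_age_logistic(flags, ages))
      pos <- pos + (fit$beta_age > 0)
    }
    expect_gte(pos, 90)
  })
  expect_error(loy_age_logistic(rep(TRUE, 10), rnorm(10)), "classes")
  expect_warning(
    fit <- loy_age_logistic(c(rep(FALSE, 10), rep(TRUE, 10)),
                            c(1:10, 21:30)),
    "separation"
  )
  expect_true(fit$separation)
})

test_that("Fisher's exact test reproduces enumeration and its symmetries", {
  # 3 mutated, all within the 7 X-loss carriers, among 41 patients
  tab <- matrix(c(3, 4, 0, 34), 2)
  res <- loy_fisher_test(tab)
  # independent oracle: hypergeometric enumeration over all tables with
  # the observed margins, probability-mass rule
  probs <- dhyper(0:3, 7, 34, 3)
  oracle <- sum(probs[probs <= dhyper(3, 7, 34, 3) * (1 + 1e-7)])
  expect_equal(res$p, oracle, tolerance = 1e-10)
  expect_equal(res$p, 35 / 10660, tolerance = 1e-10)

  expect_equal(loy_fisher_test(matrix(c(1, 1, 1, 1), 2))$p, 1)
  expect_equal(loy_fisher_test(matrix(c(0, 0, 5, 7), 2, byrow = TRUE))$p, 1)
  # invariant to transposition and to swapping rows and columns
  expect_equal(loy_fisher_test(t(tab))$p, res$p)
  expect_equal(loy_fisher_test(tab[2:1, 2:1])$p, res$p)
  # logical-vector interface builds the same table
  a <- c(rep(TRUE, 3), rep(FALSE, 38))
  b <- c(rep(TRUE, 7), rep(FALSE, 34))
  res2 <- loy_fisher_test(a, b)
  expect_equal(res2$n11, 3)
  expect_equal(res2$p, res$p)
})

test_that("the aberration union counts any-affected samples per sex", {
  df <- tibble::tibble(
    sex = rep("female", 41),
    lox = c(rep(TRUE, 7), rep(FALSE, 34)),
    focal = c(rep(FALSE, 7), TRUE, TRUE, rep(FALSE, 32)),
    mut = c(rep(TRUE, 3), rep(FALSE, 38)) # inside the LOX set
  )
  u <- aberration_union(df, c("lox", "focal", "mut"))
  expect_equal(u$n_affected, 9)
  expect_equal(u$percent, 22)

  expect_equal(aberration_union(dplyr::mutate(df, lox = FALSE, focal = FALSE,
                                              mut = FALSE),
                                c("lox", "focal", "mut"))$n_affected, 0)
  # random table equals the brute-force row-wise OR
  withr::with_seed(15, {
    rnd <- tibble::tibble(sex = sample(c("male", "female"), 60, TRUE),
                          a = sample(c(TRUE, FALSE), 60, TRUE),
                          b = sample(c(TRUE, FALSE), 60, TRUE))
    u2 <- aberration_union(rnd, c("a", "b"))
    brute <- tapply(rnd$a | rnd$b, rnd$sex, sum)
    expect_equal(u2$n_affected, as.numeric(brute[u2$sex]),
                 ignore_attr = TRUE)
  })
  expect_error(aberration_union(tibble::tibble(sex = "other", a = TRUE), "a"),
               "sex")
})
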