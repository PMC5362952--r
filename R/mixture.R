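# Gaussian mixture null for arm-level coverage (and probe amplification).
#
# Across samples, an unaffected arm produces a tight cluster of arm-median
# coverage values around the baseline, while affected samples fall away from
# it in proportion to their aberrant cell fraction. A two-component Gaussian
# mixture is fitted by EM; the heavier ("main") component is the null
# distribution from which per-sample p-values are drawn. A one-component
# fit is computed alongside and the model is chosen by BIC, so that cohorts
# with no aberrant cluster keep an unbiased null instead of an artificial
# split of the single mode.

em_two_gaussian <- function(x, max_iter = 500, tol = 1e-8,
                            sigma_floor = 1e-4) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  if (q[1] == q[2]) q <- range(x)
  km <- suppressWarnings(kmeans(x, centers = matrix(q, ncol = 1)))
  cl <- km$cluster
  mu <- as.numeric(tapply(x, cl, mean))
  s <- as.numeric(tapply(x, cl, sd))
  s[is.na(s)] <- sigma_floor
  s <- pmax(s, sigma_floor)
  w <- as.numeric(table(cl)) / length(x)
  ll_old <- -Inf
  ll <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot <= 0] <- .Machine$double.xmin
    r <- d1 / tot
    sr1 <- sum(r)
    sr2 <- length(x) - sr1
    if (sr1 > 1e-12) {
      mu[1] <- sum(r * x) / sr1
      s[1] <- max(sqrt(sum(r * (x - mu[1])^2) / sr1), sigma_floor)
    }
    if (sr2 > 1e-12) {
      mu[2] <- sum((1 - r) * x) / sr2
      s[2] <- max(sqrt(sum((1 - r) * (x - mu[2])^2) / sr2), sigma_floor)
    }
    w <- c(sr1, sr2) / length(x)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = s, weight = w, loglik = ll, iter = it,
       converged = converged)
}

#' Fit the Gaussian mixture null to cross-sample values
#'
#' Fits a two-component univariate Gaussian mixture by EM (deterministic
#' 2-means initialization, sd floored at `sigma_floor`) together with a
#' single-Gaussian fit, keeps the model with the lower BIC, and designates
#' the component with the larger weight as the null, preferring a
#' baseline-compatible component (see `min_separation`) and breaking exact
#' weight ties towards `baseline`. With fewer than `min_n`
#' finite values, or with constant input, a single-Gaussian fallback is
#' returned with a warning.
#'
#' @param x Numeric values (arm-median coverage or probe summaries across
#'   samples); non-finite entries are dropped.
#' @param baseline Expected null location, used only to break weight ties
#'   (optional).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param sigma_floor Lower bound on component sds (default 1e-4). The
#'   effective floor is raised to half the measurement resolution (the
#'   smallest gap between distinct values) so that exact ties from
#'   discretized coverage cannot collapse a component into a spike.
#' @param min_n Minimum values for a mixture fit (default 8).
#' @param min_separation Smallest distance between component means that can
#'   represent a genuine aberrant cluster (default 0: no constraint). When
#'   the two fitted means are closer than this, the two-component model is
#'   rejected in favour of the single Gaussian, and a component within it
#'   of `baseline` is preferred as the null over a heavier component that
#'   is not. Callers set it to the coverage shift at the minimum callable
#'   cell fraction.
#' @return Object of class `loy_mixture` with fields `mu`, `sigma`,
#'   `weight`, `null` (null-component index), `n`, `loglik`, `bic`,
#'   `k` (components kept), `converged`, `fallback`.
#' @export
#' @examples
#' x <- c(rnorm(95, 1, 0.01), rnorm(5, 0.6, 0.01))
#' fit <- fit_mixture_null(x, baseline = 1)
#' tidy(fit)
fit_mixture_null <- function(x, baseline = NA_real_, max_iter = 500,
                             tol = 1e-8, sigma_floor = 1e-4, min_n = 8,
                             min_separation = 0) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) abort("no finite values to fit.")
  # discretized measurements (bin-count medians at depth lambda sit on a
  # 1/(2*lambda) lattice) produce exact ties; a Gaussian component collapsing
  # onto such a spike is a degenerate fit, so the sd floor is raised to the
  # sd of the implied rounding error (lattice step / sqrt(12))
  ux <- sort(unique(x))
  if (length(ux) > 1) {
    sigma_floor <- max(sigma_floor, min(diff(ux)) / sqrt(12))
  }
  single <- list(mu = mean(x), sigma = max(sd(x), sigma_floor, na.rm = TRUE),
                 weight = 1)
  if (n < min_n || length(ux) == 1) {
    if (n >= min_n) {
      warn("constant input; degenerate single-Gaussian null.")
    } else {
      warn(paste0("only ", n, " values; falling back to a single-Gaussian null."))
    }
    return(new_loy_mixture(mu = single$mu, sigma = single$sigma, weight = 1,
                           null = 1L, n = n, loglik = NA_real_,
                           bic = NA_real_, k = 1L, converged = TRUE,
                           fallback = TRUE))
  }
  ll1 <- sum(dnorm(x, single$mu, single$sigma, log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  fit2 <- em_two_gaussian(x, max_iter = max_iter, tol = tol,
                          sigma_floor = sigma_floor)
  bic2 <- -2 * fit2$loglik + 5 * log(n)
  # components closer than the smallest callable coverage shift cannot be a
  # genuine aberrant cluster (they are lattice lobes or a split of a single
  # mode); keep the single Gaussian so its sd reflects the full null spread
  if (abs(diff(fit2$mu)) < min_separation) bic2 <- Inf
  if (bic2 < bic1) {
    null <- which.max(fit2$weight)
    if (is.finite(baseline)) {
      # the null cluster cannot sit farther from the expected baseline than
      # the smallest callable shift while the other component sits at it:
      # prefer the heaviest baseline-compatible component, and break exact
      # weight ties towards the baseline
      compat <- abs(fit2$mu - baseline) <= min_separation
      if (any(compat) && !compat[null]) {
        null <- which(compat)[which.max(fit2$weight[compat])]
      } else if (fit2$weight[1] == fit2$weight[2]) {
        null <- which.min(abs(fit2$mu - baseline))
      }
    }
    new_loy_mixture(mu = fit2$mu, sigma = fit2$sigma, weight = fit2$weight,
                    null = as.integer(null), n = n, loglik = fit2$loglik,
                    bic = bic2, k = 2L, converged = fit2$converged,
                    fallback = FALSE)
  } else {
    new_loy_mixture(mu = single$mu, sigma = single$sigma, weight = 1,
                    null = 1L, n = n, loglik = ll1, bic = bic1, k = 1L,
                    converged = TRUE, fallback = FALSE)
  }
}

new_loy_mixture <- function(mu, sigma, weight, null, n, loglik, bic, k,
                            converged, fallback) {
  structure(
    list(mu = mu, sigma = sigma, weight = weight, null = null, n = n,
         loglik = loglik, bic = bic, k = k, converged = converged,
         fallback = fallback),
    class = "loy_mixture"
  )
}

#' @export
print.loy_mixture <- function(x, ...) {
  cat("<loy_mixture> ", x$k, " component(s), n = ", x$n,
      if (x$fallback) " [fallback]", "\n", sep = "")
  for (i in seq_along(x$mu)) {
    cat(sprintf("  comp %d%s: mean %.4f, sd %.5f, weight %.3f\n", i,
                if (i == x$null) " (null)" else "", x$mu[i], x$sigma[i],
                x$weight[i]))
  }
  invisible(x)
}

#' @describeIn fit_mixture_null One row per mixture component.
#' @param x,object A `loy_mixture`.
#' @param ... Unused.
#' @export
tidy.loy_mixture <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$mu),
    mean = x$mu,
    sd = x$sigma,
    weight = x$weight,
    null = seq_along(x$mu) == x$null
  )
}

#' @describeIn fit_mixture_null One-row model summary.
#' @export
glance.loy_mixture <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, loglik = x$loglik, bic = x$bic,
                 converged = x$converged, fallback = x$fallback)
}

#' Two-sided p-value against a fitted mixture null
#'
#' `p = 2 * Phi(-|value - mu_null| / sigma_null)`, clipped to `[0, 1]`.
#'
#' @param values Numeric vector.
#' @param fit A `loy_mixture`.
#' @return Numeric p-values.
#' @export
null_pvalue <- function(values, fit) {
  stopifnot(inherits(fit, "loy_mixture"))
  mu <- fit$mu[fit$null]
  s <- fit$sigma[fit$null]
  pmin(1, 2 * pnorm(-abs(values - mu) / s))
}
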