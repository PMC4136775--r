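# Self-contained statistics used across the pipeline.  These are
# implemented from first principles (rather than wrapping stats::ks.test /
# prop.trend.test) because the pipeline contract pins down the exact
# statistic and the asymptotic reference distribution; the test suite
# cross-checks them against independent oracles.

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D`, the supremum over all thresholds of the absolute
#' difference between the two empirical distribution functions (attained
#' at pooled sample points), and an asymptotic two-sided p-value from the
#' Kolmogorov distribution with effective sample size
#' `n = |x||y| / (|x| + |y|)`.
#'
#' @param x,y Numeric samples (each of length >= 1, finite).
#' @return List of class `ks_result` with `D`, `p`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  nx <- length(x); ny <- length(y)
  pts <- sort(unique(c(x, y)))
  ecdf_x <- vapply(pts, function(t) sum(x <= t), 0) / nx
  ecdf_y <- vapply(pts, function(t) sum(y <= t), 0) / ny
  D <- max(abs(ecdf_x - ecdf_y))
  n_eff <- nx * ny / (nx + ny)
  p <- kolmogorov_sf(sqrt(n_eff) * D)
  structure(list(D = D, p = p, n_x = nx, n_y = ny), class = "ks_result")
}

# survival function of the Kolmogorov distribution:
# P(K > lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, p = %.4g (n = %d, %d)\n",
              x$D, x$p, x$n_x, x$n_y))
  invisible(x)
}

#' Cochran-Armitage trend test for a 2x3 case/control dosage table
#'
#' Tests for a linear trend in genotype dosage between cases and controls
#' with weights `w` (default additive, `(0, 1, 2)`).  With column totals
#' `n_i = r_i + s_i`, case total `R` and control total `S`, the statistic is
#' `T = sum_i w_i (r_i S - s_i R)` and `chi2 = T^2 / Var(T)` where
#' `Var(T) = (R S / N) (N sum w_i^2 n_i - (sum w_i n_i)^2)`; the p-value is
#' the upper tail of chi-squared with 1 df.  Degenerate tables (all cases,
#' all controls, or a single occupied dosage column) return `chi2 = 0`,
#' `p = 1`.
#'
#' @param cases Integer vector `(r0, r1, r2)`: fusion carriers by dosage.
#' @param controls Integer vector `(s0, s1, s2)`.
#' @param w Dosage weights.
#' @return List with `chi2`, `p`, `T`, `var_T`.
#' @export
cochran_armitage_trend <- function(cases, controls, w = c(0, 1, 2)) {
  if (length(cases) != length(w) || length(controls) != length(w)) {
    stop("cases/controls must have one count per weight")
  }
  if (any(cases < 0) || any(controls < 0)) stop("negative counts")
  R <- sum(cases); S <- sum(controls); N <- R + S
  if (N < 2) stop("need at least 2 individuals")
  n <- cases + controls
  if (R == 0 || S == 0 || sum(n > 0) < 2) {
    return(list(chi2 = 0, p = 1, T = 0, var_T = 0))
  }
  T_stat <- sum(w * (cases * S - controls * R))
  var_T <- (R * S / N) * (N * sum(w^2 * n) - sum(w * n)^2)
  if (var_T <= 0) return(list(chi2 = 0, p = 1, T = T_stat, var_T = var_T))
  chi2 <- T_stat^2 / var_T
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       T = T_stat, var_T = var_T)
}

#' Bonferroni adjustment
#'
#' @param p Raw p-value(s) in `[0, 1]`.
#' @param m Number of tests in the family (>= 1).
#' @return `min(1, m * p)`, vectorized over `p`.
#' @export
bonferroni_adjust <- function(p, m) {
  if (any(m < 1)) stop("m must be >= 1")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  pmin(1, m * p)
}

#' Carrier odds ratio with 95% confidence interval
#'
#' Odds ratio of the 2x2 table (cases carrier/non-carrier vs controls
#' carrier/non-carrier): `OR = ad / bc`, with a Wald interval on the log
#' scale, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`.  If any cell is zero, the
#' Haldane-Anscombe continuity correction adds 0.5 to all four cells and
#' the result is flagged.
#'
#' @param a Cases carrying >= 1 alternative allele.
#' @param b Cases not carrying.
#' @param c_ Controls carrying.
#' @param d Controls not carrying.
#' @return List of class `or_result`: `or_value`, `ci_low`, `ci_high`,
#'   `corrected`, `table`.
#' @export
carrier_odds_ratio <- function(a, b, c_, d) {
  if (any(c(a, b, c_, d) < 0)) stop("negative cell count")
  if (a + b == 0 || c_ + d == 0) stop("empty case or control row")
  tab <- c(a = a, b = b, c = c_, d = d)
  corrected <- any(tab == 0)
  if (corrected) tab <- tab + 0.5
  or_value <- (tab["a"] * tab["d"]) / (tab["b"] * tab["c"])
  se <- sqrt(sum(1 / tab))
  z <- stats::qnorm(0.975)
  structure(list(or_value = unname(or_value),
                 ci_low = unname(or_value * exp(-z * se)),
                 ci_high = unname(or_value * exp(z * se)),
                 corrected = corrected,
                 table = c(a = a, b = b, c = c_, d = d)),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR = %.3f (95%% CI %.3f-%.3f)%s\n", x$or_value, x$ci_low,
              x$ci_high, if (x$corrected) " [continuity-corrected]" else ""))
  invisible(x)
}

#' Minor allele frequency from dosages
#'
#' @param dosages Integer dosages in `{0, 1, 2}`, `NA` = missing.
#' @return `min(f, 1 - f)` where `f` is the alternative-allele frequency
#'   over non-missing samples.
#' @export
minor_allele_frequency <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("all dosages missing")
  if (any(!d %in% 0:2)) stop("dosages must be 0, 1 or 2")
  f <- sum(d) / (2 * length(d))
  min(f, 1 - f)
}
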