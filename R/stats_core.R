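# Statistical tests and empirical p-value machinery shared by every stage.
#
# The classical tests wrap the stats package; the wrappers fix the edge-case
# conventions used throughout (degenerate inputs return p = 1 rather than
# NaN) and return plain lists so results serialize cleanly.

#' Welch's two-sample t-test
#'
#' @param a,b Numeric vectors (length >= 2, finite).
#' @return List with `t`, `df` (Welch–Satterthwaite), `p` (two-sided).
#'   Both samples constant with equal means gives `t = 0`, `p = 1`;
#'   both constant with different means is an error (undefined variance).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per sample")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    stop("zero variance in both samples with unequal means: t undefined")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the usual "tables at most as probable as the observed"
#' rule (the `stats::fisher.test` convention).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value; any empty margin returns 1 by convention.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("`tab` must be 2x2")
  if (any(tab < 0) || any(tab != floor(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Two-proportion test with Yates' continuity correction
#'
#' @param x1,n1,x2,n2 Successes and totals of the two groups.
#' @return List with `chi2` (1 df, continuity-corrected) and `p` (two-sided).
#'   A pooled proportion of exactly 0 or 1 returns `chi2 = 0`, `p = 1`.
#' @export
two_prop_yates <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) return(list(chi2 = 0, p = 1))
  ht <- suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = TRUE)
  )
  list(chi2 = unname(ht$statistic), p = ht$p.value)
}

#' Two-sample Kolmogorov–Smirnov test
#'
#' @param a,b Numeric vectors (length >= 1).
#' @return List with `D` and asymptotic two-sided `p`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  ht <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(ht$statistic), p = ht$p.value)
}

#' Construct a null distribution record
#'
#' Holds the values of a statistic computed on resampled backgrounds, plus
#' the sampling metadata needed to reproduce them.
#'
#' @param values Numeric vector of resampled statistic values.
#' @param statistic_name Short name of the statistic.
#' @param seed Integer seed that generated the samples.
#' @param constraint Free-text description of the sampling constraint.
#' @return An object of class `null_distribution`.
#' @export
null_distribution <- function(values, statistic_name, seed = NA_integer_,
                              constraint = "uniform sampling") {
  values <- as.numeric(values)
  if (length(values) < 1) stop("a null distribution needs >= 1 value")
  structure(
    list(values = values, statistic_name = statistic_name,
         n_samples = length(values), seed = seed, constraint = constraint),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution>", x$statistic_name, "\n",
      " n_samples:", x$n_samples, " seed:", x$seed, "\n",
      " constraint:", x$constraint, "\n",
      " mean:", signif(mean(x$values), 4),
      " sd:", signif(stats::sd(x$values), 4), "\n")
  invisible(x)
}

#' Empirical p-value against a resampling null
#'
#' Uses the add-one estimator `p = (1 + k) / (1 + n)`, where `k` counts null
#' values as or more extreme than `observed`, so p is never exactly 0. When
#' `k = 0` the result is an upper bound (`is_bound = TRUE`), conventionally
#' reported as "p < 1/n_samples".
#'
#' @param null A `null_distribution` (or bare numeric vector).
#' @param observed Observed statistic.
#' @param tail `"upper"` (as-or-larger counts as extreme) or `"lower"`.
#' @return List with `p`, `is_bound`, and `bound` (`1/n_samples`).
#' @export
empirical_p <- function(null, observed, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  values <- if (inherits(null, "null_distribution")) null$values else as.numeric(null)
  n <- length(values)
  if (n < 1) stop("empty null distribution")
  k <- if (tail == "upper") sum(values >= observed) else sum(values <= observed)
  list(p = (1 + k) / (1 + n), is_bound = (k == 0), bound = 1 / n)
}

#' Format an empirical p-value for reporting
#'
#' Bounded results print as `"< 1e-06"` style bounds (the convention used
#' when no resampled value reaches the observed statistic).
#'
#' @param ep Result of [empirical_p()].
#' @return A single character string.
#' @export
format_empirical_p <- function(ep) {
  if (isTRUE(ep$is_bound)) paste0("< ", format(ep$bound, scientific = TRUE))
  else format(ep$p, digits = 3)
}
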