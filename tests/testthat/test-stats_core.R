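test_that("welch_t matches the closed-form Welch formula", {
  # identical samples: no evidence
  res <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # frozen from the closed form: t = -1.2247, df = 4, p = 0.2879
  res <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.2878641, tolerance = 1e-6)

  # oracle agreement on random inputs
  set.seed(11)
  for (i in 1:50) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), mean = runif(1, -2, 2))
    o <- oracle_welch(a, b)
    r <- welch_t(a, b)
    expect_equal(r$t, o$t, tolerance = 1e-10)
    expect_equal(r$df, o$df, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)
  }

  # large shift with tiny variance is decisive
  expect_lt(welch_t(rnorm(10, 0, 0.01), rnorm(10, 10, 0.01))$p, 1e-6)

  # degenerate cases
  expect_equal(welch_t(c(2, 2, 2), c(2, 2))$p, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("fisher_exact_2x2 agrees with exhaustive enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  # empty margin convention
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 2), 2)), 1)

  # all tables with total <= 20 via random margins
  set.seed(42)
  for (i in 1:300) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2)
    expect_equal(fisher_exact_2x2(tab), oracle_fisher_2x2(tab),
                 tolerance = 1e-9)
  }
  # the fully disjoint-support table
  tab <- matrix(c(0, 5, 5, 0), 2)
  expect_equal(fisher_exact_2x2(tab), oracle_fisher_2x2(tab),
               tolerance = 1e-12)
})

test_that("two_prop_yates matches the hand-computed Yates chi-square", {
  res <- two_prop_yates(10, 100, 10, 100)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)

  o <- oracle_yates_chi2(41, 100, 22, 100)
  r <- two_prop_yates(41, 100, 22, 100)
  expect_equal(r$chi2, o$chi2, tolerance = 1e-10)
  expect_equal(r$p, o$p, tolerance = 1e-10)

  # the continuity correction can only make the test more conservative
  set.seed(7)
  for (i in 1:100) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    if ((x1 + x2) %in% c(0, n1 + n2)) next
    p_yates <- two_prop_yates(x1, n1, x2, n2)$p
    p_plain <- suppressWarnings(
      stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$p.value)
    expect_gte(p_yates, p_plain - 1e-12)
  }

  expect_equal(two_prop_yates(0, 10, 0, 20)$p, 1)
  expect_equal(two_prop_yates(10, 10, 20, 20)$p, 1)
})

test_that("empirical_p implements the add-one estimator with bound flag", {
  # all 999 null values below the observation
  ep <- empirical_p(null_distribution(runif(999), "x"), 2, tail = "upper")
  expect_equal(ep$p, 1 / 1000)
  expect_true(ep$is_bound)

  # observed at the null median of an odd-length null
  vals <- 1:101
  ep <- empirical_p(null_distribution(vals, "x"), 51, tail = "upper")
  expect_equal(ep$p, (1 + 51) / 102)
  expect_false(ep$is_bound)

  # never exactly zero, never above one
  set.seed(3)
  for (i in 1:50) {
    vals <- rnorm(sample(c(1, 5, 100), 1))
    obs <- rnorm(1)
    for (tail in c("upper", "lower")) {
      p <- empirical_p(null_distribution(vals, "x"), obs, tail)$p
      expect_gt(p, 0)
      expect_lte(p, 1)
    }
  }

  # monotone non-increasing in the observation for the upper tail
  vals <- rnorm(200)
  obs <- sort(rnorm(20))
  ps <- vapply(obs, function(o) {
    empirical_p(null_distribution(vals, "x"), o, "upper")$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))

  # reporting convention for bounded p-values
  ep <- empirical_p(null_distribution(runif(1e4), "x"), 2, "upper")
  expect_match(format_empirical_p(ep), "^< 1e-04$")
})

test_that("ks_two_sample equals the brute-force ECDF gap", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:5, 1:5)$p, 1)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)
  set.seed(21)
  for (i in 1:50) {
    a <- rnorm(sample(2:15, 1)); b <- rnorm(sample(2:15, 1))
    expect_equal(ks_two_sample(a, b)$D, oracle_ks_D(a, b), tolerance = 1e-12)
  }
})
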