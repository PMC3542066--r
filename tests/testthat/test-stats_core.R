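test_that("KS statistic matches the brute-force ECDF scan", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$statistic, 0.5)
  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(sample(3:40, 1)); y <- rnorm(sample(3:40, 1), sd = 2)
    expect_equal(ks_two_sample(x, y)$statistic, ks_oracle_d(x, y))
  }
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("KS D is invariant under strictly monotone transforms", {
  set.seed(12)
  x <- rexp(25); y <- rexp(30, rate = 2)
  d0 <- ks_two_sample(x, y)$statistic
  for (f in list(function(z) z^3, log, function(z) 5 * z - 2))
    expect_equal(ks_two_sample(f(x), f(y))$statistic, d0)
})

test_that("one-way ANOVA agrees with the sum-of-squares oracle", {
  expect_equal(anova_oneway(list(c(1, 2, 3), c(3, 2, 1)))$statistic, 0)
  g <- list(c(1, 2), c(2, 3), c(3, 4))
  expect_equal(anova_oneway(g)$statistic, anova_oracle_f(g))
  # also cross-check statistic and p against the classical F test
  set.seed(13)
  for (i in 1:20) {
    g <- replicate(sample(2:5, 1),
                   rnorm(sample(3:12, 1), mean = runif(1)),
                   simplify = FALSE)
    got <- anova_oneway(g)
    ref <- stats::oneway.test(
      values ~ grp,
      data = data.frame(values = unlist(g),
                        grp = rep(seq_along(g), lengths(g))),
      var.equal = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
  }
  deg <- anova_oneway(list(c(0, 0), c(1, 1)))
  expect_true(deg$degenerate)
  expect_identical(deg$statistic, Inf)
  expect_identical(deg$p_value, 0)
  expect_error(anova_oneway(list(c(1, 1), c(1, 1))), "identical")
  expect_error(anova_oneway(list(1, c(1, 2))), "at least two values")
})

test_that("Mann-Whitney U matches exhaustive pair counting", {
  expect_equal(mann_whitney(c(1, 2), c(1, 2))$statistic, 2)  # |x||y|/2
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$statistic, 0)
  expect_equal(mann_whitney(c(1, 3, 5), c(2, 4))$statistic,
               mw_oracle_u(c(1, 3, 5), c(2, 4)))
  set.seed(14)
  for (i in 1:30) {
    x <- sample(1:10, sample(2:12, 1), replace = TRUE)  # with ties
    y <- sample(1:10, sample(2:12, 1), replace = TRUE)
    expect_equal(mann_whitney(x, y)$statistic, mw_oracle_u(x, y))
  }
})

test_that("Fisher's exact test matches the hypergeometric enumeration oracle", {
  r <- fisher_exact(10, 10, 10, 10)
  expect_equal(r$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(r$p_value, 1)
  expect_equal(fisher_exact(0, 10, 10, 10)$odds_ratio, 0)
  ora <- fisher_oracle(12, 5, 7, 15)
  got <- fisher_exact(12, 5, 7, 15)
  expect_equal(got$odds_ratio, ora$odds_ratio, tolerance = 1e-6)
  expect_equal(got$p_value, ora$p_value, tolerance = 1e-9)
  expect_error(fisher_exact(0, 0, 3, 4), "zero margin")
  expect_error(fisher_exact(-1, 2, 3, 4), "nonnegative")
})

test_that("Fisher estimate and p agree with the oracle on a random margin sweep", {
  set.seed(15)
  for (i in 1:150) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c_ <- sample(0:15, 1); d <- sample(0:15, 1)
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
    got <- fisher_exact(a, b, c_, d)
    ora <- fisher_oracle(a, b, c_, d)
    expect_equal(got$p_value, ora$p_value, tolerance = 1e-9)
    if (is.finite(ora$odds_ratio) && ora$odds_ratio > 0)
      expect_equal(got$odds_ratio, ora$odds_ratio, tolerance = 1e-6)
    else
      expect_identical(got$odds_ratio, ora$odds_ratio)
  }
})

test_that("BH adjustment reproduces the step-up formula and its guarantees", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(16)
  for (i in 1:30) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
    expect_true(all(diff(sort(q)[order(order(sort(p)))]) >= -1e-12))
  }
  # all p <= alpha/n implies all q <= alpha
  n <- 12; alpha <- 0.05
  p <- runif(n, 0, alpha / n)
  expect_true(all(bh_fdr(p) <= alpha))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})
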