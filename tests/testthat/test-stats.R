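# Rank statistics against exhaustive oracles.

test_that("spearman association matches the mid-rank oracle", {
  expect_equal(spearman_association(1:6, c(0, 0, 1, 1, 2, 3))$statistic,
               bf_spearman_rho(1:6, c(0, 0, 1, 1, 2, 3)))
  s <- spearman_association(c(1, 2, 3, 4, 5), c(0, 0, 1, 1, 2))
  expect_equal(s$statistic, bf_spearman_rho(c(1, 2, 3, 4, 5), c(0, 0, 1, 1, 2)))
  expect_equal(spearman_association(1:8, rep(0:3, each = 2))$statistic,
               bf_spearman_rho(1:8, rep(0:3, each = 2)))
  expect_equal(spearman_association(4:1, 0:3)$statistic, -1)
  expect_equal(spearman_association(1:4, 0:3)$statistic, 1)
  withr::with_seed(4, {
    for (i in 1:10) {
      x <- rnorm(10)
      g <- sample(0:3, 10, replace = TRUE)
      if (length(unique(g)) < 2) next
      expect_equal(spearman_association(x, g)$statistic, bf_spearman_rho(x, g))
    }
  })
})

test_that("spearman p-value uses the t approximation", {
  withr::with_seed(5, {
    x <- rnorm(12)
    g <- sample(0:3, 12, replace = TRUE)
    s <- spearman_association(x, g)
    rho <- s$statistic
    tt <- rho * sqrt((12 - 2) / (1 - rho^2))
    expect_equal(s$p_value, 2 * pt(-abs(tt), 10))
  })
  # degenerate grades flagged missing, not zero
  s <- spearman_association(1:5, rep(1, 5))
  expect_true(is.na(s$statistic) && is.na(s$p_value))
})

test_that("kruskal-wallis reproduces the hand-ranked H", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE))
  expect_equal(kw$statistic,
               bf_kruskal_h(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))))
  withr::with_seed(6, {
    for (i in 1:10) {
      gs <- split(sample(1:6, 12, replace = TRUE), rep(1:3, each = 4))
      expect_equal(kruskal_wallis(gs)$statistic, bf_kruskal_h(gs))
    }
  })
})

test_that("kruskal-wallis degenerate conventions", {
  kw <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p_value, 1)
  expect_equal(kruskal_wallis(list(c(1, 3, 5), c(1, 3, 5)))$statistic, 0)
  expect_error(kruskal_wallis(list(1:5)), class = "qube_content_error")
})

test_that("lin's concordance matches direct evaluation", {
  expect_equal(lin_ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  x <- c(-2, 0, 2)
  expect_equal(lin_ccc(x, -x), -1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  withr::with_seed(7, {
    for (i in 1:10) {
      x <- rnorm(8)
      y <- rnorm(8)
      expect_equal(lin_ccc(x, y), bf_lin_ccc(x, y))
    }
  })
  expect_true(is.na(lin_ccc(c(1, 1), c(1, 1))))
  # sample-moment variant agrees with the population variant up to the
  # mean-gap weighting
  x <- c(1, 2, 4)
  y <- c(2, 2, 5)
  expect_equal(lin_ccc(x, y, moments = "sample"),
               2 * cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2))
})

test_that("wilcoxon signed-rank matches exact enumeration", {
  x <- c(1, 2, 3, 4, 5, 6)
  w <- wilcoxon_signed_rank(x + 10, x)
  expect_equal(w$p_value, 2 / 64)
  expect_equal(w$p_value, bf_wilcoxon_exact(x + 10, x))
  expect_equal(w$statistic, 21)
  withr::with_seed(8, {
    for (i in 1:10) {
      a <- rnorm(9)
      b <- rnorm(9)
      expect_equal(wilcoxon_signed_rank(a, b)$p_value, bf_wilcoxon_exact(a, b))
    }
    # with ties in |differences|
    a <- c(3, 5, 1, 7, 2, 9)
    b <- a - c(2, 2, -2, 4, 1, -1)
    expect_equal(wilcoxon_signed_rank(a, b)$p_value, bf_wilcoxon_exact(a, b))
  })
})

test_that("wilcoxon degenerate conventions hold", {
  x <- c(1, 2, 3)
  expect_equal(wilcoxon_signed_rank(x, x)$p_value, 1)
  expect_equal(wilcoxon_signed_rank(x, x)$statistic, 0)
  w <- suppressMessages(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 2)))
  expect_equal(w$p_value, 1)  # single non-zero pair
  expect_identical(w$n, 1L)
})

test_that("large-sample wilcoxon agrees with the reference implementation", {
  withr::with_seed(9, {
    a <- rnorm(30)
    b <- rnorm(30, 0.3)
    w <- wilcoxon_signed_rank(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("median and IQR use inclusive linear interpolation", {
  expect_equal(summarize_median_iqr(c(1, 2, 3, 4, 5)),
               c(median = 3, q1 = 2, q3 = 4))
  expect_equal(summarize_median_iqr(rep(4.2, 6)),
               c(median = 4.2, q1 = 4.2, q3 = 4.2))
  expect_equal(summarize_median_iqr(c(1, 2)),
               c(median = 1.5, q1 = 1.25, q3 = 1.75))
  s <- summarize_median_iqr(rnorm(11))
  expect_true(s["q1"] <= s["median"] && s["median"] <= s["q3"])
  expect_error(summarize_median_iqr(numeric(0)), class = "qube_content_error")
})
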