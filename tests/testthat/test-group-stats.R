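toy_cosine_matrix <- function(items, seed = 1) {
  k <- length(items)
  v <- withr::with_seed(seed, matrix(rnorm(k * 3), k, 3))
  rownames(v) <- items
  cosine_matrix(v)
}

test_that("pair_vector enumerates the upper triangle in lexicographic order", {
  cm <- toy_cosine_matrix(c("B", "A", "C"))
  pv <- pair_vector(cm, c("B", "A", "C"))
  expect_equal(pv$item1, c("A", "A", "B"))
  expect_equal(pv$item2, c("B", "C", "C"))
  expect_equal(pv$cosine, c(cm["A", "B"], cm["A", "C"], cm["B", "C"]))
  # 6 items -> 15 pairs
  cm6 <- toy_cosine_matrix(LETTERS[1:6], seed = 2)
  expect_equal(nrow(pair_vector(cm6, LETTERS[1:6])), 15)
  expect_error(pair_vector(cm, c("A", "B", "Z")), "Z")
  expect_error(pair_vector(cm, c("A", "B")), "at least 3")
})

test_that("pair ordering is identical across matrices over the same items", {
  a <- pair_vector(toy_cosine_matrix(LETTERS[1:5], seed = 3), LETTERS[1:5])
  b <- pair_vector(toy_cosine_matrix(LETTERS[1:5], seed = 4), LETTERS[1:5])
  expect_equal(a[c("item1", "item2")], b[c("item1", "item2")])
})

test_that("correlate_pair_vectors is the product-moment correlation", {
  a <- pair_vector(toy_cosine_matrix(LETTERS[1:6], seed = 5), LETTERS[1:6])
  expect_equal(correlate_pair_vectors(a, a), 1)
  neg <- a
  neg$cosine <- -a$cosine
  expect_equal(correlate_pair_vectors(a, neg), -1)
  b <- pair_vector(toy_cosine_matrix(LETTERS[1:6], seed = 6), LETTERS[1:6])
  # brute-force covariance formula
  x <- a$cosine; y <- b$cosine
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate_pair_vectors(a, b), brute, tolerance = 1e-12)
  # misaligned pair lists are an error
  swapped <- b[c(2, 1, 3:15), ]
  expect_error(correlate_pair_vectors(a, swapped), "alignment")
  const <- a
  const$cosine <- rep(0.5, nrow(const))
  expect_error(correlate_pair_vectors(a, const), "constant")
})

test_that("meng_test is zero at equal correlations and antisymmetric", {
  m0 <- meng_test(0.5, 0.5, 0.3, 20, alternative = "two.sided")
  expect_equal(unname(m0$statistic), 0)
  expect_equal(m0$p.value, 1)
  m1 <- meng_test(0.2, 0.6, 0.4, 30, alternative = "two.sided")
  m2 <- meng_test(0.6, 0.2, 0.4, 30, alternative = "two.sided")
  expect_equal(unname(m1$statistic), -unname(m2$statistic))
  expect_equal(m1$p.value, m2$p.value)
  # sign convention: r1 < r2 with alternative "less" gives p < 0.5
  expect_lt(meng_test(0.2, 0.6, 0.4, 30, alternative = "less")$p.value, 0.5)
})

test_that("meng_test validates its domain", {
  expect_error(meng_test(0.2, 0.4, 0.3, 3), "sample-size")
  expect_error(meng_test(1.0, 0.4, 0.3, 10), "domain")
  expect_error(meng_test(0.2, 0.4, 1.2, 10), "domain")
  # equal correlations of 1 (identical inputs) are the allowed degenerate case
  expect_equal(unname(meng_test(1, 1, 1, 15)$statistic), 0)
})

test_that("meng_test approaches the independent-groups comparison for small r", {
  # with r_overlap = 0 and negligible squared correlations, h -> 1 and the
  # statistic reduces to the classic (z1 - z2) / sqrt(2 / (n - 3))
  for (r1 in c(-0.05, 0.02)) {
    for (r2 in c(-0.03, 0.04)) {
      m <- meng_test(r1, r2, 0, 100, alternative = "two.sided")
      classic <- (atanh(r1) - atanh(r2)) / sqrt(2 / 97)
      expect_equal(unname(m$statistic), classic, tolerance = 1e-2)
    }
  }
})

test_that("meng_test tidy/glance expose the full result", {
  td <- tidy(meng_test(0.41, 0.75, 0.68, 15, alternative = "less"))
  expect_equal(td$r1, 0.41)
  expect_equal(td$n, 15L)
  expect_true(td$conf.low < td$fisher_diff && td$fisher_diff < td$conf.high)
  expect_equal(td$alternative, "less")
})

test_that("summary-statistic t tests agree with raw-data computations", {
  x <- withr::with_seed(8, rnorm(40, 10, 2))
  y <- withr::with_seed(9, rnorm(25, 11, 3))
  pooled <- pooled_t_test(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(pooled$df, unname(ref$parameter))
  expect_equal(pooled$p.value, ref$p.value, tolerance = 1e-10)
  welch <- welch_t_test(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  refw <- stats::t.test(x, y)
  expect_equal(welch$statistic, unname(refw$statistic), tolerance = 1e-10)
  expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-10)
})

test_that("t tests handle degenerate summaries", {
  expect_equal(pooled_t_test(5, 0, 10, 5, 0, 10)$statistic, 0)
  expect_error(pooled_t_test(5, 0, 10, 6, 0, 10), "undefined-value")
  expect_equal(pooled_t_test(5, 1, 10, 5, 1, 10)$statistic, 0)
  # equal variances and sizes: Welch df reduces to 2n - 2
  w <- welch_t_test(4, 1.5, 12, 6, 1.5, 12)
  expect_equal(w$df, 22)
  expect_error(welch_t_test(4, 0, 12, 6, 1.5, 12), "positive")
})

test_that("levene_test is an ANOVA on absolute mean deviations", {
  # identical spread pattern -> F = 0
  expect_equal(levene_test(c(1, 2, 3), c(11, 12, 13))$statistic, 0)
  # inflating one sample's scale raises F above 0
  expect_gt(levene_test(c(1, 2, 3, 4), 3 * c(1, 2, 3, 4))$statistic, 0)
  x <- withr::with_seed(10, rnorm(30, 0, 1))
  y <- withr::with_seed(11, rnorm(20, 0, 4))
  got <- levene_test(x, y)
  # brute-force one-way ANOVA on the deviations
  adev <- c(abs(x - mean(x)), abs(y - mean(y)))
  g <- rep(1:2, c(30, 20))
  gm <- tapply(adev, g, mean)
  ssb <- sum(tabulate(g) * (gm - mean(adev))^2)
  ssw <- sum((adev - gm[g])^2)
  brute_f <- (ssb / 1) / (ssw / 48)
  expect_equal(got$statistic, brute_f, tolerance = 1e-10)
  expect_error(levene_test(c(1, 1), c(2, 2)), "constant")
})

test_that("levene_test matches car::leveneTest with mean centring", {
  skip_if_not_installed("car")
  x <- withr::with_seed(12, rnorm(25, 0, 1))
  y <- withr::with_seed(13, rnorm(35, 0, 2.5))
  got <- levene_test(x, y)
  ref <- car::leveneTest(c(x, y), factor(rep(1:2, c(25, 35))), center = mean)
  expect_equal(got$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(got$p.value, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("chi_square_2x2 is the uncorrected Pearson statistic", {
  # proportional table has no association
  expect_equal(chi_square_2x2(10, 10, 20, 20)$statistic, 0)
  # brute force sum (O - E)^2 / E
  o <- c(5, 10, 15, 20)
  n <- sum(o)
  e <- outer(c(15, 35), c(20, 30)) / n
  brute <- sum((matrix(o, 2, byrow = TRUE) - e)^2 / e)
  expect_equal(chi_square_2x2(5, 10, 15, 20)$statistic, brute, tolerance = 1e-12)
  expect_error(chi_square_2x2(0, 0, 3, 4), "degenerate")
  expect_error(chi_square_2x2(-1, 2, 3, 4), "non-negative")
})
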