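seeded_binary_matrix <- function(nr, nc, seed, p = 0.45) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(nr * nc, 1, p), nr, nc)
  })
  # no all-zero rows (items with zero occurrence are excluded upstream)
  m[rowSums(m) == 0, 1] <- 1
  rownames(m) <- sprintf("I%02d", seq_len(nr))
  m
}

test_that("decompose_ism reproduces closed-form spectra", {
  expect_equal(decompose_ism(diag(2))$d, c(1, 1))
  m1 <- outer(c(1, 1, 0, 1), c(1, 0, 1))     # rank one
  d <- decompose_ism(m1)$d
  expect_equal(sum(d > 1e-10 * d[1]), 1)
  expect_error(decompose_ism(matrix(1, 1, 3)), "dimension")
})

test_that("singular values match an independent Gram-matrix eigen-decomposition", {
  m <- seeded_binary_matrix(12, 28, seed = 101)
  sp <- decompose_ism(m)
  ev <- eigen(m %*% t(m), symmetric = TRUE)$values
  expect_equal(sp$d, sqrt(pmax(ev, 0)), tolerance = 1e-8)
  # full factors reconstruct the matrix
  rec <- sp$u %*% diag(sp$d) %*% t(sp$v)
  expect_lt(max(abs(rec - m)), 1e-8)
})

test_that("select_dimensions implements the cumulative singular-value rule", {
  expect_equal(select_dimensions(c(1, 0, 0), 0.7), 1L)
  expect_equal(select_dimensions(c(5, 3, 1, 1), 0.70), 2L)
  expect_equal(select_dimensions(c(5, 3, 1, 1), 0.5), 1L)
  expect_equal(select_dimensions(c(5, 3, 1, 1), 1.0), 4L)
  expect_equal(select_dimensions(c(1, 1, 0, 0), 1.0), 2L)  # nonzero count
  # variance-based option squares the spectrum
  expect_equal(select_dimensions(c(5, 3, 1, 1), 0.70, method = "variance"), 2L)
  expect_equal(select_dimensions(c(5, 3, 1, 1), 0.69, method = "variance"), 1L)
  expect_error(select_dimensions(c(0, 0), 0.7), "zero")
})

test_that("select_dimensions is non-decreasing in the threshold", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      d <- sort(rexp(8), decreasing = TRUE)
      ks <- vapply(seq(0.05, 1, by = 0.05),
                   function(th) select_dimensions(d, th), integer(1))
      expect_false(is.unsorted(ks))
    }
  })
})

test_that("full-rank item vectors preserve raw row cosines", {
  m <- seeded_binary_matrix(10, 24, seed = 202)
  sp <- decompose_ism(m)
  r <- sum(sp$d > 1e-10 * sp$d[1])
  raw_cos <- cosine_matrix(m + 0)  # cosines between original rows
  red_cos <- cosine_matrix(item_vectors(sp, k = r))
  expect_equal(red_cos, raw_cos, tolerance = 1e-8)
})

test_that("one-dimensional vectors are pairwise collinear", {
  m <- seeded_binary_matrix(8, 15, seed = 303)
  cm <- cosine_matrix(item_vectors(decompose_ism(m), k = 1))
  expect_true(all(abs(abs(cm) - 1) < 1e-10))
})

test_that("reduced item vectors equal the projected rank-k reconstruction", {
  m <- seeded_binary_matrix(9, 20, seed = 404)
  sp <- decompose_ism(m)
  v3 <- item_vectors(sp, k = 3)
  proj <- m %*% sp$v[, 1:3]  # rows projected on top-3 right-singular axes
  expect_equal(unname(v3), unname(proj), tolerance = 1e-8)
  expect_error(item_vectors(sp, k = 0), "bounds")
  expect_error(item_vectors(sp, k = 100), "bounds")
})

test_that("cosine_matrix matches hand-computed plane trigonometry", {
  v <- rbind(A = c(1, 0), B = c(1, 1), C = c(0, 2))
  cm <- cosine_matrix(v)
  expect_equal(cm["A", "B"], cos(pi / 4), tolerance = 1e-12)
  expect_equal(cm["A", "C"], 0, tolerance = 1e-12)
  expect_equal(cm["B", "C"], cos(pi / 4), tolerance = 1e-12)
  expect_equal(diag(cm), c(A = 1, B = 1, C = 1))
  expect_equal(cm, t(cm))
  expect_error(cosine_matrix(rbind(A = c(1, 0), Z = c(0, 0))),
               "zero-norm.*Z")
})

test_that("identical and orthogonal vectors give cosines 1 and 0", {
  v <- rbind(A = c(2, 0), B = c(5, 0), C = c(0, 3))
  cm <- cosine_matrix(v)
  expect_equal(cm["A", "B"], 1)
  expect_equal(cm["A", "C"], 0)
})

test_that("permuting subjects leaves spectrum and cosines unchanged", {
  m <- seeded_binary_matrix(10, 30, seed = 505)
  perm <- withr::with_seed(9, sample(ncol(m)))
  sp1 <- reduce_space(decompose_ism(m))
  sp2 <- reduce_space(decompose_ism(m[, perm]))
  expect_equal(sp1$d, sp2$d, tolerance = 1e-10)
  expect_equal(cosine_matrix(sp1), cosine_matrix(sp2), tolerance = 1e-10)
})

test_that("cosine_profile extracts without recomputation", {
  m <- seeded_binary_matrix(13, 25, seed = 606)
  cm <- cosine_matrix(item_vectors(decompose_ism(m), k = 4))
  targets <- rownames(cm)[1:12]
  pr <- cosine_profile(cm, "I01", targets)
  expect_equal(nrow(pr), 12)
  expect_equal(pr$cosine[pr$target == "I01"], 1)
  expect_equal(pr$cosine, unname(cm["I01", targets]))
  expect_error(cosine_profile(cm, "NOT_AN_ITEM", targets), "NOT_AN_ITEM")
})

test_that("a focal item's strongest associate is a cluster-mate under high coherence", {
  hits <- vapply(1:50, function(i) {
    res <- cohort_cosines(small_cohort_config(coherence = 0.8, seed = 1000 + i))
    gt <- stats::setNames(res$cohort$ground_truth$cluster,
                          res$cohort$ground_truth$item)
    targets <- setdiff(rownames(res$cm), "DOG")
    pr <- cosine_profile(res$cm, "DOG", targets)
    gt[[pr$target[which.max(pr$cosine)]]] == gt[["DOG"]]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("coherent cohorts show a within-cluster cosine excess at the selected k", {
  gaps <- vapply(1:50, function(i) {
    res <- cohort_cosines(small_cohort_config(coherence = 0.8, seed = 4000 + i))
    cluster_cosine_gap(res$cm, res$cohort$ground_truth)
  }, numeric(1))
  expect_gte(mean(gaps > 0.15), 0.9)
})

test_that("semantic space exports round-trip through CSV", {
  m <- seeded_binary_matrix(8, 16, seed = 707)
  sp <- reduce_space(decompose_ism(m))
  dir <- withr::local_tempdir()
  paths <- write_semantic_space(sp, dir)
  sv <- utils::read.csv(paths["singular_values"])
  expect_equal(sv$sigma, sp$d, tolerance = 1e-12)
  cm <- utils::read.csv(paths["cosine_matrix"], check.names = FALSE)
  expect_equal(as.matrix(cm[, -1]), unname(cosine_matrix(sp)),
               tolerance = 1e-12, ignore_attr = TRUE)
})
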