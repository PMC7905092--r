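#' Flatten a cosine matrix over a fixed item set into a pair vector
#'
#' Extracts the upper triangle of the cosine matrix restricted to `items`,
#' in lexicographic pair order, so vectors from different strata over the
#' same item set align pair-for-pair and can be correlated.
#'
#' @param cm A cosine matrix from [cosine_matrix()].
#' @param items Item labels (at least 3) present in `cm`.
#' @return A tibble with columns `item1`, `item2` (item1 < item2,
#'   lexicographic order) and `cosine`; m items give m(m-1)/2 rows.
#' @export
pair_vector <- function(cm, items) {
  items <- as.character(items)
  if (length(items) < 3) stop("at least 3 items are required", call. = FALSE)
  if (anyDuplicated(items)) stop("items must be distinct", call. = FALSE)
  unknown <- setdiff(items, rownames(cm))
  if (length(unknown) > 0) {
    stop("lookup error: item(s) not in cosine matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  items <- sort(items)
  idx <- utils::combn(length(items), 2)
  tibble::tibble(
    item1 = items[idx[1, ]],
    item2 = items[idx[2, ]],
    cosine = cm[cbind(items[idx[1, ]], items[idx[2, ]])]
  )
}

#' Pearson correlation of two aligned pair vectors
#'
#' @param a,b Pair vectors from [pair_vector()] over the same item set.
#' @return The Pearson product-moment correlation of the two cosine
#'   sequences.
#' @export
correlate_pair_vectors <- function(a, b) {
  for (pv in list(a, b)) {
    if (!all(c("item1", "item2", "cosine") %in% names(pv))) {
      stop("expected pair vectors with item1/item2/cosine columns", call. = FALSE)
    }
  }
  if (nrow(a) != nrow(b) || !all(a$item1 == b$item1) || !all(a$item2 == b$item2)) {
    stop("alignment error: pair vectors cover different item pairs", call. = FALSE)
  }
  if (nrow(a) < 4) stop("at least 4 pairs are required", call. = FALSE)
  if (stats::sd(a$cosine) == 0 || stats::sd(b$cosine) == 0) {
    stop("undefined-value error: a pair vector is constant", call. = FALSE)
  }
  stats::cor(a$cosine, b$cosine)
}

#' Meng's z-test for two dependent overlapping correlations
#'
#' Compares the correlations of two variables with a shared third variable
#' (here: the baseline and follow-up cosine vectors, each correlated with the
#' healthy-reference cosine vector), accounting for their dependence through
#' the correlation `r_overlap` between the two non-shared variables.
#'
#' With z(r) the Fisher transform, the statistic is
#' \deqn{z = (z(r_1) - z(r_2)) \sqrt{\frac{n - 3}{2 (1 - r_{ov}) h}},}
#' where \eqn{\bar r^2 = (r_1^2 + r_2^2)/2},
#' \eqn{f = \min\{1, (1 - r_{ov}) / (2 (1 - \bar r^2))\}} and
#' \eqn{h = (1 - f \bar r^2) / (1 - \bar r^2)}. The confidence interval is
#' reported on the Fisher-z difference scale:
#' \eqn{(z(r_1) - z(r_2)) \pm z_{crit} \sqrt{2 (1 - r_{ov}) h / (n - 3)}}.
#'
#' When `r1 == r2` the statistic is exactly 0 (this also covers the
#' degenerate identical-input case r1 = r2 = 1, where the Fisher transforms
#' alone would diverge).
#'
#' @param r1,r2 The two correlations sharing a variable (|r| < 1).
#' @param r_overlap Correlation between the two non-shared variables.
#' @param n Number of paired observations (>= 4). For cosine pair vectors
#'   over m items this is the pair count m(m-1)/2 — the only sample size
#'   present in the computation; note it is *not* the number of subjects.
#' @param alternative `"less"` (H1: r1 < r2, the planned one-tailed
#'   improvement contrast), `"greater"`, or `"two.sided"` (alias
#'   `"two_sided"`).
#' @param conf_level Two-sided confidence level for the Fisher-z-difference
#'   interval (default 0.95).
#' @return An object of class `meng_test` with fields `statistic` (z),
#'   `p.value`, `estimate` (r1, r2, r_overlap), `n`, `conf.int`,
#'   `fisher_diff`, `alternative`. Supports [print()], [generics::tidy()]
#'   and [generics::glance()].
#' @examples
#' meng_test(0.41, 0.75, r_overlap = 0.68, n = 15, alternative = "less")
#' @export
meng_test <- function(r1, r2, r_overlap, n,
                      alternative = c("less", "greater", "two.sided", "two_sided"),
                      conf_level = 0.95) {
  alternative <- match.arg(alternative)
  if (alternative == "two_sided") alternative <- "two.sided"
  for (v in list(r1 = r1, r2 = r2, r_overlap = r_overlap)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      stop("correlations must be single finite numbers", call. = FALSE)
    }
  }
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 4) {
    stop("sample-size error: n must be an integer >= 4", call. = FALSE)
  }
  equal <- isTRUE(all.equal(r1, r2))
  if (!equal && (abs(r1) >= 1 || abs(r2) >= 1)) {
    stop("domain error: |r1| and |r2| must be < 1", call. = FALSE)
  }
  if (abs(r_overlap) > 1) {
    stop("domain error: |r_overlap| must be <= 1", call. = FALSE)
  }
  if (equal) {
    z <- 0
    diff_z <- 0
    se <- if (abs(r1) < 1) {
      rbar2 <- r1^2
      f <- min(1, (1 - r_overlap) / (2 * (1 - rbar2)))
      h <- (1 - f * rbar2) / (1 - rbar2)
      sqrt(2 * (1 - r_overlap) * h / (n - 3))
    } else NA_real_
  } else {
    rbar2 <- (r1^2 + r2^2) / 2
    f <- min(1, (1 - r_overlap) / (2 * (1 - rbar2)))
    h <- (1 - f * rbar2) / (1 - rbar2)
    diff_z <- atanh(r1) - atanh(r2)
    se <- sqrt(2 * (1 - r_overlap) * h / (n - 3))
    z <- diff_z / se
  }
  p <- switch(alternative,
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE),
              two.sided = 2 * stats::pnorm(-abs(z)))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else diff_z + c(-1, 1) * zc * se
  structure(
    list(statistic = c(z = z), p.value = p,
         estimate = c(r1 = r1, r2 = r2, r_overlap = r_overlap),
         n = as.integer(n), fisher_diff = diff_z,
         conf.int = ci, conf.level = conf_level,
         alternative = alternative,
         method = "Meng's z-test for dependent overlapping correlations"),
    class = "meng_test"
  )
}

#' @export
print.meng_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat(sprintf("r1 = %.3f, r2 = %.3f, r_overlap = %.3f, n = %d\n",
              x$estimate["r1"], x$estimate["r2"], x$estimate["r_overlap"], x$n))
  cat(sprintf("z = %.3f, p = %.4f (%s)\n",
              x$statistic, x$p.value, x$alternative))
  cat(sprintf("%d%% CI on Fisher-z difference: [%.3f, %.3f]\n\n",
              round(100 * x$conf.level), x$conf.int[1], x$conf.int[2]))
  invisible(x)
}

#' Tidy methods for test objects
#'
#' @param x A `meng_test`.
#' @param ... Unused.
#' @return `tidy()` and `glance()` both return a one-row tibble with the
#'   correlations, the z statistic, p-value and confidence bounds.
#' @method tidy meng_test
#' @export
tidy.meng_test <- function(x, ...) {
  tibble::tibble(
    r1 = unname(x$estimate["r1"]),
    r2 = unname(x$estimate["r2"]),
    r_overlap = unname(x$estimate["r_overlap"]),
    n = x$n,
    fisher_diff = x$fisher_diff,
    statistic = unname(x$statistic),
    p.value = x$p.value,
    conf.low = x$conf.int[1],
    conf.high = x$conf.int[2],
    alternative = x$alternative
  )
}

#' @rdname tidy.meng_test
#' @method glance meng_test
#' @export
glance.meng_test <- function(x, ...) tidy.meng_test(x)

#' Two-sample t-test from summary statistics (pooled variance)
#'
#' Classical equal-variance two-sample t computed from group means, standard
#' deviations and sizes, as used for demographic comparisons when only
#' summary statistics are available.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A one-row tibble: `statistic` (t, sign of mean1 - mean2), `df`
#'   (n1 + n2 - 2), `p.value` (two-sided), `method`.
#' @examples
#' pooled_t_test(35.8, 11.9, 335, 40.9, 9.8, 28)  # t = -2.205, df = 361
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  check_summary_args(sd1, n1, sd2, n2, min_sd = 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 != mean2) {
      stop("undefined-value error: zero pooled variance with unequal means",
           call. = FALSE)
    }
    t <- 0
  } else {
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  tibble::tibble(statistic = t, df = df,
                 p.value = 2 * stats::pt(-abs(t), df),
                 method = "pooled t")
}

#' Welch's t-test from summary statistics
#'
#' Unequal-variance two-sample t with Satterthwaite degrees of freedom,
#' applied when a variance-equality test rejects.
#'
#' @inheritParams pooled_t_test
#' @return A one-row tibble: `statistic`, `df` (Satterthwaite, fractional),
#'   `p.value` (two-sided), `method`.
#' @export
welch_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  check_summary_args(sd1, n1, sd2, n2, min_sd = .Machine$double.xmin)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(statistic = t, df = df,
                 p.value = 2 * stats::pt(-abs(t), df),
                 method = "Welch t")
}

check_summary_args <- function(sd1, n1, sd2, n2, min_sd) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 < min_sd || sd2 < min_sd) {
    stop("standard deviations must be ",
         if (min_sd == 0) "non-negative" else "positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' Levene's test for equality of variances (mean-centred)
#'
#' One-way ANOVA on the absolute deviations of each observation from its
#' group mean — the original mean-centred variant.
#'
#' @param sample1,sample2 Numeric vectors (each of length >= 2).
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
levene_test <- function(sample1, sample2) {
  if (length(sample1) < 2 || length(sample2) < 2) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  adev <- c(abs(sample1 - mean(sample1)), abs(sample2 - mean(sample2)))
  g <- factor(rep(c("a", "b"), c(length(sample1), length(sample2))))
  if (stats::sd(adev) == 0) {
    stop("undefined-value error: absolute deviations are constant", call. = FALSE)
  }
  an <- stats::anova(stats::lm(adev ~ g))
  tibble::tibble(statistic = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
                 p.value = an$`Pr(>F)`[1])
}

#' Pearson chi-square for a 2x2 table (no continuity correction)
#'
#' @param a,b First row counts (e.g. group 1 male/female).
#' @param c,d Second row counts.
#' @return A one-row tibble: `statistic` (chi-square), `df` (1), `p.value`.
#' @examples
#' chi_square_2x2(154, 181, 16, 12)  # chi2 = 1.295
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate-table error: a margin of the 2x2 table is zero", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p.value = ct$p.value)
}
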