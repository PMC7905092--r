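#' Singular value decomposition of an item-by-subject matrix
#'
#' Factorises the occurrence matrix M = U D V' and keeps the item-side
#' factors, the raw material of the latent semantic space. No weighting is
#' applied: the decomposition acts on the plain binary occurrence matrix.
#'
#' @param ism A `fluency_ism` (or plain numeric matrix with item rownames)
#'   with at least 2 items.
#' @return A `semantic_space` holding `items`, the non-increasing singular
#'   values `d`, the left-singular matrix `u` (items x rank basis), and the
#'   number of subjects. The selected dimensionality `k` is unset until
#'   [reduce_space()] / [select_dimensions()] is applied.
#' @seealso [select_dimensions()], [item_vectors()], [cosine_matrix()]
#' @export
decompose_ism <- function(ism) {
  m <- unclass(ism)
  if (!is.matrix(m) || !is.numeric(m)) stop("expected a numeric matrix", call. = FALSE)
  if (nrow(m) < 2) {
    stop("dimension error: at least 2 items are required for decomposition",
         call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(nrow(m)))
  s <- svd(m)
  structure(
    list(items = rownames(m), d = s$d, u = s$u, v = s$v,
         n_subjects = ncol(m), k = NULL, threshold = NULL,
         group = attr(ism, "group"), session = attr(ism, "session")),
    class = "semantic_space"
  )
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf("<semantic_space> %d items, %d subjects, rank %d\n",
              length(x$items), x$n_subjects, space_rank(x)))
  if (!is.null(x$k)) {
    frac <- cumsum(x$d) / sum(x$d)
    cat(sprintf("  k = %d (cumulative singular-value fraction %.3f at threshold %.2f)\n",
                x$k, frac[x$k], x$threshold))
  }
  invisible(x)
}

# numerical rank: singular values above 1e-10 * sigma_1
space_rank <- function(space) {
  d <- if (inherits(space, "semantic_space")) space$d else space
  sum(d > 1e-10 * d[1])
}

#' Choose the reduced dimensionality from the singular-value spectrum
#'
#' Returns the smallest k at which the cumulative sum of singular values
#' reaches the given fraction of their total. This mirrors the common
#' reporting convention for latent semantic spaces ("the first k singular
#' values carry 70% of the spectrum"). A variance-based variant (cumulative
#' squared singular values, i.e. explained variance) is available via
#' `method = "variance"` but is not the default.
#'
#' @param x A numeric vector of singular values (non-increasing,
#'   non-negative) or a `semantic_space`.
#' @param threshold Cumulative fraction to reach, in (0, 1]; default 0.70.
#' @param method `"sum"` (cumulative singular values, default) or
#'   `"variance"` (cumulative squared singular values).
#' @return Integer k.
#' @examples
#' select_dimensions(c(5, 3, 1, 1), threshold = 0.70)  # -> 2
#' @export
select_dimensions <- function(x, threshold = 0.70, method = c("sum", "variance")) {
  d <- if (inherits(x, "semantic_space")) x$d else as.numeric(x)
  method <- match.arg(method)
  if (length(d) == 0 || any(d < -1e-12) || is.unsorted(rev(d) - 1e-9 * d[1])) {
    stop("singular values must be a non-negative non-increasing sequence",
         call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  if (sum(d) <= 0) {
    stop("undefined-value error: all singular values are zero", call. = FALSE)
  }
  w <- if (method == "variance") d^2 else d
  frac <- cumsum(w) / sum(w)
  # tolerate exact-boundary floating point (e.g. cumulative fraction 0.7 itself)
  which(frac >= threshold - 1e-12)[1]
}

#' Fix the dimensionality of a semantic space
#'
#' @param space A `semantic_space` from [decompose_ism()].
#' @inheritParams select_dimensions
#' @return The space with `k` and `threshold` recorded.
#' @export
reduce_space <- function(space, threshold = 0.70, method = c("sum", "variance")) {
  stopifnot(inherits(space, "semantic_space"))
  space$k <- select_dimensions(space$d, threshold, method)
  space$threshold <- threshold
  space
}

#' Item coordinates in the reduced space
#'
#' Item i's vector is its left-singular row scaled coordinate-wise by the
#' first k singular values (the U.D convention for term vectors in latent
#' semantic analysis). At k = rank these vectors reproduce the original
#' matrix rows up to rotation, so cosines between them equal cosines between
#' raw rows.
#'
#' @param space A `semantic_space`.
#' @param k Dimensionality, `1 <= k <= rank`; defaults to the k fixed by
#'   [reduce_space()].
#' @return A numeric matrix (items x k) with item rownames.
#' @export
item_vectors <- function(space, k = space$k) {
  stopifnot(inherits(space, "semantic_space"))
  if (is.null(k)) {
    stop("k is unset: call reduce_space() or pass k explicitly", call. = FALSE)
  }
  r <- space_rank(space)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 1 || k > r) {
    stop(sprintf("bounds error: k must be an integer in [1, %d]", r), call. = FALSE)
  }
  v <- space$u[, seq_len(k), drop = FALSE] %*% diag(space$d[seq_len(k)], k, k)
  rownames(v) <- space$items
  colnames(v) <- paste0("dim", seq_len(k))
  v
}

#' Inter-item cosine similarity matrix
#'
#' @param x A matrix of item row-vectors (e.g. from [item_vectors()]) or a
#'   `semantic_space` with `k` set (its reduced item vectors are used).
#' @param k Optional dimensionality override when `x` is a `semantic_space`.
#' @return A symmetric numeric matrix of cosines in \[-1, 1\] with unit
#'   diagonal and item dimnames.
#' @export
cosine_matrix <- function(x, k = NULL) {
  if (inherits(x, "semantic_space")) {
    x <- item_vectors(x, k = if (is.null(k)) x$k else k)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric matrix of item vectors", call. = FALSE)
  }
  norms <- sqrt(rowSums(x^2))
  if (any(norms == 0)) {
    stop("undefined-value error: zero-norm vector for item(s) ",
         paste(rownames(x)[norms == 0], collapse = ", "), call. = FALSE)
  }
  cm <- tcrossprod(x / norms)
  cm[cm > 1] <- 1
  cm[cm < -1] <- -1
  diag(cm) <- 1
  dimnames(cm) <- list(rownames(x), rownames(x))
  cm
}

#' Cosine profile of one focal item
#'
#' Extracts (without recomputation) the cosines between one focal item and an
#' ordered list of target items — the per-item line of a cosine-profile plot.
#'
#' @param cm A cosine matrix from [cosine_matrix()].
#' @param focal Focal item label.
#' @param targets Ordered character vector of target item labels.
#' @return A tibble with columns `focal`, `target`, `cosine` (one row per
#'   target, in target order).
#' @export
cosine_profile <- function(cm, focal, targets) {
  known <- rownames(cm)
  unknown <- setdiff(c(focal, targets), known)
  if (length(unknown) > 0) {
    stop("lookup error: item(s) not in cosine matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  values <- unname(cm[focal, targets])
  tibble::tibble(focal = focal, target = targets, cosine = values)
}

#' Export / import a semantic space as delimited text
#'
#' Writes the singular values, the reduced item vectors and the cosine matrix
#' as three CSV files so a decomposition can be inspected or re-used outside
#' R.
#'
#' @param space A `semantic_space` with `k` set.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named paths written.
#' @export
write_semantic_space <- function(space, dir) {
  stopifnot(inherits(space, "semantic_space"))
  if (is.null(space$k)) stop("k is unset: call reduce_space() first", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    singular_values = file.path(dir, "singular_values.csv"),
    item_vectors = file.path(dir, "item_vectors.csv"),
    cosine_matrix = file.path(dir, "cosine_matrix.csv")
  )
  utils::write.csv(data.frame(index = seq_along(space$d), sigma = space$d),
                   paths["singular_values"], row.names = FALSE)
  v <- item_vectors(space)
  utils::write.csv(data.frame(item = rownames(v), v, check.names = FALSE),
                   paths["item_vectors"], row.names = FALSE)
  cm <- cosine_matrix(v)
  utils::write.csv(data.frame(item = rownames(cm), cm, check.names = FALSE),
                   paths["cosine_matrix"], row.names = FALSE)
  invisible(paths)
}

#' Tidy a semantic space or occurrence matrix
#'
#' `tidy()` on a `semantic_space` returns the singular-value spectrum with
#' cumulative fractions; on a `fluency_ism` it returns the long 0/1
#' occurrence table. `glance()` summarises the space in one row.
#'
#' @param x A `semantic_space` or `fluency_ism`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy semantic_space
#' @export
tidy.semantic_space <- function(x, ...) {
  tibble::tibble(
    index = seq_along(x$d),
    sigma = x$d,
    fraction = x$d / sum(x$d),
    cumulative = cumsum(x$d) / sum(x$d)
  )
}

#' @rdname tidy.semantic_space
#' @method glance semantic_space
#' @export
glance.semantic_space <- function(x, ...) {
  tibble::tibble(
    n_items = length(x$items),
    n_subjects = x$n_subjects,
    rank = space_rank(x),
    k = if (is.null(x$k)) NA_integer_ else x$k,
    threshold = if (is.null(x$threshold)) NA_real_ else x$threshold,
    cumulative_at_k = if (is.null(x$k)) NA_real_ else cumsum(x$d)[x$k] / sum(x$d)
  )
}
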