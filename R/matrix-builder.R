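#' Build the binary item-by-subject occurrence matrix
#'
#' Rows are canonical items, columns are subjects; a cell is 1 iff the subject
#' produced the item (after cleaning). Because repetitions are removed by
#' cleaning, a subject contributes each item at most once, so cells are
#' binary and row sums are the per-item occurrence frequencies. The matrix is
#' built within a single (group, session) stratum; mixing strata is an error
#' because each stratum is decomposed into its own semantic space.
#'
#' @param cleaned A cleaned transcript tibble from [clean_transcripts()],
#'   restricted to one group and session.
#' @return A `fluency_ism`: a 0/1 integer matrix with item rownames and
#'   subject colnames, carrying `group` and `session` attributes. Items and
#'   subjects are sorted alphabetically for determinism.
#' @examples
#' lex <- fluency_lexicon(c("DOG", "CAT"))
#' tr <- tibble::tibble(subject_id = "S1", group = "patient",
#'                      session = "baseline", rank = 1:2,
#'                      token = c("DOG", "CAT"))
#' build_ism(clean_transcripts(tr, lex))
#' @export
build_ism <- function(cleaned) {
  kept <- kept_responses(cleaned)
  strata <- unique(paste(cleaned$group, cleaned$session, sep = "\r"))
  if (length(strata) > 1) {
    stop("stratum error: transcripts mix more than one (group, session) stratum; ",
         "build one matrix per stratum", call. = FALSE)
  }
  if (nrow(kept) == 0) {
    stop("empty-matrix error: no kept tokens in this stratum", call. = FALSE)
  }
  items <- sort(unique(kept$canonical))
  subjects <- sort(unique(cleaned$subject_id))
  m <- matrix(0L, nrow = length(items), ncol = length(subjects),
              dimnames = list(items, subjects))
  m[cbind(match(kept$canonical, items), match(kept$subject_id, subjects))] <- 1L
  structure(m, class = c("fluency_ism", class(m)),
            group = cleaned$group[1], session = cleaned$session[1])
}

#' @export
print.fluency_ism <- function(x, ...) {
  cat(sprintf("<fluency_ism> %d items x %d subjects (%s / %s)\n",
              nrow(x), ncol(x), attr(x, "group"), attr(x, "session")))
  invisible(x)
}

#' Item frequency table
#'
#' Per-item occurrence counts (number of subjects producing the item), ranked
#' by descending count with alphabetical tie-breaking so rankings are
#' reproducible.
#'
#' @param x A `fluency_ism` from [build_ism()], or a tibble with `item` and
#'   `count` columns (e.g. published counts) to be re-ranked.
#' @return A tibble with columns `rank`, `item`, `count`.
#' @export
frequency_table <- function(x) {
  if (inherits(x, "fluency_ism")) {
    tb <- tibble::tibble(item = rownames(x), count = as.integer(rowSums(x)))
  } else if (is.data.frame(x)) {
    if (!all(c("item", "count") %in% names(x))) {
      stop("frequency_table() needs 'item' and 'count' columns", call. = FALSE)
    }
    tb <- tibble::tibble(item = as.character(x$item), count = as.integer(x$count))
  } else {
    stop("frequency_table() expects a fluency_ism or a data frame", call. = FALSE)
  }
  if (any(tb$count < 1)) {
    stop("frequency counts must be >= 1 (zero-occurrence items are excluded)",
         call. = FALSE)
  }
  tb <- dplyr::arrange(tb, dplyr::desc(.data$count), .data$item)
  dplyr::mutate(tb, rank = dplyr::row_number(), .before = 1)
}

#' Items frequent in every table
#'
#' Returns the items whose count reaches `min_freq` in *every* supplied
#' frequency table — the dual-session selection rule used to pick the item
#' set submitted to the semantic-space comparison. The threshold is
#' inclusive (`count >= min_freq`).
#'
#' @param ... Two or more frequency tables (tibbles with `item` and `count`),
#'   or a single list of them.
#' @param min_freq Minimum count required in each table (default 10).
#' @return Alphabetically sorted character vector of items (possibly empty).
#' @export
select_common_frequent_items <- function(..., min_freq = 10) {
  tables <- list(...)
  if (length(tables) == 1 && is.list(tables[[1]]) && !is.data.frame(tables[[1]])) {
    tables <- tables[[1]]
  }
  if (length(tables) < 1) stop("at least one frequency table is required", call. = FALSE)
  if (!is.numeric(min_freq) || length(min_freq) != 1 || min_freq < 1) {
    stop("min_freq must be a single count >= 1", call. = FALSE)
  }
  sets <- lapply(tables, function(tb) {
    if (!all(c("item", "count") %in% names(tb))) {
      stop("each table needs 'item' and 'count' columns", call. = FALSE)
    }
    tb$item[tb$count >= min_freq]
  })
  sort(Reduce(intersect, sets))
}

#' Top-k most frequent items
#'
#' @param table A frequency table (tibble with `item` and `count`).
#' @param k Number of items, `1 <= k <=` number of items in the table.
#' @return Character vector of the `k` highest-ranked items (descending
#'   count, alphabetical ties).
#' @export
top_k_items <- function(table, k) {
  tb <- frequency_table(table)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  if (k > nrow(tb)) {
    stop(sprintf("bounds error: k = %d exceeds the %d items in the table",
                 as.integer(k), nrow(tb)), call. = FALSE)
  }
  tb$item[seq_len(k)]
}

#' @rdname tidy.semantic_space
#' @method tidy fluency_ism
#' @export
tidy.fluency_ism <- function(x, ...) {
  tibble::tibble(
    item = rep(rownames(x), times = ncol(x)),
    subject_id = rep(colnames(x), each = nrow(x)),
    present = as.integer(x)
  )
}

#' Write / read an item-by-subject matrix as delimited text
#'
#' @param ism A `fluency_ism`.
#' @param path File path.
#' @return `path` (write) or a `fluency_ism` (read).
#' @export
write_ism <- function(ism, path) {
  stopifnot(inherits(ism, "fluency_ism"))
  df <- data.frame(item = rownames(ism), unclass(ism), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param group,session Stratum labels to attach on read.
#' @rdname write_ism
#' @export
read_ism <- function(path, group = NA_character_, session = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$item
  storage.mode(m) <- "integer"
  structure(m, class = c("fluency_ism", class(m)), group = group, session = session)
}
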