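#' Read category-fluency transcripts from delimited text
#'
#' A transcript file holds one row per uttered token, in long format, with
#' header columns `subject_id`, `group`, `session`, `rank`, `token`. `rank` is
#' the 1-based position of the token within a subject-session list; rows may
#' appear in any order in the file.
#'
#' @param source Path to a delimited text file (or a connection).
#' @param delim Field delimiter, default comma.
#' @return A tibble with columns `subject_id`, `group`, `session` (character),
#'   `rank` (integer) and `token` (character), sorted by subject, session and
#'   rank. The row count equals the number of data rows in the file.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("subject_id,group,session,rank,token",
#'              "S1,patient,baseline,2,cat",
#'              "S1,patient,baseline,1,dog"), tf)
#' read_transcripts(tf)
#' @export
read_transcripts <- function(source, delim = ",") {
  df <- utils::read.csv(source, sep = delim, colClasses = "character",
                        strip.white = TRUE, fileEncoding = "UTF-8")
  required <- c("subject_id", "group", "session", "rank", "token")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("transcript format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df[required])
  rank <- suppressWarnings(as.integer(df$rank))
  if (anyNA(rank) || any(rank < 1)) {
    stop("transcript format error: 'rank' must be a positive integer",
         call. = FALSE)
  }
  df$rank <- rank
  key <- paste(df$subject_id, df$session, df$rank, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf(
      "transcript integrity error: duplicate (subject_id, session, rank) = (%s, %s, %d)",
      dup$subject_id, dup$session, dup$rank), call. = FALSE)
  }
  dplyr::arrange(df, .data$subject_id, .data$session, .data$rank)
}

#' Construct a category lexicon
#'
#' A lexicon defines the target category for cleaning: the canonical item
#' labels, a synonym map from raw surface forms to canonical forms, and the
#' surface forms to be scored as proper-noun errors. All forms are matched
#' case-insensitively (stored upper-case).
#'
#' @param canonical Character vector of canonical item labels.
#' @param synonyms Named character vector mapping raw forms (names) to
#'   canonical forms (values). Values must be canonical items.
#' @param proper_nouns Character vector of surface forms scored as proper
#'   nouns; must be disjoint from the canonical items.
#' @return An object of class `fluency_lexicon`.
#' @examples
#' lex <- fluency_lexicon(c("DOG", "CAT"), synonyms = c(PUPPY = "DOG"),
#'                        proper_nouns = "SNOOPY")
#' @export
fluency_lexicon <- function(canonical, synonyms = character(), proper_nouns = character()) {
  canonical <- unique(toupper(trimws(as.character(canonical))))
  canonical <- canonical[nzchar(canonical)]
  if (length(canonical) == 0) stop("lexicon needs at least one canonical item", call. = FALSE)
  proper_nouns <- unique(toupper(trimws(as.character(proper_nouns))))
  proper_nouns <- proper_nouns[nzchar(proper_nouns)]
  if (length(synonyms) > 0) {
    if (is.null(names(synonyms)) || any(!nzchar(names(synonyms)))) {
      stop("synonyms must be a named character vector (raw -> canonical)", call. = FALSE)
    }
    syn <- toupper(trimws(as.character(synonyms)))
    names(syn) <- toupper(trimws(names(synonyms)))
    if (!all(syn %in% canonical)) {
      stop("synonym targets must be canonical items: ",
           paste(setdiff(syn, canonical), collapse = ", "), call. = FALSE)
    }
    synonyms <- syn
  } else {
    synonyms <- stats::setNames(character(), character())
  }
  if (length(intersect(proper_nouns, canonical)) > 0) {
    stop("proper nouns must be disjoint from canonical items: ",
         paste(intersect(proper_nouns, canonical), collapse = ", "), call. = FALSE)
  }
  structure(list(canonical = sort(canonical), synonym_map = synonyms,
                 proper_nouns = sort(proper_nouns)),
            class = "fluency_lexicon")
}

#' @export
print.fluency_lexicon <- function(x, ...) {
  cat("<fluency_lexicon> ", length(x$canonical), " canonical items, ",
      length(x$synonym_map), " synonyms, ",
      length(x$proper_nouns), " proper nouns\n", sep = "")
  invisible(x)
}

#' Read a lexicon from delimited text
#'
#' Expected header: `raw,canonical,is_proper_noun`. A row with `raw ==
#' canonical` declares a canonical item; a row with a different non-empty
#' `canonical` declares a synonym; a row with `is_proper_noun` true declares a
#' proper-noun form (its `canonical` field is ignored). Rows with an empty
#' `canonical` and false `is_proper_noun` merely enumerate known intrusions;
#' they carry no information for cleaning (any unknown form is an intrusion).
#'
#' @param source Path or connection to the lexicon file.
#' @param delim Field delimiter, default comma.
#' @return A [fluency_lexicon()] object.
#' @export
read_lexicon <- function(source, delim = ",") {
  df <- utils::read.csv(source, sep = delim, colClasses = "character",
                        strip.white = TRUE, fileEncoding = "UTF-8")
  required <- c("raw", "canonical", "is_proper_noun")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("lexicon format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pn_flag <- tolower(trimws(df$is_proper_noun)) %in% c("true", "t", "1", "yes")
  raw <- toupper(trimws(df$raw))
  canon <- toupper(trimws(df$canonical))
  is_item <- !pn_flag & nzchar(canon) & raw == canon
  is_syn <- !pn_flag & nzchar(canon) & raw != canon
  fluency_lexicon(
    canonical = canon[is_item | is_syn],
    synonyms = stats::setNames(canon[is_syn], raw[is_syn]),
    proper_nouns = raw[pn_flag]
  )
}

#' Write a lexicon to delimited text
#'
#' Inverse of [read_lexicon()]; used when exporting synthetic fixtures.
#'
#' @param lexicon A [fluency_lexicon()].
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path, delim = ",") {
  stopifnot(inherits(lexicon, "fluency_lexicon"))
  df <- rbind(
    data.frame(raw = lexicon$canonical, canonical = lexicon$canonical,
               is_proper_noun = "false"),
    if (length(lexicon$synonym_map) > 0)
      data.frame(raw = names(lexicon$synonym_map),
                 canonical = unname(lexicon$synonym_map),
                 is_proper_noun = "false"),
    if (length(lexicon$proper_nouns) > 0)
      data.frame(raw = lexicon$proper_nouns, canonical = "",
                 is_proper_noun = "true")
  )
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Clean fluency transcripts: repetitions, intrusions, proper nouns
#'
#' Applies the normative scoring rules for category fluency: every token is
#' trimmed, case-folded and synonym-mapped to a candidate canonical form, then
#' classified in this order — proper noun (surface form flagged in the
#' lexicon), intrusion (candidate form not a canonical category member),
#' repetition (canonical form already produced earlier in the same
#' subject-session list), otherwise kept. Each token receives exactly one
#' status, so kept + removed counts always equal the raw token count, and kept
#' items preserve their order of first production.
#'
#' A repetition is a repeat of the same *canonical* item: "dog" after "DOG",
#' or a synonym of an item already named, counts as a repetition.
#'
#' @param transcripts A transcript tibble as returned by [read_transcripts()]
#'   (columns `subject_id`, `group`, `session`, `rank`, `token`).
#' @param lexicon A [fluency_lexicon()].
#' @return The transcript tibble with two added columns: `canonical` (the
#'   normalised, synonym-mapped form) and `status` (one of `"kept"`,
#'   `"repetition"`, `"intrusion"`, `"proper_noun"`).
#' @examples
#' lex <- fluency_lexicon(c("DOG", "CAT"))
#' tr <- tibble::tibble(subject_id = "S1", group = "patient",
#'                      session = "baseline", rank = 1:3,
#'                      token = c("DOG", "dog", "APPLE"))
#' clean_transcripts(tr, lex)
#' @export
clean_transcripts <- function(transcripts, lexicon) {
  stopifnot(inherits(lexicon, "fluency_lexicon"))
  required <- c("subject_id", "group", "session", "rank", "token")
  missing <- setdiff(required, names(transcripts))
  if (length(missing) > 0) {
    stop("transcripts missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::arrange(tibble::as_tibble(transcripts),
                        .data$subject_id, .data$session, .data$rank)
  norm <- toupper(trimws(out$token))
  mapped <- ifelse(norm %in% names(lexicon$synonym_map),
                   unname(lexicon$synonym_map[norm]), norm)
  out$canonical <- mapped
  out$status <- dplyr::if_else(
    mapped %in% lexicon$proper_nouns, "proper_noun",
    dplyr::if_else(mapped %in% lexicon$canonical, NA_character_, "intrusion")
  )
  out <- dplyr::group_by(out, .data$subject_id, .data$session)
  out <- dplyr::mutate(
    out,
    status = {
      s <- .data$status
      member <- is.na(s)
      s[member] <- ifelse(duplicated(.data$canonical[member]),
                          "repetition", "kept")
      s
    }
  )
  dplyr::ungroup(out)
}

#' Keep only retained tokens of a cleaned transcript
#'
#' @param cleaned Output of [clean_transcripts()].
#' @return The subset of rows with `status == "kept"`.
#' @export
kept_responses <- function(cleaned) {
  if (!"status" %in% names(cleaned)) {
    stop("expected a cleaned transcript (no 'status' column); run clean_transcripts() first",
         call. = FALSE)
  }
  dplyr::filter(cleaned, .data$status == "kept")
}

#' Per-token cleaning audit counts
#'
#' @param cleaned Output of [clean_transcripts()].
#' @return A tibble of token counts per group, session and status.
#' @export
cleaning_audit <- function(cleaned) {
  if (!"status" %in% names(cleaned)) {
    stop("expected a cleaned transcript; run clean_transcripts() first", call. = FALSE)
  }
  dplyr::count(cleaned, .data$group, .data$session, .data$status, name = "n_tokens")
}

#' Type-token ratio of cleaned fluency output
#'
#' The type-token ratio (TTR) is the number of distinct canonical items
#' divided by the total number of kept tokens, a lexical-diversity summary.
#' By default it is pooled across all rows (the per-condition convention);
#' pass `by` to compute it per stratum or per subject instead.
#'
#' @param cleaned Output of [clean_transcripts()].
#' @param by Optional character vector of grouping columns (e.g.
#'   `c("group", "session")` or `"subject_id"`).
#' @return A single ratio in (0, 1] when `by` is `NULL`; otherwise a tibble
#'   with the grouping columns, `types`, `tokens` and `ttr`.
#' @export
type_token_ratio <- function(cleaned, by = NULL) {
  kept <- kept_responses(cleaned)
  if (is.null(by)) {
    if (nrow(kept) == 0) {
      stop("type-token ratio undefined: no kept tokens", call. = FALSE)
    }
    return(length(unique(kept$canonical)) / nrow(kept))
  }
  out <- dplyr::summarise(
    dplyr::group_by(kept, dplyr::across(dplyr::all_of(by))),
    types = dplyr::n_distinct(.data$canonical),
    tokens = dplyr::n(),
    .groups = "drop"
  )
  dplyr::mutate(out, ttr = .data$types / .data$tokens)
}
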