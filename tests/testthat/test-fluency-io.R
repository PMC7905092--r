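test_that("read_transcripts orders tokens by rank and conserves rows", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,session,rank,token",
               "S1,patient,baseline,2,cat",
               "S1,patient,baseline,1,dog"), tf)
  tr <- read_transcripts(tf)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$token, c("dog", "cat"))
  expect_equal(tr$rank, 1:2)
})

test_that("read_transcripts handles an empty file with header", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject_id,group,session,rank,token", tf)
  expect_equal(nrow(read_transcripts(tf)), 0)
})

test_that("read_transcripts is invariant to file row order", {
  lists <- list(S1 = c("dog", "cat", "lion"), S2 = c("tiger", "cat"),
                S3 = c("giraffe", "elephant", "dog", "cat"))
  base <- make_transcripts(lists)
  shuffled <- base[c(7, 2, 9, 5, 1, 8, 4, 3, 6), ]
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(base, f1, row.names = FALSE, quote = FALSE)
  utils::write.csv(shuffled, f2, row.names = FALSE, quote = FALSE)
  expect_equal(read_transcripts(f1), read_transcripts(f2))
})

test_that("read_transcripts rejects malformed files", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,rank,token", "S1,patient,1,dog"), tf)
  expect_error(read_transcripts(tf), "missing column.*session")
  writeLines(c("subject_id,group,session,rank,token",
               "S1,patient,baseline,1,dog",
               "S1,patient,baseline,1,cat"), tf)
  expect_error(read_transcripts(tf), "duplicate")
})

test_that("lexicon invariants are enforced and round-trip through files", {
  expect_error(fluency_lexicon("DOG", proper_nouns = "DOG"), "disjoint")
  expect_error(fluency_lexicon("DOG", synonyms = c(PUP = "WOLF")), "canonical")
  lex <- tiny_lexicon()
  tf <- withr::local_tempfile(fileext = ".csv")
  write_lexicon(lex, tf)
  lex2 <- read_lexicon(tf)
  expect_equal(lex2$canonical, lex$canonical)
  expect_equal(sort(names(lex2$synonym_map)), sort(names(lex$synonym_map)))
  expect_equal(lex2$proper_nouns, lex$proper_nouns)
})

test_that("cleaning classifies repetitions, intrusions and proper nouns", {
  lex <- tiny_lexicon()
  cl <- clean_transcripts(make_transcripts(list(S1 = c("DOG", "dog", "CAT"))), lex)
  expect_equal(cl$status, c("kept", "repetition", "kept"))
  expect_equal(cl$canonical[cl$status == "kept"], c("DOG", "CAT"))

  cl <- clean_transcripts(make_transcripts(list(S1 = c("DOG", "APPLE"))), lex)
  expect_equal(cl$status, c("kept", "intrusion"))

  # synonym mapping happens before the repetition check; proper nouns
  # are flagged before category membership
  cl <- clean_transcripts(
    make_transcripts(list(S1 = c("puppy", "DOG", "SNOOPY", "snoopy"))), lex)
  expect_equal(cl$canonical[1], "DOG")
  expect_equal(cl$status, c("kept", "repetition", "proper_noun", "proper_noun"))
})

test_that("cleaning is idempotent on the kept list", {
  lex <- tiny_lexicon()
  raw <- make_transcripts(list(S1 = c("DOG", "dog", "APPLE", "CAT", "SNOOPY")))
  cl <- clean_transcripts(raw, lex)
  kept <- kept_responses(cl)
  again <- clean_transcripts(
    make_transcripts(list(S1 = kept$canonical)), lex)
  expect_true(all(again$status == "kept"))
  expect_equal(again$canonical, kept$canonical)
})

test_that("cleaning conserves tokens with one reason each, preserving order", {
  cfg <- small_cohort_config(seed = 11, n_subjects = 20,
                             error_rates = c(repetition = 0.1,
                                             intrusion = 0.08,
                                             proper_noun = 0.05))
  coh <- generate_cohort(cfg)
  cl <- clean_transcripts(coh$transcripts, coh$lexicon)
  # conservation: every raw token got exactly one status
  expect_equal(nrow(cl), nrow(coh$transcripts))
  expect_true(all(cl$status %in% c("kept", "repetition", "intrusion", "proper_noun")))
  # kept items keep their relative order and are unique per subject
  per_subject <- split(cl[cl$status == "kept", ], cl$subject_id[cl$status == "kept"])
  for (df in per_subject) {
    expect_false(is.unsorted(df$rank))
    expect_false(anyDuplicated(df$canonical) > 0)
  }
})

test_that("type-token ratio matches its definition", {
  lex <- tiny_lexicon()
  # 3 subjects, disjoint pairs -> 6 types / 6 tokens
  cl <- clean_transcripts(make_transcripts(list(
    S1 = c("DOG", "CAT"), S2 = c("LION", "TIGER"),
    S3 = c("ELEPHANT", "GIRAFFE"))), lex)
  expect_equal(type_token_ratio(cl), 1.0)
  # 4 subjects all saying DOG -> 1 type / 4 tokens
  cl <- clean_transcripts(make_transcripts(list(
    S1 = "DOG", S2 = "DOG", S3 = "DOG", S4 = "DOG")), lex)
  expect_equal(type_token_ratio(cl), 0.25)
  # no kept tokens -> undefined
  cl <- clean_transcripts(make_transcripts(list(S1 = "APPLE")), lex)
  expect_error(type_token_ratio(cl), "undefined|no kept")
})

test_that("type-token ratio equals the brute-force pooled count", {
  cfg <- small_cohort_config(seed = 21, n_subjects = 15)
  coh <- generate_cohort(cfg)
  cl <- clean_transcripts(coh$transcripts, coh$lexicon)
  kept <- kept_responses(cl)
  expect_equal(type_token_ratio(cl),
               length(unique(kept$canonical)) / length(kept$canonical))
  by_subj <- type_token_ratio(cl, by = "subject_id")
  expect_equal(nrow(by_subj), length(unique(coh$transcripts$subject_id)))
  expect_true(all(by_subj$ttr > 0 & by_subj$ttr <= 1))
})
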