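# small shared fixtures, all built in code

tiny_lexicon <- function() {
  fluency_lexicon(
    canonical = c("DOG", "CAT", "LION", "TIGER", "ELEPHANT", "GIRAFFE"),
    synonyms = c(PUPPY = "DOG", KITTY = "CAT"),
    proper_nouns = "SNOOPY"
  )
}

# named list subject_id -> token vector, one stratum
make_transcripts <- function(lists, group = "patient", session = "baseline") {
  dplyr::bind_rows(lapply(names(lists), function(id) {
    tibble::tibble(subject_id = id, group = group, session = session,
                   rank = seq_along(lists[[id]]), token = lists[[id]])
  }))
}

# 12-item clustered patient-scale cohort configuration
small_cohort_config <- function(coherence = 0.8, seed = 1, n_subjects = 28,
                                list_length_mean = 7, list_length_sd = 2.5,
                                ...) {
  synthetic_config(animal_clusters(4), coherence = coherence,
                   list_length_mean = list_length_mean,
                   list_length_sd = list_length_sd,
                   n_subjects = n_subjects, group = "patient",
                   session = "single", subject_prefix = "P",
                   seed = seed, ...)
}

cohort_cosines <- function(cfg) {
  coh <- generate_cohort(cfg)
  cleaned <- clean_transcripts(coh$transcripts, coh$lexicon)
  space <- reduce_space(decompose_ism(build_ism(cleaned)))
  list(cohort = coh, cleaned = cleaned, space = space,
       cm = cosine_matrix(space))
}

# mean within-cluster minus mean between-cluster cosine
cluster_cosine_gap <- function(cm, ground_truth) {
  gt <- stats::setNames(ground_truth$cluster, ground_truth$item)
  same <- outer(gt[rownames(cm)], gt[colnames(cm)], "==")
  ut <- upper.tri(cm)
  mean(cm[ut & same]) - mean(cm[ut & !same])
}
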