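#' Built-in animal lexicon with subcategory clusters
#'
#' A fixed animal vocabulary organised into the three subcategories that
#' structure adult category-fluency output — pets, carnivores and herbivores
#' — used as the default ground truth of the synthetic cohort generator.
#'
#' @param n_per_cluster Items per cluster (1 to 12). The small 4-per-cluster
#'   variant (12 items) matches the size of a typical frequent-item set; the
#'   full 12-per-cluster variant (36 items) gives a realistic vocabulary from
#'   which a frequent subset emerges.
#' @return Named list of character vectors (`pet`, `carnivore`,
#'   `herbivore`).
#' @export
animal_clusters <- function(n_per_cluster = 12) {
  pools <- list(
    pet = c("DOG", "CAT", "RABBIT", "BIRD", "HAMSTER", "GOLDFISH", "TURTLE",
            "PONY", "PARROT", "FERRET", "CANARY", "GUINEA_PIG"),
    carnivore = c("LION", "TIGER", "BEAR", "WOLF", "FOX", "LEOPARD",
                  "CHEETAH", "HYENA", "JAGUAR", "PUMA", "LYNX", "BADGER"),
    herbivore = c("ELEPHANT", "GIRAFFE", "ZEBRA", "HORSE", "COW", "SHEEP",
                  "DEER", "GOAT", "HIPPOPOTAMUS", "RHINOCEROS", "CAMEL",
                  "KANGAROO")
  )
  stopifnot(n_per_cluster >= 1, n_per_cluster <= 12)
  lapply(pools, function(x) x[seq_len(n_per_cluster)])
}

#' Zipf-like popularity weights over clustered items
#'
#' Assigns weight 1 / rank^s, with ranks interleaved across clusters (first
#' item of each cluster first, then second of each, ...) so that the most
#' popular items span subcategories, as observed in empirical frequency
#' rankings.
#'
#' @param clusters Named list of item vectors.
#' @param exponent Zipf exponent s (default 1).
#' @return Named numeric vector of positive weights over all items.
#' @export
zipf_popularity <- function(clusters, exponent = 1) {
  order <- unlist(lapply(seq_len(max(lengths(clusters))), function(i) {
    unlist(lapply(clusters, function(x) if (i <= length(x)) x[i] else NULL))
  }), use.names = FALSE)
  stats::setNames(1 / seq_along(order)^exponent, order)
}

default_intrusions <- function() {
  c("APPLE", "ORANGE", "BANANA", "CARROT", "MELON", "GRAPE", "TABLE", "CHAIR")
}

default_proper_nouns <- function() {
  c("SNOOPY", "MICKEY", "POCHI", "TAMA", "HACHI", "DUMBO")
}

#' Configuration of a synthetic fluency cohort
#'
#' Defines the generative model for one cohort: a clustered vocabulary with
#' Zipf-like item popularity, a cluster-coherent recall walk, a per-subject
#' list-length distribution, and per-token error rates. Defaults emulate the
#' healthy reference cohort of the motivating study: 335 subjects, mean raw
#' list length 20.9 (SD 4.5), a 36-item vocabulary in three subcategories.
#'
#' @param clusters Named list of disjoint item vectors (the cluster ground
#'   truth).
#' @param popularity Named positive weights covering every item; default
#'   [zipf_popularity()] over `clusters`.
#' @param coherence Probability c in \[0, 1\] that recall continues within
#'   the current subcategory rather than sampling from the whole unused
#'   vocabulary.
#' @param list_length_mean,list_length_sd Normal mean/SD of the per-subject
#'   recalled-item count, truncated to \[1, number of items\]. The mean must
#'   not exceed the vocabulary size.
#' @param n_subjects Cohort size.
#' @param error_rates Named probabilities in \[0, 1) — `repetition`,
#'   `intrusion`, `proper_noun` — of inserting an error token after each
#'   recalled token.
#' @param group,session Stratum labels attached to the transcripts.
#' @param subject_prefix Prefix for generated subject IDs.
#' @param intrusion_pool,proper_noun_pool Surface forms used for injected
#'   errors; the proper-noun pool is flagged in the cohort lexicon, the
#'   intrusion pool is simply absent from it.
#' @param seed Integer seed; identical configurations and seeds yield
#'   byte-identical cohorts.
#' @return A validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(clusters = animal_clusters(12),
                             popularity = zipf_popularity(clusters),
                             coherence = 0.7,
                             list_length_mean = 20.9,
                             list_length_sd = 4.5,
                             n_subjects = 335,
                             error_rates = c(repetition = 0.04,
                                             intrusion = 0.02,
                                             proper_noun = 0.01),
                             group = "control", session = "single",
                             subject_prefix = "C",
                             intrusion_pool = default_intrusions(),
                             proper_noun_pool = default_proper_nouns(),
                             seed = 1L) {
  items <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(items)) {
    stop("config error: cluster item lists must be disjoint", call. = FALSE)
  }
  if (!all(items %in% names(popularity)) || any(popularity <= 0)) {
    stop("config error: popularity must assign a positive weight to every item",
         call. = FALSE)
  }
  if (coherence < 0 || coherence > 1) {
    stop("config error: coherence must lie in [0, 1]", call. = FALSE)
  }
  need <- c("repetition", "intrusion", "proper_noun")
  if (!all(need %in% names(error_rates)) ||
      any(error_rates[need] < 0) || any(error_rates[need] >= 1)) {
    stop("config error: error_rates must name repetition/intrusion/proper_noun, each in [0, 1)",
         call. = FALSE)
  }
  if (list_length_mean < 1 || list_length_mean > length(items)) {
    stop(sprintf(
      "config error: list_length_mean (%.1f) must lie within [1, %d] (vocabulary size)",
      list_length_mean, length(items)), call. = FALSE)
  }
  if (n_subjects < 1) stop("config error: n_subjects must be >= 1", call. = FALSE)
  if (any(intrusion_pool %in% items) || any(proper_noun_pool %in% items)) {
    stop("config error: error pools must be disjoint from the vocabulary",
         call. = FALSE)
  }
  structure(
    list(clusters = clusters, popularity = popularity[items],
         coherence = coherence, list_length_mean = list_length_mean,
         list_length_sd = list_length_sd, n_subjects = as.integer(n_subjects),
         error_rates = error_rates[need], group = group, session = session,
         subject_prefix = subject_prefix,
         intrusion_pool = toupper(intrusion_pool),
         proper_noun_pool = toupper(proper_noun_pool),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %d subjects (%s/%s), %d items in %d clusters, coherence %.2f, seed %d\n",
    x$n_subjects, x$group, x$session, length(x$popularity),
    length(x$clusters), x$coherence, x$seed))
  invisible(x)
}

#' Lexicon implied by a synthetic configuration
#'
#' @param config A [synthetic_config()].
#' @return A [fluency_lexicon()] whose canonical items are the configured
#'   vocabulary and whose proper nouns are the configured proper-noun pool.
#' @export
cohort_lexicon <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  fluency_lexicon(canonical = unlist(config$clusters, use.names = FALSE),
                  proper_nouns = config$proper_noun_pool)
}

# weighted draw of one element; safe for length-1 pools
draw_one <- function(pool, weights) {
  pool[sample.int(length(pool), 1L, prob = weights)]
}

generate_subject_tokens <- function(config, cluster_of) {
  items <- names(config$popularity)
  pop <- config$popularity
  len <- round(stats::rnorm(1, config$list_length_mean, config$list_length_sd))
  len <- max(1L, min(length(items), len))
  recall <- character(len)
  unused <- items
  current <- NA_character_
  for (i in seq_len(len)) {
    in_cluster <- if (is.na(current)) character() else
      unused[cluster_of[unused] == current]
    pool <- if (i > 1 && stats::runif(1) < config$coherence &&
                length(in_cluster) > 0) in_cluster else unused
    pick <- draw_one(pool, pop[pool])
    recall[i] <- pick
    current <- cluster_of[[pick]]
    unused <- setdiff(unused, pick)
  }
  # error injection: after each recalled token, independently insert errors
  rates <- config$error_rates
  tokens <- character(0)
  for (i in seq_len(len)) {
    tokens <- c(tokens, recall[i])
    if (stats::runif(1) < rates[["repetition"]]) {
      tokens <- c(tokens, draw_one(recall[seq_len(i)], NULL))
    }
    if (stats::runif(1) < rates[["intrusion"]]) {
      tokens <- c(tokens, draw_one(config$intrusion_pool, NULL))
    }
    if (stats::runif(1) < rates[["proper_noun"]]) {
      tokens <- c(tokens, draw_one(config$proper_noun_pool, NULL))
    }
  }
  tokens
}

#' Generate a synthetic fluency cohort
#'
#' Simulates each subject's recall as a popularity-weighted walk over the
#' vocabulary without replacement: with probability `coherence` the next item
#' is drawn from the unused members of the current subcategory (moving on
#' when the subcategory is exhausted), otherwise from all unused items. Error
#' tokens (repetitions of earlier output, out-of-category intrusions,
#' proper nouns) are then inserted at the configured per-token rates, so the
#' raw transcripts exercise every cleaning rule.
#'
#' @param config A [synthetic_config()].
#' @return A list with `transcripts` (long tibble in the standard transcript
#'   format), `ground_truth` (tibble `item`, `cluster`), `lexicon` (the
#'   [cohort_lexicon()]) and `config`.
#' @examples
#' cfg <- synthetic_config(animal_clusters(4), n_subjects = 5,
#'                         list_length_mean = 7, list_length_sd = 2, seed = 42)
#' cohort <- generate_cohort(cfg)
#' head(cohort$transcripts)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cluster_of <- stats::setNames(
    rep(names(config$clusters), lengths(config$clusters)),
    unlist(config$clusters, use.names = FALSE))
  transcripts <- withr::with_seed(config$seed, {
    rows <- lapply(seq_len(config$n_subjects), function(s) {
      tokens <- generate_subject_tokens(config, cluster_of)
      tibble::tibble(
        subject_id = sprintf("%s%03d", config$subject_prefix, s),
        group = config$group, session = config$session,
        rank = seq_along(tokens), token = tokens)
    })
    dplyr::bind_rows(rows)
  })
  list(
    transcripts = transcripts,
    ground_truth = tibble::tibble(item = names(cluster_of),
                                  cluster = unname(cluster_of)),
    lexicon = cohort_lexicon(config),
    config = config
  )
}

#' Generate the three-cohort study design
#'
#' Produces patient-baseline, patient-followup and healthy-reference cohorts
#' sharing one vocabulary and cluster ground truth, labelled and bound into a
#' single transcript table ready for the full pipeline. The three
#' configurations typically differ in coherence (baseline lower than
#' follow-up and reference) and cohort size. Sessions are generated
#' independently; any baseline-follow-up dependence emerges from the shared
#' popularity and cluster structure.
#'
#' @param config_baseline,config_followup Configurations for the patient
#'   sessions (group/session labels are forced to `patient` /
#'   `baseline`/`followup`).
#' @param config_reference Configuration for the healthy reference cohort
#'   (forced to `control` / `single`).
#' @return A list with `transcripts` (all three strata), `ground_truth`,
#'   `lexicon` and `configs`.
#' @export
paired_cohorts <- function(config_baseline, config_followup, config_reference) {
  configs <- list(baseline = config_baseline, followup = config_followup,
                  reference = config_reference)
  for (cfg in configs) stopifnot(inherits(cfg, "synthetic_config"))
  same_lex <- function(a, b) {
    identical(a$clusters, b$clusters) &&
      identical(a$proper_noun_pool, b$proper_noun_pool) &&
      identical(a$intrusion_pool, b$intrusion_pool)
  }
  if (!same_lex(config_baseline, config_followup) ||
      !same_lex(config_baseline, config_reference)) {
    stop("config error: the three cohorts must share one lexicon (clusters and error pools)",
         call. = FALSE)
  }
  labels <- list(baseline = c("patient", "baseline", "P"),
                 followup = c("patient", "followup", "P"),
                 reference = c("control", "single", "C"))
  cohorts <- lapply(names(configs), function(nm) {
    cfg <- configs[[nm]]
    cfg$group <- labels[[nm]][1]
    cfg$session <- labels[[nm]][2]
    cfg$subject_prefix <- labels[[nm]][3]
    generate_cohort(cfg)
  })
  names(cohorts) <- names(configs)
  list(
    transcripts = dplyr::bind_rows(lapply(cohorts, `[[`, "transcripts")),
    ground_truth = cohorts$baseline$ground_truth,
    lexicon = cohorts$baseline$lexicon,
    configs = lapply(cohorts, `[[`, "config")
  )
}
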