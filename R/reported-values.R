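#' Published item frequencies from the motivating fluency study
#'
#' The 20 most frequent animal items produced by 335 healthy controls and by
#' 28 patients with schizophrenia at baseline and one month after
#' multi-session transcranial direct current stimulation, as printed in the
#' study this package reimplements. These counts are inputs for the
#' item-selection rules ([select_common_frequent_items()], [top_k_items()]);
#' the underlying transcripts are not publicly deposited.
#'
#' @return A tibble with columns `stratum` (`"control"`,
#'   `"patient_baseline"`, `"patient_followup"`), `rank`, `item`, `count`.
#' @examples
#' freq <- reported_item_frequencies()
#' tabs <- split(freq, freq$stratum)
#' select_common_frequent_items(tabs$patient_baseline, tabs$patient_followup,
#'                              min_freq = 10)
#' @export
reported_item_frequencies <- function() {
  control <- c(DOG = 309, CAT = 305, LION = 250, GIRAFFE = 244, TIGER = 239,
               ELEPHANT = 235, MONKEY = 234, HORSE = 171, SHEEP = 163,
               COW = 155, MOUSE = 152, RABBIT = 148, HIPPOPOTAMUS = 143,
               BEAR = 122, RHINOCEROS = 116, BIRD = 115, PANDA = 110,
               CHEETAH = 102, SNAKE = 102, ZEBRA = 102)
  baseline <- c(DOG = 24, LION = 23, CAT = 22, ELEPHANT = 21, GIRAFFE = 21,
                MOUSE = 17, TIGER = 17, HORSE = 13, MONKEY = 13, BEAR = 10,
                BIRD = 10, PANDA = 10, RABBIT = 10, RACOON_DOG = 8,
                SHEEP = 8, HAMSTER = 7, LEOPARD = 7, RHINOCEROS = 7,
                SPARROW = 7, ZEBRA = 7)
  followup <- c(CAT = 24, DOG = 24, LION = 23, ELEPHANT = 19, MONKEY = 15,
                TIGER = 15, BIRD = 13, GIRAFFE = 12, BEAR = 11, GORILLA = 11,
                MOUSE = 11, PANDA = 11, RABBIT = 11, COW = 9, SHEEP = 9,
                HIPPOPOTAMUS = 8, HORSE = 8, CHEETAH = 7, CHIMPANZEE = 7,
                RACOON_DOG = 7)
  one <- function(x, stratum) {
    tibble::tibble(stratum = stratum, rank = seq_along(x),
                   item = names(x), count = as.integer(unname(x)))
  }
  dplyr::bind_rows(one(control, "control"),
                   one(baseline, "patient_baseline"),
                   one(followup, "patient_followup"))
}

#' Published demographic and fluency summary statistics
#'
#' Group means, standard deviations and sizes for the continuous demographic
#' and category-fluency variables of the motivating study (335 healthy
#' controls vs 28 patients). Suitable inputs for the summary-statistic tests
#' [pooled_t_test()] and [welch_t_test()].
#'
#' @return A tibble with one row per variable: `variable`, `control_mean`,
#'   `control_sd`, `control_n`, `patient_mean`, `patient_sd`, `patient_n`.
#' @examples
#' demo <- reported_demographics()
#' age <- demo[demo$variable == "age", ]
#' pooled_t_test(age$control_mean, age$control_sd, age$control_n,
#'               age$patient_mean, age$patient_sd, age$patient_n)
#' @export
reported_demographics <- function() {
  tibble::tribble(
    ~variable, ~control_mean, ~control_sd, ~control_n,
    ~patient_mean, ~patient_sd, ~patient_n,
    "age", 35.8, 11.9, 335L, 40.9, 9.8, 28L,
    "education_years", 15.2, 2.2, 335L, 13.8, 1.7, 28L,
    "premorbid_iq", 109.3, 12.2, 335L, 99.6, 12.0, 28L,
    "fluency_baseline", 20.9, 4.5, 335L, 16.4, 5.1, 28L,
    "fluency_followup", 20.9, 4.5, 335L, 16.9, 5.5, 28L
  )
}

#' Published sex distribution (2x2 counts)
#'
#' Male/female counts for healthy controls (154/181) and patients (16/12),
#' suitable input for [chi_square_2x2()].
#'
#' @return A named list with `control = c(male, female)` and
#'   `patient = c(male, female)`.
#' @export
reported_sex_counts <- function() {
  list(control = c(male = 154L, female = 181L),
       patient = c(male = 16L, female = 12L))
}

#' Published cosine pair-vector correlations
#'
#' The Pearson correlations among the three inter-item cosine vectors of the
#' motivating study, over the 15 pairs of its top six items: patients'
#' baseline vs healthy reference (r_BH = 0.41), patients' follow-up vs
#' healthy reference (r_FH = 0.75), and baseline vs follow-up (the overlap
#' correlation, 0.68). These feed [meng_test()] directly when raw transcripts
#' are unavailable.
#'
#' @return A named list: `r_bh`, `r_fh`, `r_bf`, `n_items`, `n_pairs`.
#' @examples
#' rr <- reported_cosine_correlations()
#' meng_test(rr$r_bh, rr$r_fh, rr$r_bf, n = rr$n_pairs, alternative = "less")
#' @export
reported_cosine_correlations <- function() {
  list(r_bh = 0.41, r_fh = 0.75, r_bf = 0.68, n_items = 6L, n_pairs = 15L)
}
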