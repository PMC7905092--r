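#' Analyse one (group, session) stratum
#'
#' Convenience wrapper running the per-stratum chain: occurrence matrix,
#' frequency table, decomposition, dimensionality selection and cosine
#' matrix. Each stratum gets its own semantic space with its own k.
#'
#' @param cleaned A cleaned transcript tibble (all strata).
#' @param group,session Stratum labels to extract.
#' @param threshold Cumulative singular-value fraction for
#'   [select_dimensions()].
#' @return A list: `group`, `session`, `ism`, `frequencies`, `space`
#'   (reduced), `cosines`.
#' @export
analyze_stratum <- function(cleaned, group, session, threshold = 0.70) {
  sub <- dplyr::filter(cleaned, .data$group == !!group, .data$session == !!session)
  if (nrow(sub) == 0) {
    stop(sprintf("missing stratum: no transcripts for (%s, %s)", group, session),
         call. = FALSE)
  }
  ism <- build_ism(sub)
  space <- reduce_space(decompose_ism(ism), threshold = threshold)
  list(group = group, session = session, ism = ism,
       frequencies = frequency_table(ism), space = space,
       cosines = cosine_matrix(space))
}

#' Longitudinal comparison of cosine profiles within the patient group
#'
#' Selects the items frequent (`count >= min_freq`) in *both* patient
#' sessions, builds each session its own semantic space, and emits cosine
#' profiles of the most frequent focal items over the common item set for
#' baseline and follow-up — the within-group view of structure change.
#'
#' @param cleaned Cleaned transcripts containing patient baseline and
#'   follow-up strata.
#' @param min_freq Inclusive frequency threshold for the common item set
#'   (default 10).
#' @param n_focal Number of focal items profiled (default 6); ranked by the
#'   baseline frequency table restricted to the common set.
#' @param threshold Dimensionality-selection fraction (default 0.70).
#' @param group Patient group label (default `"patient"`).
#' @param sessions Baseline and follow-up session labels.
#' @return An object of class `fluency_longitudinal`: `common_items`,
#'   `focal_items`, `profiles` (tibble with `session`, `focal`, `target`,
#'   `cosine`), `frequencies`, `spaces` (per session), `params`.
#' @export
run_longitudinal <- function(cleaned, min_freq = 10, n_focal = 6,
                             threshold = 0.70, group = "patient",
                             sessions = c("baseline", "followup")) {
  strata <- lapply(sessions, function(s)
    analyze_stratum(cleaned, group, s, threshold))
  names(strata) <- sessions
  common <- select_common_frequent_items(
    lapply(strata, `[[`, "frequencies"), min_freq = min_freq)
  if (length(common) < 3) {
    stop(sprintf(
      "insufficient-items error: only %d item(s) reach frequency %d in both sessions",
      length(common), min_freq), call. = FALSE)
  }
  base_freq <- strata[[1]]$frequencies
  ranked_common <- base_freq$item[base_freq$item %in% common]
  focal <- ranked_common[seq_len(min(n_focal, length(common)))]
  profiles <- dplyr::bind_rows(lapply(sessions, function(s) {
    dplyr::bind_rows(lapply(focal, function(f)
      cosine_profile(strata[[s]]$cosines, f, common))) |>
      dplyr::mutate(session = s, .before = 1)
  }))
  structure(
    list(common_items = common, focal_items = focal, profiles = profiles,
         frequencies = lapply(strata, `[[`, "frequencies"),
         spaces = lapply(strata, `[[`, "space"),
         params = list(min_freq = min_freq, n_focal = n_focal,
                       threshold = threshold)),
    class = "fluency_longitudinal"
  )
}

#' Cross-sectional comparison against the healthy reference
#'
#' Takes the `top_k` most frequent items of the reference cohort, forms the
#' inter-item cosine pair vector over exactly those items in each of the
#' three per-stratum semantic spaces, correlates the patient vectors with
#' the reference vector (r_BH at baseline, r_FH at follow-up; r_BF is the
#' overlap correlation), and tests the r_BH vs r_FH difference with
#' [meng_test()] using the pair count as n.
#'
#' @param cleaned Cleaned transcripts with reference, baseline and follow-up
#'   strata.
#' @param top_k Number of reference items compared (default 6, giving 15
#'   pairs).
#' @param threshold Dimensionality-selection fraction.
#' @param alternative Meng alternative; the planned improvement contrast is
#'   `"less"` (r_BH < r_FH).
#' @param reference,patient Group labels.
#' @param sessions Patient baseline and follow-up session labels.
#' @param reference_session Reference session label.
#' @return An object of class `fluency_cross_sectional`: `items`,
#'   `pair_vectors` (tibble with `stratum` column), `correlations` (tibble
#'   r_BH/r_FH/r_BF), `meng` (a [meng_test()] result), `spaces`.
#' @export
run_cross_sectional <- function(cleaned, top_k = 6, threshold = 0.70,
                                alternative = "less",
                                reference = "control", patient = "patient",
                                sessions = c("baseline", "followup"),
                                reference_session = "single") {
  ref <- analyze_stratum(cleaned, reference, reference_session, threshold)
  strata <- lapply(sessions, function(s)
    analyze_stratum(cleaned, patient, s, threshold))
  names(strata) <- sessions
  items <- top_k_items(ref$frequencies, top_k)
  all_strata <- c(list(reference = ref), strata)
  for (nm in names(all_strata)) {
    absent <- setdiff(items, rownames(all_strata[[nm]]$cosines))
    if (length(absent) > 0) {
      stop(sprintf("lookup error: item(s) %s absent from stratum '%s'",
                   paste(absent, collapse = ", "), nm), call. = FALSE)
    }
  }
  pvs <- lapply(all_strata, function(st) pair_vector(st$cosines, items))
  r_bh <- correlate_pair_vectors(pvs[[sessions[1]]], pvs$reference)
  r_fh <- correlate_pair_vectors(pvs[[sessions[2]]], pvs$reference)
  r_bf <- correlate_pair_vectors(pvs[[sessions[1]]], pvs[[sessions[2]]])
  meng <- meng_test(r_bh, r_fh, r_overlap = r_bf, n = nrow(pvs$reference),
                    alternative = alternative)
  pair_tbl <- dplyr::bind_rows(lapply(names(pvs), function(nm)
    dplyr::mutate(pvs[[nm]], stratum = nm, .before = 1)))
  structure(
    list(items = items,
         pair_vectors = pair_tbl,
         correlations = tibble::tibble(
           comparison = c("r_BH", "r_FH", "r_BF"),
           r = c(r_bh, r_fh, r_bf)),
         meng = meng,
         spaces = lapply(all_strata, `[[`, "space"),
         params = list(top_k = top_k, threshold = threshold,
                       alternative = alternative)),
    class = "fluency_cross_sectional"
  )
}

#' Full fluency analysis pipeline
#'
#' Cleans the transcripts and runs every applicable analysis stage: cleaning
#' audit, per-stratum type-token ratios and frequency tables, the
#' longitudinal profile comparison (when both patient sessions are present)
#' and the cross-sectional Meng comparison (when a reference stratum is also
#' present).
#'
#' @param transcripts Long transcript tibble (see [read_transcripts()]).
#' @param lexicon A [fluency_lexicon()].
#' @param min_freq,n_focal,top_k,threshold,alternative Stage parameters; see
#'   [run_longitudinal()] and [run_cross_sectional()].
#' @return An object of class `fluency_report` bundling `audit`, `ttr`,
#'   `frequencies`, `longitudinal`, `cross_sectional` and the parameters.
#'   Supports `print()`, [generics::tidy()], [generics::glance()] and
#'   [write_report()].
#' @export
run_fluency_pipeline <- function(transcripts, lexicon, min_freq = 10,
                                 n_focal = 6, top_k = 6, threshold = 0.70,
                                 alternative = "less") {
  cleaned <- clean_transcripts(transcripts, lexicon)
  strata <- dplyr::distinct(cleaned, .data$group, .data$session)
  has <- function(g, s) any(strata$group == g & strata$session == s)
  frequencies <- lapply(seq_len(nrow(strata)), function(i) {
    frequency_table(build_ism(
      dplyr::filter(cleaned, .data$group == strata$group[i],
                    .data$session == strata$session[i])))
  })
  names(frequencies) <- paste(strata$group, strata$session, sep = "_")
  longitudinal <- if (has("patient", "baseline") && has("patient", "followup")) {
    run_longitudinal(cleaned, min_freq = min_freq, n_focal = n_focal,
                     threshold = threshold)
  }
  cross_sectional <- if (!is.null(longitudinal) && has("control", "single")) {
    run_cross_sectional(cleaned, top_k = top_k, threshold = threshold,
                        alternative = alternative)
  }
  structure(
    list(audit = cleaning_audit(cleaned),
         ttr = type_token_ratio(cleaned, by = c("group", "session")),
         frequencies = frequencies,
         longitudinal = longitudinal,
         cross_sectional = cross_sectional,
         cleaned = cleaned,
         params = list(min_freq = min_freq, n_focal = n_focal, top_k = top_k,
                       threshold = threshold, alternative = alternative)),
    class = "fluency_report"
  )
}

#' @export
print.fluency_report <- function(x, ...) {
  cat("<fluency_report>\n")
  cat("  strata:", paste(names(x$frequencies), collapse = ", "), "\n")
  if (!is.null(x$longitudinal)) {
    cat(sprintf("  longitudinal: %d common items, focal %s\n",
                length(x$longitudinal$common_items),
                paste(x$longitudinal$focal_items, collapse = ", ")))
  }
  if (!is.null(x$cross_sectional)) {
    cr <- x$cross_sectional$correlations
    cat(sprintf("  cross-sectional: r_BH = %.3f, r_FH = %.3f, r_BF = %.3f\n",
                cr$r[1], cr$r[2], cr$r[3]))
    m <- x$cross_sectional$meng
    cat(sprintf("  Meng z = %.3f, one-sided p = %.4f\n",
                m$statistic, m$p.value))
  }
  invisible(x)
}

#' @rdname tidy.meng_test
#' @method tidy fluency_report
#' @export
tidy.fluency_report <- function(x, ...) {
  if (is.null(x$cross_sectional)) {
    stop("report has no cross-sectional comparison to tidy", call. = FALSE)
  }
  x$cross_sectional$correlations
}

#' @rdname tidy.meng_test
#' @method glance fluency_report
#' @export
glance.fluency_report <- function(x, ...) {
  ks <- if (!is.null(x$cross_sectional))
    vapply(x$cross_sectional$spaces, function(s) s$k, integer(1))
  tibble::tibble(
    n_strata = length(x$frequencies),
    n_common_items = if (is.null(x$longitudinal)) NA_integer_ else
      length(x$longitudinal$common_items),
    r_bh = if (is.null(x$cross_sectional)) NA_real_ else
      x$cross_sectional$correlations$r[1],
    r_fh = if (is.null(x$cross_sectional)) NA_real_ else
      x$cross_sectional$correlations$r[2],
    r_bf = if (is.null(x$cross_sectional)) NA_real_ else
      x$cross_sectional$correlations$r[3],
    meng_z = if (is.null(x$cross_sectional)) NA_real_ else
      unname(x$cross_sectional$meng$statistic),
    meng_p = if (is.null(x$cross_sectional)) NA_real_ else
      x$cross_sectional$meng$p.value,
    k_reference = if (is.null(ks)) NA_integer_ else ks[["reference"]],
    k_baseline = if (is.null(ks)) NA_integer_ else ks[["baseline"]],
    k_followup = if (is.null(ks)) NA_integer_ else ks[["followup"]]
  )
}

report_payload <- function(report) {
  payload <- list(
    params = report$params,
    audit = report$audit,
    ttr = report$ttr,
    frequencies = report$frequencies
  )
  if (!is.null(report$longitudinal)) {
    lg <- report$longitudinal
    payload$longitudinal <- list(
      common_items = lg$common_items, focal_items = lg$focal_items,
      k = lapply(lg$spaces, `[[`, "k"), profiles = lg$profiles)
  }
  if (!is.null(report$cross_sectional)) {
    cs <- report$cross_sectional
    payload$cross_sectional <- list(
      items = cs$items, pair_vectors = cs$pair_vectors,
      correlations = cs$correlations,
      k = lapply(cs$spaces, `[[`, "k"),
      singular_value_fraction_at_k = lapply(cs$spaces, function(s)
        cumsum(s$d)[s$k] / sum(s$d)),
      meng = tidy.meng_test(cs$meng))
  }
  payload
}

#' Serialise an analysis report
#'
#' `report_json()` renders the report deterministically as JSON (identical
#' inputs and seeds give byte-identical strings); `write_report()` writes
#' `report.json` plus CSV side files for the tabular intermediates.
#'
#' @param report A `fluency_report`.
#' @return `report_json()`: a JSON string. `write_report()`: the output
#'   directory, invisibly.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(report_payload(report), digits = NA,
                                auto_unbox = TRUE, pretty = TRUE))
}

#' @param dir Output directory for `write_report()`.
#' @rdname report_json
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(report_json(report), file.path(dir, "report.json"))
  for (nm in names(report$frequencies)) {
    utils::write.csv(report$frequencies[[nm]],
                     file.path(dir, paste0("frequencies_", nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(report$longitudinal)) {
    utils::write.csv(report$longitudinal$profiles,
                     file.path(dir, "profiles.csv"), row.names = FALSE)
  }
  if (!is.null(report$cross_sectional)) {
    utils::write.csv(report$cross_sectional$pair_vectors,
                     file.path(dir, "pair_vectors.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Build the three study-design configurations
#'
#' Returns baseline / follow-up / reference [synthetic_config()]s sharing one
#' clustered vocabulary, differing in coherence and size — the synthetic
#' analogue of the study design (28 patients measured twice, 335 healthy
#' reference subjects, baseline recall less subcategory-coherent than
#' follow-up and reference).
#'
#' @param coherence Named numeric: `baseline`, `followup`, `reference`.
#' @param n_subjects Named integer cohort sizes.
#' @param n_per_cluster Items per cluster of [animal_clusters()] (default 4,
#'   i.e. a 12-item vocabulary, the size of a frequent-item set).
#' @param list_length_mean Named per-cohort mean recalled-item counts. The
#'   defaults (7 patients / 8 controls) reproduce the per-subject occurrence
#'   rates implied by published frequent-item counts at this vocabulary
#'   size.
#' @param list_length_sd Common SD of list length.
#' @param error_rates Per-token error probabilities (see
#'   [synthetic_config()]).
#' @param seed Base seed; the three cohorts use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @return Named list of three `synthetic_config`s.
#' @export
study_configs <- function(coherence = c(baseline = 0.3, followup = 0.8,
                                        reference = 0.8),
                          n_subjects = c(baseline = 28, followup = 28,
                                         reference = 335),
                          n_per_cluster = 4,
                          list_length_mean = c(baseline = 7, followup = 7,
                                               reference = 8),
                          list_length_sd = 2.5,
                          error_rates = c(repetition = 0.04, intrusion = 0.02,
                                          proper_noun = 0.01),
                          seed = 1L) {
  clusters <- animal_clusters(n_per_cluster)
  mk <- function(nm, offset) {
    synthetic_config(
      clusters = clusters, coherence = coherence[[nm]],
      list_length_mean = list_length_mean[[nm]],
      list_length_sd = list_length_sd,
      n_subjects = n_subjects[[nm]], error_rates = error_rates,
      seed = as.integer(seed) + offset)
  }
  list(baseline = mk("baseline", 0L), followup = mk("followup", 1L),
       reference = mk("reference", 2L))
}

#' Replicate the end-to-end recovery experiment
#'
#' Repeatedly generates the three-cohort design, runs the full pipeline and
#' records the recovered correlations — the package's own check that a true
#' coherence improvement (baseline below follow-up/reference) is reported as
#' r_FH > r_BH.
#'
#' @param n_replicates Number of seeded replicates.
#' @param seed Base seed; replicate i uses seeds `seed + 3 (i - 1) + (0:2)`.
#' @param swap If `TRUE`, exchange the baseline and follow-up coherence
#'   values (the recovered difference should flip sign).
#' @param ... Passed to [study_configs()] (e.g. `coherence`, `n_subjects`).
#' @param top_k,threshold Pipeline parameters.
#' @return A tibble with one row per replicate: `replicate`, `r_bh`, `r_fh`,
#'   `r_bf`, `z`, `p` (NA if a degenerate replicate could not be analysed).
#' @export
replicate_recovery <- function(n_replicates = 50, seed = 1L, swap = FALSE,
                               ..., top_k = 6, threshold = 0.70) {
  rows <- lapply(seq_len(n_replicates), function(i) {
    cfgs <- study_configs(..., seed = as.integer(seed) + 3L * (i - 1L))
    if (swap) {
      cb <- cfgs$baseline$coherence
      cfgs$baseline$coherence <- cfgs$followup$coherence
      cfgs$followup$coherence <- cb
    }
    design <- paired_cohorts(cfgs$baseline, cfgs$followup, cfgs$reference)
    res <- tryCatch({
      cleaned <- clean_transcripts(design$transcripts, design$lexicon)
      cs <- run_cross_sectional(cleaned, top_k = top_k, threshold = threshold)
      tibble::tibble(replicate = i,
                     r_bh = cs$correlations$r[1], r_fh = cs$correlations$r[2],
                     r_bf = cs$correlations$r[3],
                     z = unname(cs$meng$statistic), p = cs$meng$p.value)
    }, error = function(e) {
      tibble::tibble(replicate = i, r_bh = NA_real_, r_fh = NA_real_,
                     r_bf = NA_real_, z = NA_real_, p = NA_real_)
    })
    res
  })
  dplyr::bind_rows(rows)
}

#' Read a pipeline run configuration from YAML
#'
#' The configuration holds either an `inputs:` block (`transcripts`,
#' `lexicon` file paths) or a `synthetic:` block (arguments of
#' [study_configs()]), plus optional `selection:` (`min_freq`, `top_k`,
#' `n_focal`), `svd:` (`threshold`), `test:` (`alternative`, `alpha`),
#' `seed` and `output` entries.
#'
#' @param path YAML file path.
#' @return The configuration list (class `fluency_run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  has_inputs <- !is.null(cfg$inputs)
  has_synth <- !is.null(cfg$synthetic)
  if (has_inputs == has_synth) {
    stop("config error: exactly one of 'inputs' and 'synthetic' must be present",
         call. = FALSE)
  }
  structure(cfg, class = "fluency_run_config")
}

config_study_args <- function(cfg) {
  synth <- cfg$synthetic
  args <- list(seed = if (!is.null(cfg$seed)) cfg$seed else 1L)
  for (nm in c("coherence", "n_subjects", "n_per_cluster", "list_length_mean",
               "list_length_sd", "error_rates")) {
    if (!is.null(synth[[nm]])) args[[nm]] <- unlist(synth[[nm]])
  }
  args
}

#' Run the pipeline from a configuration
#'
#' @param config A `fluency_run_config` (or path to one).
#' @param seed Optional seed overriding the configured one (synthetic runs).
#' @return A `fluency_report`.
#' @export
run_from_config <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  params <- list(
    min_freq = config$selection$min_freq %||% 10,
    n_focal = config$selection$n_focal %||% 6,
    top_k = config$selection$top_k %||% 6,
    threshold = config$svd$threshold %||% 0.70,
    alternative = config$test$alternative %||% "less"
  )
  if (!is.null(config$synthetic)) {
    args <- config_study_args(config)
    if (!is.null(seed)) args$seed <- seed
    cfgs <- do.call(study_configs, args)
    design <- paired_cohorts(cfgs$baseline, cfgs$followup, cfgs$reference)
    transcripts <- design$transcripts
    lexicon <- design$lexicon
  } else {
    transcripts <- read_transcripts(config$inputs$transcripts)
    lexicon <- read_lexicon(config$inputs$lexicon)
  }
  do.call(run_fluency_pipeline,
          c(list(transcripts = transcripts, lexicon = lexicon), params))
}

#' Write synthetic fixture files to disk
#'
#' Materialises a synthetic study design as the standard on-disk formats —
#' `transcripts.csv`, `lexicon.csv`, `ground_truth.csv` — plus a
#' `manifest.json` recording the seeds and MD5 checksums, so a run can be
#' replayed and verified byte-for-byte.
#'
#' @param config A `fluency_run_config` with a `synthetic` block, or a list
#'   of three [synthetic_config()]s as returned by [study_configs()].
#' @param dir Output directory.
#' @return Named character vector of the files written, invisibly.
#' @export
generate_fixtures <- function(config, dir) {
  if (inherits(config, "fluency_run_config")) {
    if (is.null(config$synthetic)) {
      stop("config error: generate_fixtures() needs a 'synthetic' block",
           call. = FALSE)
    }
    config <- do.call(study_configs, config_study_args(config))
  }
  design <- paired_cohorts(config$baseline, config$followup, config$reference)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(transcripts = file.path(dir, "transcripts.csv"),
             lexicon = file.path(dir, "lexicon.csv"),
             ground_truth = file.path(dir, "ground_truth.csv"))
  utils::write.csv(design$transcripts, paths["transcripts"],
                   row.names = FALSE, quote = FALSE)
  write_lexicon(design$lexicon, paths["lexicon"])
  utils::write.csv(design$ground_truth, paths["ground_truth"],
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    seeds = lapply(design$configs, `[[`, "seed"),
    n_subjects = lapply(design$configs, `[[`, "n_subjects"),
    coherence = lapply(design$configs, `[[`, "coherence"),
    checksums = as.list(stats::setNames(unname(tools::md5sum(unname(paths))),
                                        names(paths)))
  )
  manifest_path <- file.path(dir, "manifest.json")
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           pretty = TRUE)), manifest_path)
  invisible(c(paths, manifest = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
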