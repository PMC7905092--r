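#' Plot cosine profiles across sessions
#'
#' Line plot of per-focal-item cosine profiles, one panel per session —
#' cluster-based structure shows as within-subcategory peaks.
#'
#' @param profiles Profile tibble (`session`, `focal`, `target`, `cosine`),
#'   e.g. `run_longitudinal()$profiles`.
#' @param clusters Optional named list mapping cluster labels to item
#'   vectors; when given, target labels are ordered by cluster.
#' @return A ggplot object.
#' @export
plot_cosine_profiles <- function(profiles, clusters = NULL) {
  targets <- unique(profiles$target)
  if (!is.null(clusters)) {
    ordered <- intersect(unlist(clusters, use.names = FALSE), targets)
    targets <- c(ordered, setdiff(targets, ordered))
  }
  profiles$target <- factor(profiles$target, levels = targets)
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$target, y = .data$cosine,
                               colour = .data$focal, group = .data$focal)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~session, ncol = 1) +
    ggplot2::labs(x = NULL, y = "cosine", colour = "focal item") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scree plot of a semantic space
#'
#' Singular values with the cumulative fraction of their sum; the selected k
#' (if set) is marked.
#'
#' @param object A `semantic_space`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot semantic_space
#' @export
autoplot.semantic_space <- function(object, ...) {
  tb <- tidy.semantic_space(object)
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$fraction), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative), colour = "steelblue") +
    ggplot2::labs(x = "dimension", y = "singular-value fraction") +
    ggplot2::theme_minimal()
  if (!is.null(object$k)) {
    p <- p +
      ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
      ggplot2::geom_hline(yintercept = object$threshold, linetype = "dotted")
  }
  p
}

#' Plot the longitudinal profiles of a full report
#'
#' @param object A `fluency_report` with a longitudinal component.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fluency_report
#' @export
autoplot.fluency_report <- function(object, ...) {
  if (is.null(object$longitudinal)) {
    stop("report has no longitudinal profiles to plot", call. = FALSE)
  }
  plot_cosine_profiles(object$longitudinal$profiles)
}

#' Scatter plot of two pair vectors
#'
#' Visualises the correlation underlying r_BH / r_FH: each point is one item
#' pair, with the reference cosine on the x axis.
#'
#' @param report A `fluency_report` with a cross-sectional component.
#' @return A ggplot object.
#' @export
plot_pair_correlations <- function(report) {
  cs <- report$cross_sectional
  if (is.null(cs)) stop("report has no cross-sectional comparison", call. = FALSE)
  wide <- tidyr::pivot_wider(cs$pair_vectors, names_from = "stratum",
                             values_from = "cosine")
  long <- tidyr::pivot_longer(wide, cols = c("baseline", "followup"),
                              names_to = "session", values_to = "cosine")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$reference, y = .data$cosine)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::facet_wrap(~session) +
    ggplot2::labs(x = "reference cosine", y = "patient cosine") +
    ggplot2::theme_minimal()
}
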