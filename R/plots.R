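#' Plot the grid-search objective over alpha
#'
#' Line plot of the cross-validated fitness against the number of matched
#' cell lines, with the selected (smallest maximizing) `alpha` marked.
#'
#' @param object A `ccm_alpha_search` from [optimize_alpha()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ccm_alpha_search
#' @export
autoplot.ccm_alpha_search <- function(object, ...) {
  ggplot2::ggplot(object$objective,
                  ggplot2::aes(x = .data$alpha, y = .data$fitness)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$optimal_alpha,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = expression(alpha ~ "(matched cell lines per patient)"),
      y = "mean cross-validated fitness",
      title = sprintf("Optimal alpha = %d", object$optimal_alpha)
    ) +
    ggplot2::theme_minimal()
}

#' Plot matched cell-line correlations for patients
#'
#' Shows each patient's Spearman correlation profile down the ranked list
#' of matched cell lines.
#'
#' @param matches Match tibble from [match_cell_lines()].
#' @param patients Optional subset of patient identifiers.
#' @return A ggplot object.
#' @export
plot_matches <- function(matches, patients = NULL) {
  if (!is.null(patients)) {
    matches <- matches[matches$patient_id %in% patients, ]
  }
  ggplot2::ggplot(matches,
                  ggplot2::aes(x = .data$rank, y = .data$rho,
                               group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "match rank", y = "Spearman correlation") +
    ggplot2::theme_minimal()
}

#' Plot a drug's AUC distribution with its sensitivity threshold
#'
#' Histogram of the drug's AUC values across cell lines, with the
#' interpolated percentile point `P_gamma` (dotted) and the integer
#' threshold `theta` (dashed): mean AUCs strictly left of `theta` are
#' called sensitive.
#'
#' @param auc AUC tibble.
#' @param threshold One-row threshold tibble from [compute_threshold()].
#' @return A ggplot object.
#' @export
plot_auc_threshold <- function(auc, threshold) {
  stopifnot(nrow(threshold) == 1)
  d <- threshold$drug_id
  df <- tibble::tibble(auc = auc[[d]][!is.na(auc[[d]])])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0,
                            fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = threshold$p_gamma, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = threshold$theta, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "AUC", y = "cell lines",
                  title = sprintf("%s: P_gamma = %.2f, theta = %d",
                                  d, threshold$p_gamma, threshold$theta)) +
    ggplot2::theme_minimal()
}

#' Plot a recommendation list
#'
#' Mean AUC of the recommended drugs for one patient, grouped by category
#' and coloured by predicted response.
#'
#' @param recommendations Tibble from [recommend_drugs()].
#' @param patient Patient identifier (defaults to the first present).
#' @return A ggplot object.
#' @export
plot_recommendations <- function(recommendations,
                                 patient = recommendations$patient_id[1]) {
  df <- recommendations[recommendations$patient_id == patient, ]
  df$category <- factor(df$category, levels = drug_categories)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mean_auc,
    y = stats::reorder(.data$drug_id, -.data$mean_auc),
    fill = .data$predicted_responsive)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$category),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "mean AUC across matched cell lines", y = NULL,
                  fill = "predicted\nresponsive", title = patient) +
    ggplot2::theme_minimal()
}
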