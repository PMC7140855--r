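#' Spearman correlation between two rank vectors
#'
#' Applies the Pearson product-moment formula to two vectors of per-sample
#' gene ranks, which is the Spearman rank correlation of the underlying
#' profiles. Both vectors must cover the same genes in the same order.
#'
#' @param p_ranks,cl_ranks Numeric rank vectors of equal length (>= 3).
#' @return A correlation in `[-1, 1]`.
#' @examples
#' spearman_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
#' @export
spearman_correlation <- function(p_ranks, cl_ranks) {
  if (length(p_ranks) != length(cl_ranks)) {
    abort("rank vectors differ in length")
  }
  if (length(p_ranks) < 3) abort("need at least 3 genes")
  if (stats::sd(p_ranks) == 0 || stats::sd(cl_ranks) == 0) {
    abort("undefined correlation: a rank vector has zero variance (all ties)")
  }
  cor(p_ranks, cl_ranks)
}

#' Match patients to their most similar cell lines
#'
#' The first layer of the decision system: every patient profile is
#' correlated (Spearman, over the entire shared gene set, no feature
#' selection) against every cell line of the panel, and the top `alpha`
#' cell lines are returned per patient, sorted by decreasing correlation
#' with ties broken lexicographically by cell-line identifier so the
#' ordering is deterministic.
#'
#' Inputs that are not yet rank-normalized are ranked internally, making
#' the matching invariant under any strictly monotone transform of the raw
#' expression. Cell lines whose profile has zero rank variance (constant
#' expression) have no defined correlation and are skipped with a warning.
#'
#' @param patients Expression tibble of patient profiles (one column per
#'   patient), gene-aligned with `panel` (see [harmonize_genes()]).
#' @param panel Expression tibble of cell-line profiles.
#' @param alpha Number of cell lines to retain per patient; capped at the
#'   panel size.
#' @return A tibble with columns `patient_id`, `rank` (1 = most similar),
#'   `cell_line` and `rho`.
#' @export
match_cell_lines <- function(patients, panel, alpha) {
  patients <- as_expression(patients, ranked = is_ranked(patients))
  panel <- as_expression(panel, ranked = is_ranked(panel))
  if (alpha < 1) abort("alpha must be >= 1")
  if (!identical(patients$gene, panel$gene)) {
    abort("patients and panel must share an identical gene order; harmonize first")
  }
  if (!is_ranked(patients)) patients <- rank_normalize(patients)
  if (!is_ranked(panel)) panel <- rank_normalize(panel)

  pm <- expr_matrix(patients)
  cm <- expr_matrix(panel)
  keep <- apply(cm, 2, stats::sd) > 0
  if (any(!keep)) {
    warn(sprintf("skipping zero-variance cell line(s): %s",
                 paste(colnames(cm)[!keep], collapse = ", ")))
    cm <- cm[, keep, drop = FALSE]
  }
  if (ncol(cm) == 0) abort("no cell line has a defined correlation")
  p_ok <- apply(pm, 2, stats::sd) > 0
  if (any(!p_ok)) {
    abort(sprintf("patient profile(s) with zero rank variance: %s",
                  paste(colnames(pm)[!p_ok], collapse = ", ")))
  }

  rho <- cor(pm, cm)                      # patients x cell lines, Pearson on ranks
  alpha_eff <- min(as.integer(alpha), ncol(cm))
  purrr::map_dfr(rownames(rho), function(p) {
    r <- rho[p, ]
    ord <- order(-r, colnames(cm))
    top <- ord[seq_len(alpha_eff)]
    tibble::tibble(
      patient_id = p,
      rank = seq_len(alpha_eff),
      cell_line = colnames(cm)[top],
      rho = unname(r[top])
    )
  })
}
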