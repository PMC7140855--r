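#' Response rate of a drug from the knowledge base
#'
#' The knowledge base records, per drug, how many patients were treated and
#' how many responded; the response rate `gamma` is their ratio. Drugs with
#' no prior clinical information fall back to `gamma_default` (0.5: about
#' half of patients are assumed to respond).
#'
#' @param kb Data frame with columns `drug_id`, `n_patients`, `n_responders`.
#' @param drug_id Drug identifier.
#' @param gamma_default Rate used when the drug is absent from `kb`.
#' @return The response rate in `[0, 1]`.
#' @examples
#' kb <- tibble::tibble(drug_id = "lapatinib", n_patients = 31, n_responders = 8)
#' compute_gamma(kb, "lapatinib")
#' compute_gamma(kb, "novel-compound")
#' @export
compute_gamma <- function(kb, drug_id, gamma_default = 0.5) {
  row <- kb[kb$drug_id == drug_id, ]
  if (nrow(row) == 0) return(gamma_default)
  if (nrow(row) > 1) abort(sprintf("duplicated KB entry for '%s'", drug_id))
  if (row$n_patients == 0) {
    abort(sprintf("KB entry for '%s' has zero treated patients", drug_id))
  }
  if (row$n_responders < 0 || row$n_responders > row$n_patients) {
    abort(sprintf("KB counts for '%s' are inconsistent", drug_id))
  }
  row$n_responders / row$n_patients
}

#' Cell-line list over which a drug's AUC distribution is taken
#'
#' For a drug with prior clinical information, the matched cell lines of
#' all patients treated with it are pooled into a single de-duplicated
#' list, in order of first appearance. For a drug outside the knowledge
#' base the full panel is used.
#'
#' @param matches Match tibble from [match_cell_lines()] covering the
#'   treated patients.
#' @param kb Knowledge base (see [compute_gamma()]).
#' @param drug_id Drug identifier.
#' @param panel_cell_lines Character vector of all panel cell lines.
#' @param records Clinical records (`patient_id`, `drug_id`, `response`)
#'   identifying which patients were treated with each KB drug; required
#'   for KB drugs.
#' @return Character vector of cell-line identifiers.
#' @export
build_cell_list <- function(matches, kb, drug_id, panel_cell_lines,
                            records = NULL) {
  if (!drug_id %in% kb$drug_id) {
    return(panel_cell_lines)
  }
  if (is.null(records)) {
    abort(sprintf("clinical records are needed to locate patients treated with '%s'",
                  drug_id))
  }
  treated <- unique(records$patient_id[records$drug_id == drug_id])
  sub <- matches[matches$patient_id %in% treated, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(sprintf("no matched cell lines for any patient treated with '%s'",
                  drug_id))
  }
  sub <- sub[order(match(sub$patient_id, treated), sub$rank), ]
  unique(sub$cell_line)
}

#' Grouped-percentile point of an AUC distribution
#'
#' Builds a histogram of the values with bins of width `bin_width` anchored
#' at integer multiples of `bin_width`, locates the bin containing the
#' `ceiling(gamma * n)`-th smallest value, and interpolates within it:
#' `P = phi + (gamma * n - cf) / f * bin_width`, where `phi` is the bin's
#' lower limit, `cf` the cumulative frequency below it and `f` its
#' frequency. With unit bins the bin-width factor drops out and the
#' classical grouped-data percentile formula is recovered exactly.
#'
#' @param auc_values Non-empty numeric vector (no missing values).
#' @param gamma Percentile fraction in `[0, 1]`; `gamma * n = 0` returns the
#'   lower limit of the first occupied bin.
#' @param bin_width Histogram bin width (> 0).
#' @return The percentile point, in AUC units.
#' @examples
#' percentile_point(rep(3.2, 10), gamma = 0.5)  # 3 + 5/10 = 3.5
#' @export
percentile_point <- function(auc_values, gamma, bin_width = 1) {
  if (length(auc_values) == 0) abort("auc_values is empty")
  if (anyNA(auc_values)) abort("auc_values contains missing values")
  if (gamma < 0 || gamma > 1) abort("gamma must be in [0, 1]")
  if (bin_width <= 0) abort("bin_width must be positive")
  n <- length(auc_values)
  bins <- floor(auc_values / bin_width)
  gn <- gamma * n
  if (gn == 0) {
    return(min(bins) * bin_width)
  }
  v <- sort(auc_values)[ceiling(gn)]
  k <- floor(v / bin_width)
  phi <- k * bin_width
  cf <- sum(bins < k)
  f <- sum(bins == k)
  phi + (gn - cf) / f * bin_width
}

#' Sensitivity threshold for one drug
#'
#' The drug's AUC values across the cell-line list `L` are reduced to the
#' grouped `gamma`-percentile point `P_gamma` (see [percentile_point()]);
#' the threshold `theta` is its ceiling. A cell line (or a patient's
#' averaged AUC) with mean AUC strictly below `theta` is called sensitive.
#'
#' @param auc AUC tibble: column `cell_line` plus one numeric column per
#'   drug; missing entries allowed.
#' @param drug_id Drug identifier (a column of `auc`).
#' @param cells Cell-line list `L` (see [build_cell_list()]).
#' @param gamma Response rate for the drug.
#' @param bin_width Histogram bin width.
#' @return One-row tibble: `drug_id`, `gamma`, `p_gamma`, `theta`,
#'   `n_cells` (cells of `L` with a measured AUC).
#' @export
compute_threshold <- function(auc, drug_id, cells, gamma, bin_width = 1) {
  if (!drug_id %in% names(auc)) {
    abort(sprintf("drug '%s' is not a column of the AUC table", drug_id))
  }
  vals <- auc[[drug_id]][match(cells, auc$cell_line)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    abort(sprintf("no AUC data for drug '%s' on the supplied cell list", drug_id))
  }
  p <- percentile_point(vals, gamma, bin_width)
  tibble::tibble(
    drug_id = drug_id, gamma = gamma,
    p_gamma = p, theta = ceiling(p), n_cells = length(vals)
  )
}

#' Sensitivity thresholds for every drug of an AUC table
#'
#' Convenience wrapper applying [compute_gamma()], [build_cell_list()] and
#' [compute_threshold()] to each drug column. Drugs without any AUC value
#' on their cell list are dropped with a warning.
#'
#' @inheritParams build_cell_list
#' @inheritParams compute_threshold
#' @param gamma_default Response rate for drugs absent from `kb`.
#' @return Tibble with one row per drug (see [compute_threshold()]).
#' @export
compute_thresholds <- function(auc, kb, matches = NULL, records = NULL,
                               gamma_default = 0.5, bin_width = 1) {
  drugs <- setdiff(names(auc), "cell_line")
  purrr::map_dfr(drugs, function(d) {
    gamma <- compute_gamma(kb, d, gamma_default)
    cells <- build_cell_list(matches, kb, d, auc$cell_line, records)
    tryCatch(
      compute_threshold(auc, d, cells, gamma, bin_width),
      error = function(e) {
        warn(sprintf("dropping drug '%s': %s", d, conditionMessage(e)))
        NULL
      }
    )
  })
}
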