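drug_categories <- c("fda", "clinical", "preclinical", "other")

#' Average AUC of a drug across a patient's matched cell lines
#'
#' Missing screening entries are removed: the mean is taken over however
#' many of the matched cell lines carry a measured AUC for the drug
#' (`freq`). A drug measured on none of them has `freq = 0` and `mean_auc
#' = NA`; such drugs are excluded from recommendations.
#'
#' @param auc AUC tibble (`cell_line` column plus one column per drug).
#' @param match Match tibble for a single patient ([match_cell_lines()]).
#' @param drug_id Drug identifier.
#' @return One-row tibble: `drug_id`, `mean_auc`, `freq`.
#' @export
average_auc <- function(auc, match, drug_id) {
  if (nrow(match) == 0) abort("match list is empty")
  if (!drug_id %in% names(auc)) {
    abort(sprintf("drug '%s' is not a column of the AUC table", drug_id))
  }
  vals <- auc[[drug_id]][match(match$cell_line, auc$cell_line)]
  vals <- vals[!is.na(vals)]
  tibble::tibble(
    drug_id = drug_id,
    mean_auc = if (length(vals)) mean(vals) else NA_real_,
    freq = length(vals)
  )
}

#' Ranked, categorized drug recommendations for matched patients
#'
#' The second layer of the decision system. For every patient, each drug's
#' AUC values across the patient's matched cell lines are averaged
#' (missing entries removed); drugs with no measured value are excluded.
#' A drug is predicted responsive when its mean AUC is *strictly* below
#' its sensitivity threshold `theta` (equality is non-responsive). Within
#' each annotation category — FDA approved, clinical, preclinical, other —
#' drugs are ranked by ascending mean AUC (most sensitive first), with
#' ties broken by drug identifier; categories are emitted in that fixed
#' order. Drugs lacking an annotation are placed in `other` with a warning.
#'
#' @param matches Match tibble from [match_cell_lines()] (one or more
#'   patients).
#' @param auc AUC tibble.
#' @param thresholds Threshold tibble from [compute_thresholds()].
#' @param annotations Optional data frame (`drug_id`, `category` with
#'   category in `fda`, `clinical`, `preclinical`, `other`).
#' @return Tibble with columns `patient_id`, `category`, `rank`, `drug_id`,
#'   `mean_auc`, `freq`, `predicted_responsive`, `theta`.
#' @export
recommend_drugs <- function(matches, auc, thresholds, annotations = NULL) {
  drugs <- thresholds$drug_id
  cats <- categorize_drugs(drugs, annotations)

  per_patient <- function(pid) {
    match <- matches[matches$patient_id == pid, ]
    res <- purrr::map_dfr(drugs, average_auc, auc = auc, match = match)
    res <- dplyr::filter(res, .data$freq > 0)
    res |>
      dplyr::left_join(thresholds[c("drug_id", "theta")], by = "drug_id") |>
      dplyr::mutate(
        patient_id = pid,
        predicted_responsive = .data$mean_auc < .data$theta,
        category = cats[.data$drug_id]
      )
  }

  out <- purrr::map_dfr(unique(matches$patient_id), per_patient)
  out |>
    dplyr::mutate(category = factor(.data$category, levels = drug_categories)) |>
    dplyr::arrange(.data$patient_id, .data$category, .data$mean_auc,
                   .data$drug_id) |>
    dplyr::group_by(.data$patient_id, .data$category) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(category = as.character(.data$category)) |>
    dplyr::select("patient_id", "category", "rank", "drug_id", "mean_auc",
                  "freq", "predicted_responsive", "theta")
}

categorize_drugs <- function(drugs, annotations) {
  cats <- rep("other", length(drugs))
  names(cats) <- drugs
  if (!is.null(annotations)) {
    annotations <- tibble::as_tibble(annotations)
    stopifnot(all(c("drug_id", "category") %in% names(annotations)))
    bad <- setdiff(unique(annotations$category), drug_categories)
    if (length(bad)) {
      abort(sprintf("unknown drug category label(s): %s",
                    paste(bad, collapse = ", ")))
    }
    hit <- match(drugs, annotations$drug_id)
    cats[!is.na(hit)] <- annotations$category[hit[!is.na(hit)]]
    unannotated <- drugs[is.na(hit)]
    if (length(unannotated)) {
      warn(sprintf("drug(s) without category annotation assigned 'other': %s",
                   paste(unannotated, collapse = ", ")))
    }
  }
  cats
}
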