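#' Confusion matrix of predicted vs. recorded drug response
#'
#' Tallies, for one drug, the four cells of the 2x2 contingency table
#' between the model's predicted response status and the recorded clinical
#' response: `a` (predicted and recorded responsive), `b` (predicted
#' responsive, recorded non-responsive), `c` (predicted non-responsive,
#' recorded responsive) and `d` (both non-responsive).
#'
#' @param predictions Data frame with columns `patient_id` and
#'   `predicted_responsive` (logical), one row per patient.
#' @param records Data frame with columns `patient_id` and `response`
#'   (`"responder"` / `"non_responder"`); every recorded patient must have
#'   a prediction.
#' @return A `ccm_confusion` object (fields `a`, `b`, `c`, `d`).
#' @seealso [new_confusion()] to build one directly from counts.
#' @export
build_confusion <- function(predictions, records) {
  stopifnot(all(c("patient_id", "predicted_responsive") %in% names(predictions)),
            all(c("patient_id", "response") %in% names(records)))
  bad <- setdiff(unique(records$response), c("responder", "non_responder"))
  if (length(bad)) {
    abort(sprintf("unknown response label(s): %s", paste(bad, collapse = ", ")))
  }
  miss <- setdiff(records$patient_id, predictions$patient_id)
  if (length(miss)) {
    abort(sprintf("no prediction for patient(s): %s",
                  paste(miss, collapse = ", ")))
  }
  pred <- predictions$predicted_responsive[
    match(records$patient_id, predictions$patient_id)]
  rec <- records$response == "responder"
  new_confusion(
    a = sum(pred & rec), b = sum(pred & !rec),
    c = sum(!pred & rec), d = sum(!pred & !rec)
  )
}

#' @rdname build_confusion
#' @param a,b,c,d Non-negative integer counts.
#' @export
new_confusion <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "ccm_confusion")
}

#' @export
print.ccm_confusion <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(predicted = c("response", "non_response"),
                              recorded = c("response", "non_response")))
  cat("<ccm_confusion>  accordance:", format(accordance(x), digits = 4), "\n")
  print(m)
  invisible(x)
}

#' @export
as.matrix.ccm_confusion <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), 2, 2,
         dimnames = list(predicted = c("response", "non_response"),
                         recorded = c("response", "non_response")))
}

#' Accordance of predicted and recorded drug response
#'
#' The fraction of patients whose predicted response status matches the
#' recorded clinical response: `(a + d) / (a + b + c + d)` — the accuracy
#' of the 2x2 confusion table. In the canonical worked scenario (20
#' treated patients; 15 correctly predicted responsive, 2 correctly
#' non-responsive, 3 incorrectly responsive) the accordance is
#' `(15 + 2) / 20 = 0.85`.
#'
#' @param cm A `ccm_confusion` object with at least one counted patient.
#' @return Accordance on the `[0, 1]` scale.
#' @examples
#' accordance(new_confusion(a = 15, b = 3, c = 0, d = 2))
#' @export
accordance <- function(cm) {
  stopifnot(inherits(cm, "ccm_confusion"))
  total <- cm$a + cm$b + cm$c + cm$d
  if (total < 1) abort("confusion matrix is empty")
  (cm$a + cm$d) / total
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value obtained by summing, over all tables with the
#' observed margins, the hypergeometric probabilities of tables at most as
#' probable as the observed one. A table with a zero margin carries no
#' information about association and returns `p = 1`.
#'
#' @param x A `ccm_confusion` object or a 2x2 matrix of non-negative
#'   integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2))
#' @export
fisher_exact <- function(x) {
  if (inherits(x, "ccm_confusion")) x <- as.matrix(x)
  stopifnot(is.matrix(x), identical(dim(x), c(2L, 2L)),
            all(x >= 0), all(x == round(x)))
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) return(1)
  fisher.test(x)$p.value
}

#' Per-drug accordance report
#'
#' Joins per-patient predictions with recorded clinical responses, builds
#' a confusion matrix per drug, and reports its accordance and the
#' two-sided Fisher exact p-value of the predicted-vs-recorded association.
#'
#' @param predictions Data frame with columns `patient_id`, `drug_id`,
#'   `predicted_responsive` (e.g. [recommend_drugs()] output).
#' @param records Clinical records (`patient_id`, `drug_id`, `response`).
#' @return Tibble with one row per drug: `drug_id`, `a`, `b`, `c`, `d`,
#'   `accordance`, `fisher_p`; mean accordance across drugs is available
#'   via `mean(out$accordance)`.
#' @export
evaluate_accordance <- function(predictions, records) {
  purrr::map_dfr(unique(records$drug_id), function(d) {
    rec <- records[records$drug_id == d, ]
    prd <- predictions[predictions$drug_id == d, ]
    cm <- build_confusion(prd, rec)
    tibble::tibble(
      drug_id = d, a = cm$a, b = cm$b, c = cm$c, d = cm$d,
      accordance = accordance(cm), fisher_p = fisher_exact(cm)
    )
  })
}

#' Fitness of an alpha setting for one drug
#'
#' The objective that the grid search maximizes, per drug: the grand mean
#' of the `alpha * n_patients` patient-to-cell-line Spearman correlations
#' of the matched lists, plus the accordance (on the `[0, 1]` scale, so
#' both summands are commensurable). Larger correlations mean the matched
#' cell lines model the tumors faithfully; larger accordance means the
#' recommendations agree with observed clinical response.
#'
#' @param matches Match tibble covering the drug's treated patients, each
#'   with exactly `alpha` entries.
#' @param ac Accordance in `[0, 1]`.
#' @param alpha The number of matched cell lines per patient.
#' @return The fitness value `F`.
#' @examples
#' m <- tibble::tibble(patient_id = "p1", rank = 1:2,
#'                     cell_line = c("A", "B"), rho = c(0.8, 0.6))
#' fitness(m, ac = 1, alpha = 2)  # 0.7 + 1
#' @export
fitness <- function(matches, ac, alpha) {
  stopifnot(ac >= 0, ac <= 1)
  n_per <- table(matches$patient_id)
  if (any(n_per != alpha)) {
    abort(sprintf("every patient must have exactly alpha = %d matched cell lines",
                  alpha))
  }
  mean(matches$rho) + ac
}
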