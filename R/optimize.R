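#' Cross-validated grid search for the number of matched cell lines
#'
#' Scans every value of `alpha` in `alpha_range` and, for each drug of the
#' knowledge base, evaluates the fitness (mean matched correlation plus
#' accordance, see [fitness()]) under k-fold cross-validation: the treated
#' patients of each drug are split into folds by a seeded shuffle
#' stratified by recorded response; sensitivity thresholds are learned on
#' the training folds (their matched cell lines form the list `L`, and the
#' response rate `gamma` is the training-fold responder fraction, keeping
#' the threshold free of held-out information) and
#' accordance is scored on the held-out fold. The objective is the
#' unweighted mean over drugs of the mean per-fold fitness, and the
#' *smallest* `alpha` attaining the maximal objective is returned, keeping
#' the matched-cell-line list as short as possible.
#'
#' Because the correlation ranking of cell lines for a patient does not
#' depend on `alpha`, the full ordering is computed once and each `alpha`
#' re-uses its prefix. `alpha` values exceeding the panel size are
#' evaluated at the panel size.
#'
#' @param panel Cell-line expression tibble.
#' @param patients Patient expression tibble, gene-aligned with `panel`.
#' @param auc AUC tibble (`cell_line` plus one column per drug).
#' @param kb Knowledge base (`drug_id`, `n_patients`, `n_responders`).
#' @param records Clinical records (`patient_id`, `drug_id`, `response`).
#' @param alpha_range Inclusive integer bounds of the search grid.
#' @param folds Cross-validation folds; reduced to the cohort size for
#'   drugs with fewer treated patients (leave-one-out floor).
#' @param bin_width AUC histogram bin width.
#' @param seed Integer seed for the fold shuffle.
#' @return A `ccm_alpha_search` object; see [tidy.ccm_alpha_search()],
#'   [glance.ccm_alpha_search()] and [autoplot.ccm_alpha_search()].
#' @export
optimize_alpha <- function(panel, patients, auc, kb, records,
                           alpha_range = c(1L, 61L), folds = 10L,
                           bin_width = 1, seed = 1L) {
  drugs <- intersect(kb$drug_id, unique(records$drug_id))
  if (nrow(kb) == 0 || length(drugs) == 0) {
    abort("knowledge base is empty (no KB drug has clinical records)")
  }
  pat_ids <- sample_ids(patients)
  records <- records[records$patient_id %in% pat_ids, ]

  full <- match_cell_lines(patients, panel, alpha = .Machine$integer.max)
  cells_by_pat <- split(full$cell_line, full$patient_id)
  rho_by_pat <- split(full$rho, full$patient_id)
  n_panel <- length(cells_by_pat[[1]])

  am <- as.matrix(auc[setdiff(names(auc), "cell_line")])
  rownames(am) <- auc$cell_line

  # seeded, response-stratified fold assignment per drug (round robin)
  fold_of <- withr::with_seed(seed, {
    out <- list()
    for (d in sort(drugs)) {
      rec <- records[records$drug_id == d, ]
      k <- min(folds, nrow(rec))
      f <- integer(nrow(rec))
      for (grp in split(seq_len(nrow(rec)), rec$response)) {
        f[sample(grp)] <- (seq_along(grp) - 1L) %% k + 1L
      }
      out[[d]] <- stats::setNames(f, rec$patient_id)
    }
    out
  })

  alphas <- seq(alpha_range[1], alpha_range[2])
  per_drug <- purrr::map_dfr(alphas, function(alpha) {
    a_eff <- min(alpha, n_panel)
    purrr::map_dfr(sort(drugs), function(d) {
      rec <- records[records$drug_id == d, ]
      fold_id <- fold_of[[d]][rec$patient_id]
      fold_stats <- purrr::map_dfr(sort(unique(fold_id)), function(f) {
        test <- rec[fold_id == f, ]
        train <- rec$patient_id[fold_id != f]
        if (length(train) == 0) train <- test$patient_id  # degenerate 1-fold
        gamma <- mean(rec$response[rec$patient_id %in% train] == "responder")
        L <- unique(unlist(lapply(cells_by_pat[train],
                                  function(x) x[seq_len(a_eff)]),
                           use.names = FALSE))
        thr <- compute_threshold(auc, d, L, gamma, bin_width)
        pred_mean <- vapply(test$patient_id, function(p) {
          v <- am[cells_by_pat[[p]][seq_len(a_eff)], d]
          v <- v[!is.na(v)]
          if (length(v)) mean(v) else NA_real_
        }, numeric(1))
        has_pred <- !is.na(pred_mean)
        if (!all(has_pred)) {
          warn(sprintf("drug '%s': %d held-out patient(s) without AUC coverage excluded",
                       d, sum(!has_pred)))
        }
        cm <- build_confusion(
          tibble::tibble(patient_id = test$patient_id[has_pred],
                         predicted_responsive = pred_mean[has_pred] < thr$theta),
          test[has_pred, ]
        )
        rho_test <- unlist(lapply(rho_by_pat[test$patient_id],
                                  function(x) x[seq_len(a_eff)]),
                           use.names = FALSE)
        tibble::tibble(fold = f, accordance = accordance(cm),
                       mean_rho = mean(rho_test),
                       fitness = mean(rho_test) + accordance(cm))
      })
      tibble::tibble(
        alpha = alpha, drug_id = d,
        cv_fitness = mean(fold_stats$fitness),
        cv_accordance = mean(fold_stats$accordance),
        cv_rho = mean(fold_stats$mean_rho),
        n_folds = nrow(fold_stats)
      )
    })
  })

  objective <- per_drug |>
    dplyr::group_by(.data$alpha) |>
    dplyr::summarise(fitness = mean(.data$cv_fitness), .groups = "drop")
  best <- objective$alpha[objective$fitness == max(objective$fitness)]

  structure(
    list(
      optimal_alpha = min(best),
      objective = objective,
      per_drug = per_drug,
      alpha_range = as.integer(alpha_range),
      folds = as.integer(folds),
      bin_width = bin_width,
      seed = as.integer(seed)
    ),
    class = "ccm_alpha_search"
  )
}

#' @export
print.ccm_alpha_search <- function(x, ...) {
  cat("<ccm_alpha_search>\n")
  cat(sprintf("  alpha grid     : [%d, %d]\n", x$alpha_range[1], x$alpha_range[2]))
  cat(sprintf("  folds          : %d  (seed %d)\n", x$folds, x$seed))
  cat(sprintf("  optimal alpha  : %d\n", x$optimal_alpha))
  cat(sprintf("  max fitness    : %.4f\n", max(x$objective$fitness)))
  invisible(x)
}

#' Tidy the per-drug grid-search trace
#'
#' @param x A `ccm_alpha_search` object.
#' @param ... Unused.
#' @return Tibble with one row per (`alpha`, `drug_id`): `cv_fitness`,
#'   `cv_accordance`, `cv_rho`, `n_folds`.
#' @method tidy ccm_alpha_search
#' @export
tidy.ccm_alpha_search <- function(x, ...) x$per_drug

#' One-row summary of an alpha grid search
#'
#' @param x A `ccm_alpha_search` object.
#' @param ... Unused.
#' @return Tibble: `optimal_alpha`, `max_fitness`, `n_drugs`, `folds`, `seed`.
#' @method glance ccm_alpha_search
#' @export
glance.ccm_alpha_search <- function(x, ...) {
  tibble::tibble(
    optimal_alpha = x$optimal_alpha,
    max_fitness = max(x$objective$fitness),
    n_drugs = length(unique(x$per_drug$drug_id)),
    folds = x$folds,
    seed = x$seed
  )
}
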