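#' Configuration of the synthetic cohort generator
#'
#' Describes a fully synthetic benchmark emulating the structure of the
#' real inputs: a cell-line panel with cluster structure (in the spirit of
#' lineage groups in large panels), patients generated as noisy copies of
#' designated cell lines, a drug-screening AUC table with planted low-AUC
#' (sensitive) drugs per cluster, binary clinical response records
#' consistent with the planted sensitivity, and a knowledge base tallied
#' from those records.
#'
#' Expression is generated on the log2 scale (cluster archetype +
#' within-cluster deviation) and exponentiated, so values stay positive
#' and noise perturbs ranks in an interpretable way. AUC values are drawn
#' around `sensitive_auc_mean` for planted (cluster, drug) pairs and
#' `resistant_auc_mean` otherwise, truncated at zero; the defaults (5 vs.
#' 12, sd 0.5) mimic the low-vs-high separation of dose-response AUCs on
#' a 0-30 scale. Per-drug response rates are not set directly: they emerge
#' from which clusters a drug is planted sensitive in and how many
#' patients sit in those clusters, and the knowledge base is tallied from
#' the generated records so its rates always equal the empirical responder
#' fractions.
#'
#' @param n_genes,n_cell_lines,n_patients,n_drugs Problem dimensions.
#' @param n_clusters Number of cell-line clusters (archetypes).
#' @param noise_sd Patient expression noise, sd on the log2 scale.
#' @param sensitive_auc_mean,resistant_auc_mean Mean AUC of planted
#'   sensitive vs. resistant (cluster, drug) pairs; sensitive < resistant.
#' @param auc_sd AUC noise sd.
#' @param missing_rate Fraction of AUC entries masked as missing.
#' @param label_noise Probability that a clinical response label is flipped.
#' @param n_kb_drugs Number of drugs with planted sensitivity and clinical
#'   records (assigned to clusters round-robin).
#' @param seed Integer seed; all generators are bit-reproducible under it.
#' @return A named list of class `ccm_sim_config`.
#' @export
sim_config <- function(n_genes = 500L, n_cell_lines = 60L, n_patients = 40L,
                       n_drugs = 30L, n_clusters = 4L, noise_sd = 0.3,
                       sensitive_auc_mean = 5, resistant_auc_mean = 12,
                       auc_sd = 0.5, missing_rate = 0.05, label_noise = 0,
                       n_kb_drugs = n_clusters, seed = 1L) {
  stopifnot(
    n_genes >= 3, n_cell_lines >= 1, n_patients >= 1, n_drugs >= 1,
    n_clusters >= 1, n_clusters <= n_cell_lines, noise_sd >= 0,
    sensitive_auc_mean < resistant_auc_mean, sensitive_auc_mean >= 0,
    auc_sd >= 0, missing_rate >= 0, missing_rate <= 1,
    label_noise >= 0, label_noise <= 1, n_kb_drugs <= n_drugs
  )
  structure(
    list(n_genes = as.integer(n_genes),
         n_cell_lines = as.integer(n_cell_lines),
         n_patients = as.integer(n_patients),
         n_drugs = as.integer(n_drugs),
         n_clusters = as.integer(n_clusters),
         noise_sd = noise_sd,
         sensitive_auc_mean = sensitive_auc_mean,
         resistant_auc_mean = resistant_auc_mean,
         auc_sd = auc_sd,
         missing_rate = missing_rate,
         label_noise = label_noise,
         n_kb_drugs = as.integer(n_kb_drugs),
         seed = as.integer(seed)),
    class = "ccm_sim_config"
  )
}

sim_cluster_of_cell <- function(config) {
  (seq_len(config$n_cell_lines) - 1L) %% config$n_clusters + 1L
}

#' Generate a synthetic cell-line expression panel
#'
#' Cell lines are drawn from `n_clusters` archetypes: on the log2 scale,
#' each archetype is a Normal(6, 2) gene profile and each cell line adds a
#' Normal(0, 0.4) within-cluster deviation; values are exponentiated to
#' positive, log-normal-like intensities. Cluster membership is assigned
#' round-robin and stored in the `clusters` attribute (a tibble with
#' columns `cell_line`, `cluster`).
#'
#' @param config A [sim_config()] object.
#' @return An unranked expression tibble with a `clusters` attribute.
#' @export
simulate_panel <- function(config) {
  cluster <- sim_cluster_of_cell(config)
  out <- withr::with_seed(config$seed, {
    arch <- matrix(rnorm(config$n_genes * config$n_clusters, mean = 6, sd = 2),
                   config$n_genes, config$n_clusters)
    dev <- matrix(rnorm(config$n_genes * config$n_cell_lines, sd = 0.4),
                  config$n_genes, config$n_cell_lines)
    2^(arch[, cluster, drop = FALSE] + dev)
  })
  colnames(out) <- sprintf("CL%03d", seq_len(config$n_cell_lines))
  rownames(out) <- sprintf("G%04d", seq_len(config$n_genes))
  expr <- matrix_expr(out, ranked = FALSE)
  attr(expr, "clusters") <- tibble::tibble(
    cell_line = colnames(out), cluster = cluster
  )
  expr
}

#' Generate synthetic patients as noisy copies of cell lines
#'
#' Each patient is a designated cell line's profile perturbed by
#' independent Normal(0, `noise_sd`) noise on the log2 scale; with
#' `noise_sd = 0` the patient columns are exact copies. The generating
#' cell line of each patient is stored in the `assignment` attribute
#' (tibble `patient_id`, `cell_line`).
#'
#' @param config A [sim_config()] object.
#' @param panel Panel from [simulate_panel()].
#' @param assignment Optional character vector of panel cell lines, one
#'   per patient; defaults to a round-robin assignment.
#' @return An unranked expression tibble with an `assignment` attribute.
#' @export
simulate_patients <- function(config, panel, assignment = NULL) {
  cl_ids <- sample_ids(panel)
  if (is.null(assignment)) {
    assignment <- cl_ids[(seq_len(config$n_patients) - 1L) %% length(cl_ids) + 1L]
  }
  if (!all(assignment %in% cl_ids)) {
    abort("assignment targets cell lines absent from the panel")
  }
  base <- log2(expr_matrix(panel)[, assignment, drop = FALSE])
  out <- withr::with_seed(config$seed + 1L, {
    2^(base + matrix(rnorm(length(base), sd = config$noise_sd),
                     nrow(base), ncol(base)))
  })
  colnames(out) <- sprintf("P%03d", seq_len(config$n_patients))
  rownames(out) <- panel$gene
  expr <- matrix_expr(out, ranked = FALSE)
  attr(expr, "assignment") <- tibble::tibble(
    patient_id = colnames(out), cell_line = assignment
  )
  expr
}

#' Generate a synthetic AUC table, clinical records and knowledge base
#'
#' Plants drug sensitivity by cluster: the first `n_kb_drugs` drugs are
#' each planted sensitive for one cluster (round-robin), so cell lines of
#' that cluster draw their AUC around `sensitive_auc_mean` and all others
#' around `resistant_auc_mean` (truncated at zero). A `missing_rate`
#' fraction of AUC entries is masked. Every patient receives a clinical
#' record for each planted drug: responder iff the drug is planted
#' sensitive for the patient's cluster, then flipped with probability
#' `label_noise`. The knowledge base is tallied from the records, so its
#' response rates equal the empirical responder fractions by construction.
#'
#' @param config A [sim_config()] object.
#' @param panel Panel from [simulate_panel()] (for its `clusters`).
#' @param patients Patients from [simulate_patients()] (for their
#'   `assignment`).
#' @return List with elements `auc` (tibble, `cell_line` + drug columns),
#'   `kb`, `records`, `annotations` and `planted` (tibble `drug_id`,
#'   `cluster`).
#' @export
simulate_auc_and_records <- function(config, panel, patients) {
  clusters <- attr(panel, "clusters")
  assignment <- attr(patients, "assignment")
  if (is.null(clusters) || is.null(assignment)) {
    abort("panel/patients must carry their 'clusters'/'assignment' attributes")
  }
  drug_ids <- sprintf("drug%02d", seq_len(config$n_drugs))
  planted <- tibble::tibble(
    drug_id = drug_ids[seq_len(config$n_kb_drugs)],
    cluster = (seq_len(config$n_kb_drugs) - 1L) %% config$n_clusters + 1L
  )
  cl_cluster <- clusters$cluster

  res <- withr::with_seed(config$seed + 2L, {
    mu <- matrix(config$resistant_auc_mean,
                 config$n_cell_lines, config$n_drugs)
    for (i in seq_len(nrow(planted))) {
      j <- match(planted$drug_id[i], drug_ids)
      mu[cl_cluster == planted$cluster[i], j] <- config$sensitive_auc_mean
    }
    auc <- mu + matrix(rnorm(length(mu), sd = config$auc_sd),
                       nrow(mu), ncol(mu))
    auc[auc < 0] <- 0
    if (config$missing_rate > 0) {
      auc[runif(length(auc)) < config$missing_rate] <- NA_real_
    }
    pat_cluster <- cl_cluster[match(assignment$cell_line, clusters$cell_line)]
    records <- tidyr::expand_grid(
      patient_id = assignment$patient_id, drug_id = planted$drug_id
    )
    sens <- planted$cluster[match(records$drug_id, planted$drug_id)] ==
      pat_cluster[match(records$patient_id, assignment$patient_id)]
    flip <- runif(nrow(records)) < config$label_noise
    records$response <- ifelse(xor(sens, flip), "responder", "non_responder")
    list(auc = auc, records = records)
  })

  colnames(res$auc) <- drug_ids
  auc_tbl <- tibble::tibble(
    cell_line = clusters$cell_line,
    tibble::as_tibble(res$auc)
  )
  kb <- res$records |>
    dplyr::group_by(drug_id = .data$drug_id) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      n_responders = sum(.data$response == "responder"),
      .groups = "drop"
    )
  annotations <- tibble::tibble(
    drug_id = drug_ids,
    category = drug_categories[(seq_along(drug_ids) - 1L) %% 4L + 1L]
  )
  list(auc = auc_tbl, kb = kb, records = res$records,
       annotations = annotations, planted = planted)
}

#' Generate a complete synthetic cohort
#'
#' Runs [simulate_panel()], [simulate_patients()] and
#' [simulate_auc_and_records()] under one configuration and returns all
#' pieces needed to exercise the full pipeline.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `ccm_cohort`: `panel`, `patients`, `auc`, `kb`,
#'   `records`, `annotations`, `assignment`, `clusters`, `planted`,
#'   `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_genes = 50, n_cell_lines = 8,
#'                                      n_patients = 6, n_drugs = 6,
#'                                      n_clusters = 2, seed = 3))
#' names(cohort)
#' @export
simulate_cohort <- function(config = sim_config()) {
  panel <- simulate_panel(config)
  patients <- simulate_patients(config, panel)
  rest <- simulate_auc_and_records(config, panel, patients)
  structure(
    list(panel = panel, patients = patients, auc = rest$auc, kb = rest$kb,
         records = rest$records, annotations = rest$annotations,
         assignment = attr(patients, "assignment"),
         clusters = attr(panel, "clusters"),
         planted = rest$planted, config = config),
    class = "ccm_cohort"
  )
}

#' @export
print.ccm_cohort <- function(x, ...) {
  cfg <- x$config
  cat("<ccm_cohort>\n")
  cat(sprintf("  %d genes x %d cell lines (%d clusters), %d patients\n",
              cfg$n_genes, cfg$n_cell_lines, cfg$n_clusters, cfg$n_patients))
  cat(sprintf("  %d drugs (%d with planted sensitivity + records), seed %d\n",
              cfg$n_drugs, cfg$n_kb_drugs, cfg$seed))
  invisible(x)
}
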