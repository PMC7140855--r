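ccm_delim <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

read_table_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_delim(path, delim = ccm_delim(path), na = c("", "NA"),
                    show_col_types = FALSE, progress = FALSE)
}

# coerce named columns to numeric, reporting offending data rows
ensure_numeric <- function(df, cols, path) {
  for (cl in cols) {
    if (is.numeric(df[[cl]])) next
    conv <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(!is.na(df[[cl]]) & is.na(conv))
    if (length(bad)) {
      abort(sprintf("%s: non-numeric value(s) in column '%s' at data row(s) %s",
                    path, cl, paste(head(bad, 5), collapse = ", ")))
    }
    df[[cl]] <- conv
  }
  df
}

#' Read and write the pipeline's tabular file formats
#'
#' All files are plain TSV (or CSV when the path ends in `.csv`) with a
#' header row, UTF-8, missing values written as `NA` and accepted as `NA`
#' or an empty field. Validation failures are fatal with messages naming
#' the offending column and data row.
#'
#' * expression: first column `gene`, one numeric column per sample
#' * AUC table: first column `cell_line`, one numeric column per drug
#' * knowledge base: `drug_id`, `n_patients`, `n_responders`
#' * clinical records: `patient_id`, `drug_id`,
#'   `response` in `responder` / `non_responder`
#' * annotations: `drug_id`, `category` in `fda` / `clinical` /
#'   `preclinical` / `other`
#' * alias map: `source_symbol`, `standard_symbol`
#' * batch labels: `sample_id`, `batch`
#'
#' @param path File path.
#' @param ranked Whether the expression file holds ranks.
#' @return The validated object (a tibble).
#' @export
read_expression <- function(path, ranked = FALSE) {
  df <- read_table_file(path)
  names(df)[1] <- "gene"
  dup <- which(duplicated(df$gene))
  if (length(dup)) {
    abort(sprintf("%s: duplicated gene symbol '%s' at data row %d",
                  path, df$gene[dup[1]], dup[1]))
  }
  df <- ensure_numeric(df, setdiff(names(df), "gene"), path)
  as_expression(df, ranked = ranked)
}

#' @rdname read_expression
#' @export
read_auc <- function(path) {
  df <- read_table_file(path)
  names(df)[1] <- "cell_line"
  df$cell_line <- as.character(df$cell_line)
  dup <- which(duplicated(df$cell_line))
  if (length(dup)) {
    abort(sprintf("%s: duplicated cell line '%s' at data row %d",
                  path, df$cell_line[dup[1]], dup[1]))
  }
  df <- ensure_numeric(df, setdiff(names(df), "cell_line"), path)
  for (cl in setdiff(names(df), "cell_line")) {
    bad <- which(!is.na(df[[cl]]) & df[[cl]] < 0)
    if (length(bad)) {
      abort(sprintf("%s: negative AUC in column '%s' at data row %s",
                    path, cl, paste(head(bad, 5), collapse = ", ")))
    }
  }
  df
}

#' @rdname read_expression
#' @export
read_kb <- function(path) {
  df <- read_table_file(path)
  need <- c("drug_id", "n_patients", "n_responders")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s: knowledge base needs columns %s",
                  path, paste(need, collapse = ", ")))
  }
  df <- ensure_numeric(df, c("n_patients", "n_responders"), path)
  bad <- which(df$n_responders > df$n_patients | df$n_responders < 0 |
                 df$n_patients < 1)
  if (length(bad)) {
    abort(sprintf("%s: inconsistent counts at data row(s) %s",
                  path, paste(head(bad, 5), collapse = ", ")))
  }
  dup <- which(duplicated(df$drug_id))
  if (length(dup)) {
    abort(sprintf("%s: duplicated drug '%s' at data row %d",
                  path, df$drug_id[dup[1]], dup[1]))
  }
  tibble::as_tibble(df[need])
}

#' @rdname read_expression
#' @export
read_records <- function(path) {
  df <- read_table_file(path)
  need <- c("patient_id", "drug_id", "response")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s: records need columns %s", path,
                  paste(need, collapse = ", ")))
  }
  bad <- which(!df$response %in% c("responder", "non_responder"))
  if (length(bad)) {
    abort(sprintf("%s: unknown response label '%s' at data row %d",
                  path, df$response[bad[1]], bad[1]))
  }
  dup <- which(duplicated(df[c("patient_id", "drug_id")]))
  if (length(dup)) {
    abort(sprintf("%s: duplicated (patient, drug) record at data row %d",
                  path, dup[1]))
  }
  tibble::as_tibble(df[need])
}

#' @rdname read_expression
#' @export
read_annotations <- function(path) {
  df <- read_table_file(path)
  need <- c("drug_id", "category")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s: annotations need columns %s", path,
                  paste(need, collapse = ", ")))
  }
  bad <- which(!df$category %in% drug_categories)
  if (length(bad)) {
    abort(sprintf("%s: unknown category '%s' at data row %d",
                  path, df$category[bad[1]], bad[1]))
  }
  tibble::as_tibble(df[need])
}

#' @rdname read_expression
#' @export
read_alias_map <- function(path) {
  df <- read_table_file(path)
  need <- c("source_symbol", "standard_symbol")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s: alias map needs columns %s", path,
                  paste(need, collapse = ", ")))
  }
  tibble::as_tibble(df[need])
}

#' @rdname read_expression
#' @export
read_batch_labels <- function(path) {
  df <- read_table_file(path)
  need <- c("sample_id", "batch")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s: batch labels need columns %s", path,
                  paste(need, collapse = ", ")))
  }
  tibble::as_tibble(df[need])
}

#' @rdname read_expression
#' @param x Object to write (expression tibble or any tibble).
#' @export
write_expression <- function(x, path) {
  readr::write_delim(x, path, delim = ccm_delim(path), na = "NA")
  invisible(path)
}

#' @rdname read_expression
#' @export
write_table <- function(x, path) {
  readr::write_delim(tibble::as_tibble(x), path, delim = ccm_delim(path),
                     na = "NA")
  invisible(path)
}

#' Write a synthetic cohort as fixture files
#'
#' Writes the five pipeline input files (panel and patient expression, AUC
#' table, knowledge base, clinical records) plus drug annotations, the
#' patient assignment and a `manifest.tsv` recording the generator
#' configuration including its seed.
#'
#' @param cohort A `ccm_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ccm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$panel, file.path(dir, "panel.tsv"))
  write_expression(cohort$patients, file.path(dir, "patients.tsv"))
  write_table(cohort$auc, file.path(dir, "auc.tsv"))
  write_table(cohort$kb, file.path(dir, "kb.tsv"))
  write_table(cohort$records, file.path(dir, "records.tsv"))
  write_table(cohort$annotations, file.path(dir, "annotations.tsv"))
  write_table(cohort$assignment, file.path(dir, "assignment.tsv"))
  cfg <- cohort$config
  manifest <- tibble::tibble(key = names(cfg),
                             value = vapply(cfg, format, character(1)))
  write_table(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
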