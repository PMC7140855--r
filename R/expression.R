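#' Expression tables
#'
#' `cellmatchr` represents an expression matrix as a tibble whose first
#' column, `gene`, holds unique gene symbols and whose remaining columns are
#' numeric, one per sample. `as_expression()` validates that contract and
#' tags the table with a `ranked` attribute (`FALSE` for raw intensities or
#' quantifications, `TRUE` once [rank_normalize()] has been applied).
#'
#' @param x A data frame with a `gene` character column followed by numeric
#'   sample columns.
#' @param ranked Logical; whether the columns already hold per-sample ranks.
#' @return A tibble with a `ranked` attribute.
#' @examples
#' expr <- as_expression(data.frame(gene = c("TP53", "ERBB2"), s1 = c(2, 5)))
#' is_ranked(expr)
#' @export
as_expression <- function(x, ranked = FALSE) {
  x <- tibble::as_tibble(x)
  if (!"gene" %in% names(x) || names(x)[1] != "gene") {
    abort("an expression table must have 'gene' as its first column")
  }
  if (ncol(x) < 2) abort("an expression table needs at least one sample column")
  x$gene <- as.character(x$gene)
  dup <- x$gene[duplicated(x$gene)]
  if (length(dup)) {
    abort(sprintf("duplicated gene symbol(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  smp <- names(x)[-1]
  if (anyDuplicated(smp)) abort("duplicated sample identifiers")
  ok <- vapply(x[smp], is.numeric, logical(1))
  if (!all(ok)) {
    abort(sprintf("non-numeric sample column(s): %s",
                  paste(smp[!ok], collapse = ", ")))
  }
  attr(x, "ranked") <- isTRUE(ranked)
  x
}

#' @rdname as_expression
#' @export
is_ranked <- function(x) isTRUE(attr(x, "ranked"))

#' Sample identifiers of an expression table
#' @param x An expression tibble (see [as_expression()]).
#' @return Character vector of sample column names.
#' @export
sample_ids <- function(x) setdiff(names(x), "gene")

# numeric matrix view, genes as rownames
expr_matrix <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "gene")])
  rownames(m) <- x$gene
  m
}

matrix_expr <- function(m, ranked = FALSE) {
  as_expression(
    tibble::tibble(gene = rownames(m),
                   tibble::as_tibble(m, .name_repair = "minimal")),
    ranked = ranked
  )
}

#' Remove missing-value and extreme-mean genes
#'
#' Drops genes with any missing value, then trims genes whose mean
#' expression lies in the distribution tails: the `floor(n * tail_fraction
#' / 2)` lowest-mean and equally many highest-mean genes are removed, i.e.
#' `tail_fraction` is the *total* trimmed fraction, split equally between
#' the two tails. Such extreme genes are treated as outliers of the
#' expression histogram and excluded before cross-platform comparison.
#' The relative order of the surviving genes is preserved.
#'
#' @param expr Unranked expression tibble.
#' @param tail_fraction Total fraction of genes to trim; `0 <= tail_fraction
#'   < 0.5`. `0` removes only missing-value genes.
#' @return A filtered expression tibble.
#' @examples
#' expr <- as_expression(tibble::tibble(
#'   gene = paste0("g", 1:6), s1 = c(1, 2, NA, 4, 5, 100), s2 = 1:6
#' ))
#' filter_genes(expr, tail_fraction = 0)
#' @export
filter_genes <- function(expr, tail_fraction = 0.05) {
  expr <- as_expression(expr, ranked = is_ranked(expr))
  if (is_ranked(expr)) abort("filter_genes() expects unranked expression")
  if (tail_fraction < 0 || tail_fraction >= 0.5) {
    abort("tail_fraction must be in [0, 0.5)")
  }
  m <- expr_matrix(expr)
  keep <- rowSums(is.na(m)) == 0
  expr <- expr[keep, , drop = FALSE]
  m <- m[keep, , drop = FALSE]
  n <- nrow(m)
  if (n == 0) abort("no genes left after removing missing-value genes")
  k <- floor(n * tail_fraction / 2)
  if (k > 0) {
    mu <- rowMeans(m)
    ord <- order(mu)                       # stable: ties keep input order
    drop_idx <- c(ord[seq_len(k)], ord[seq(n - k + 1, n)])
    expr <- expr[-drop_idx, , drop = FALSE]
  }
  if (nrow(expr) == 0) {
    abort("tail_fraction removed every gene; lower the threshold")
  }
  as_expression(expr, ranked = FALSE)
}

#' Harmonize two expression tables onto a shared gene universe
#'
#' Standardizes gene symbols through an alias map (many-to-one,
#' source symbol to standardized symbol; symbols absent from the map are
#' kept as-is), collapses any duplicates produced by aliasing by keeping
#' the row with the highest mean expression, and restricts both tables to
#' the intersection of standardized symbols, aligned in identical row
#' order (the order of appearance in `a`).
#'
#' @param a,b Expression tibbles, both unranked or both ranked.
#' @param aliases Optional data frame with columns `source_symbol` and
#'   `standard_symbol`; `NULL` for an identity map.
#' @return A list with elements `a` and `b`: the two harmonized tables,
#'   with identical `gene` columns.
#' @examples
#' a <- as_expression(tibble::tibble(gene = c("TP53", "ERBB2"), s1 = c(1, 2)))
#' b <- as_expression(tibble::tibble(gene = c("TP53", "HER2"), t1 = c(3, 4)))
#' al <- tibble::tibble(source_symbol = "HER2", standard_symbol = "ERBB2")
#' harmonize_genes(a, b, al)$b
#' @export
harmonize_genes <- function(a, b, aliases = NULL) {
  a <- as_expression(a, ranked = is_ranked(a))
  b <- as_expression(b, ranked = is_ranked(b))
  if (is_ranked(a) != is_ranked(b)) {
    abort("both tables must be unranked or both ranked")
  }
  a2 <- standardize_symbols(a, aliases)
  b2 <- standardize_symbols(b, aliases)
  common <- intersect(a2$gene, b2$gene)
  if (length(common) == 0) {
    abort(sprintf(
      "no genes in common after aliasing: first table has %d symbols (e.g. %s), second has %d (e.g. %s)",
      nrow(a2), paste(head(a2$gene, 3), collapse = ", "),
      nrow(b2), paste(head(b2$gene, 3), collapse = ", ")
    ))
  }
  common <- a2$gene[a2$gene %in% common]   # order of appearance in a
  list(
    a = as_expression(a2[match(common, a2$gene), ], ranked = is_ranked(a)),
    b = as_expression(b2[match(common, b2$gene), ], ranked = is_ranked(b))
  )
}

standardize_symbols <- function(expr, aliases) {
  if (!is.null(aliases)) {
    aliases <- tibble::as_tibble(aliases)
    stopifnot(all(c("source_symbol", "standard_symbol") %in% names(aliases)))
    if (any(!nzchar(aliases$standard_symbol))) {
      abort("alias map contains empty standardized symbols")
    }
    hit <- match(expr$gene, aliases$source_symbol)
    expr$gene <- ifelse(is.na(hit), expr$gene, aliases$standard_symbol[hit])
  }
  if (anyDuplicated(expr$gene)) {
    mu <- rowMeans(expr_matrix(expr))
    keep <- !logical(nrow(expr))
    for (g in unique(expr$gene[duplicated(expr$gene)])) {
      idx <- which(expr$gene == g)
      keep[idx] <- FALSE
      keep[idx[which.max(mu[idx])]] <- TRUE
    }
    expr <- expr[keep, , drop = FALSE]
  }
  expr
}

#' Rank-normalize expression per sample
#'
#' Replaces each sample's expression values by their descending ranks:
#' the most highly expressed gene receives rank 1 and ties receive average
#' ranks (the standard Spearman convention). Ranking makes profiles from
#' different platforms (microarray intensity vs. RNA-seq quantification)
#' directly comparable and is invariant to any strictly increasing
#' per-sample transformation of the raw values.
#'
#' @param expr Expression tibble without missing values.
#' @return The rank-transformed expression tibble, flagged as ranked.
#' @examples
#' expr <- as_expression(tibble::tibble(gene = c("a", "b", "c"),
#'                                      s1 = c(5, 1, 3)))
#' rank_normalize(expr)
#' @export
rank_normalize <- function(expr) {
  expr <- as_expression(expr, ranked = is_ranked(expr))
  if (is_ranked(expr)) abort("expression is already rank-normalized")
  m <- expr_matrix(expr)
  if (anyNA(m)) abort("missing values present; run filter_genes() first")
  r <- apply(m, 2, function(col) rank(-col, ties.method = "average"))
  if (is.null(dim(r))) r <- matrix(r, ncol = ncol(m), dimnames = dimnames(m))
  matrix_expr(r, ranked = TRUE)
}

#' Remove additive batch effects by per-gene batch-mean centering
#'
#' For every gene, each batch's values are shifted so the batch mean equals
#' the gene's grand mean across all samples. This removes additive
#' between-batch offsets while leaving the within-batch ordering of samples
#' untouched; it is a transparent, deliberately simple linear adjustment
#' applied before rank normalization.
#'
#' @param expr Unranked expression tibble.
#' @param batches Data frame with columns `sample_id` and `batch` labelling
#'   every sample of `expr`.
#' @return The batch-centered expression tibble.
#' @export
remove_batch_effect <- function(expr, batches) {
  expr <- as_expression(expr, ranked = is_ranked(expr))
  if (is_ranked(expr)) abort("remove_batch_effect() expects unranked expression")
  batches <- tibble::as_tibble(batches)
  stopifnot(all(c("sample_id", "batch") %in% names(batches)))
  smp <- sample_ids(expr)
  missing <- setdiff(smp, batches$sample_id)
  if (length(missing)) {
    abort(sprintf("unlabelled sample(s): %s", paste(missing, collapse = ", ")))
  }
  lab <- batches$batch[match(smp, batches$sample_id)]
  m <- expr_matrix(expr)
  grand <- rowMeans(m)
  for (b in unique(lab)) {
    idx <- which(lab == b)
    bm <- rowMeans(m[, idx, drop = FALSE])
    m[, idx] <- m[, idx, drop = FALSE] - bm + grand
  }
  matrix_expr(m, ranked = FALSE)
}
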