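#' Run configuration with method defaults
#'
#' Bundles the tunable parameters of the two-layer recommendation pipeline.
#' Defaults follow the published protocol: `alpha = 30` matched cell lines
#' (5% of a 610-line panel, floored), `gamma_default = 0.5` for drugs with no
#' prior clinical response information, unit-width AUC histogram bins,
#' a 5% total (2.5% per tail) trim of extreme-mean genes, an `alpha`
#' search range of 1 to 61 and 10-fold cross-validation.
#'
#' @param alpha Number of most-similar cell lines matched to each patient.
#' @param gamma_default Response rate assumed for drugs absent from the
#'   knowledge base.
#' @param bin_width Width of AUC histogram bins used by [percentile_point()],
#'   in AUC units.
#' @param tail_fraction Total fraction of extreme-mean genes removed by
#'   [filter_genes()] (split equally between the two tails).
#' @param alpha_range Inclusive bounds of the grid searched by
#'   [optimize_alpha()].
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed governing all stochastic steps.
#' @return A named list of class `ccm_config`.
#' @examples
#' cfg <- ccm_config(seed = 7)
#' cfg$alpha
#' @export
ccm_config <- function(alpha = 30L,
                       gamma_default = 0.5,
                       bin_width = 1,
                       tail_fraction = 0.05,
                       alpha_range = c(1L, 61L),
                       folds = 10L,
                       seed = 1L) {
  stopifnot(
    alpha >= 1, gamma_default >= 0, gamma_default <= 1,
    bin_width > 0, tail_fraction >= 0, tail_fraction < 0.5,
    length(alpha_range) == 2, alpha_range[1] >= 1,
    alpha_range[2] >= alpha_range[1], folds >= 2
  )
  structure(
    list(
      alpha = as.integer(alpha),
      gamma_default = gamma_default,
      bin_width = bin_width,
      tail_fraction = tail_fraction,
      alpha_range = as.integer(alpha_range),
      folds = as.integer(folds),
      seed = as.integer(seed)
    ),
    class = "ccm_config"
  )
}

#' Read a configuration file
#'
#' Reads a flat `key: value` text file and merges it over the package
#' defaults. Keys not named in [ccm_config()] are rejected. Values supplied
#' in `overrides` (e.g. parsed command-line flags) take precedence over the
#' file, which takes precedence over the defaults.
#'
#' @param path Path to a flat key-value configuration file, or `NULL`.
#' @param overrides Named list of values overriding both file and defaults.
#' @return A `ccm_config` object.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
      if (length(kv) < 2) {
        abort(sprintf("config line is not 'key: value': '%s'", ln))
      }
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = ":"))
      vals[[key]] <- val
    }
  }
  defaults <- ccm_config()
  known <- names(defaults)
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  for (key in names(vals)) {
    v <- strsplit(vals[[key]], "[,[:space:]]+")[[1]]
    defaults[[key]] <- as.numeric(v)
  }
  for (key in names(overrides)) {
    if (!key %in% known) abort(sprintf("unknown config override: %s", key))
    if (!is.null(overrides[[key]])) defaults[[key]] <- overrides[[key]]
  }
  do.call(ccm_config, unclass(defaults))
}

#' @export
print.ccm_config <- function(x, ...) {
  cat("<ccm_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-14s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
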