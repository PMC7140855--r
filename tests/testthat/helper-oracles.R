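# Independent oracles, deliberately written as plain brute force so they do
# not share code paths with the package implementation.

# Spearman via term-by-term evaluation of the product-moment formula on ranks
oracle_spearman <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# grouped-percentile point by explicit histogram walk
oracle_percentile <- function(values, gamma, bw = 1) {
  n <- length(values)
  gn <- gamma * n
  lo <- floor(min(values) / bw)
  hi <- floor(max(values) / bw)
  counts <- vapply(lo:hi, function(k) {
    sum(values >= k * bw & values < (k + 1) * bw)
  }, numeric(1))
  if (gn == 0) {
    first <- (lo:hi)[counts > 0][1]
    return(first * bw)
  }
  target <- ceiling(gn)
  cum <- 0
  for (i in seq_along(counts)) {
    if (cum + counts[i] >= target) {
      phi <- (lo + i - 1) * bw
      return(phi + (gn - cum) / counts[i] * bw)
    }
    cum <- cum + counts[i]
  }
  stop("unreachable")
}

# two-sided Fisher p by full enumeration of tables with fixed margins
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k1 <- a + c; k2 <- b + d
  if (m1 == 0 || m2 == 0 || k1 == 0 || k2 == 0) return(1)
  n <- m1 + m2
  xs <- max(0, k1 - m2):min(k1, m1)
  probs <- dhyper(xs, m1, m2, k1)
  p_obs <- dhyper(a, m1, m2, k1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive pairwise correlation + sort matching oracle (small panels)
oracle_match <- function(patient_vec, panel_mat, alpha) {
  pr <- rank(-patient_vec, ties.method = "average")
  rho <- apply(panel_mat, 2, function(cl) {
    oracle_spearman(pr, rank(-cl, ties.method = "average"))
  })
  ord <- order(-rho, names(rho))
  ids <- names(rho)[ord]
  head(data.frame(cell_line = ids, rho = rho[ord], row.names = NULL),
       min(alpha, length(ids)))
}
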