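test_that("filter_genes drops missing-value genes and trims mean tails", {
  m <- matrix(1:12, nrow = 4, dimnames = list(paste0("g", 1:4), NULL))
  m[2, 1] <- NA
  expr <- make_expr(m)
  out <- filter_genes(expr, tail_fraction = 0)
  expect_setequal(out$gene, c("g1", "g3", "g4"))

  # fixed-seed 1000-gene case: exactly the 25 lowest- and highest-mean genes go
  set.seed(42)
  big <- matrix(rnorm(1000 * 5, mean = 8, sd = 3), nrow = 1000)
  rownames(big) <- sprintf("g%04d", 1:1000)
  expr <- make_expr(big)
  out <- filter_genes(expr, tail_fraction = 0.05)
  mu <- sort(rowMeans(big))
  expected_dropped <- names(c(head(mu, 25), utils::tail(mu, 25)))
  expect_equal(nrow(out), 950)
  expect_setequal(setdiff(expr$gene, out$gene), expected_dropped)
  # order of survivors preserved
  expect_identical(out$gene, expr$gene[expr$gene %in% out$gene])
})

test_that("filter_genes is idempotent on the missing-value rule", {
  set.seed(1)
  expr <- make_expr(matrix(rexp(300), nrow = 60))
  once <- filter_genes(expr, 0)
  expect_identical(filter_genes(once, 0), once)
})

test_that("filter_genes rejects over-aggressive thresholds and bad input", {
  expr <- make_expr(matrix(1:4, nrow = 2))
  expect_error(filter_genes(expr, 0.6), "tail_fraction")
  expect_error(filter_genes(rank_normalize(expr)), "unranked")
})

test_that("rank_normalize gives descending average-tied ranks per sample", {
  expr <- make_expr(matrix(c(5, 1, 3), ncol = 1))
  expect_equal(rank_normalize(expr)[[2]], c(1, 3, 2))
  expr <- make_expr(matrix(c(2, 2, 1), ncol = 1))
  expect_equal(rank_normalize(expr)[[2]], c(1.5, 1.5, 3))
})

test_that("rank_normalize is invariant to monotone transforms and sums to n(n+1)/2", {
  set.seed(7)
  m <- matrix(rexp(40 * 3) + 0.1, nrow = 40)
  r1 <- rank_normalize(make_expr(m))
  r2 <- rank_normalize(make_expr(log(m)))
  expect_equal(r1, r2)
  sums <- colSums(as.matrix(r1[-1]))
  expect_true(all(sums == 40 * 41 / 2))
  expect_true(is_ranked(r1))
  expect_error(rank_normalize(r1), "already")
})

test_that("remove_batch_effect centers batch means onto the grand mean", {
  set.seed(3)
  m <- matrix(rnorm(20 * 9, mean = 5), nrow = 20)
  colnames(m) <- paste0("s", 1:9)
  batches <- tibble::tibble(sample_id = paste0("s", 1:9),
                            batch = rep(c("b1", "b2", "b3"), each = 3))
  # constructed offsets
  m[, 4:6] <- m[, 4:6] + 10
  m[, 7:9] <- m[, 7:9] - 2.5
  out <- remove_batch_effect(make_expr(m), batches)
  om <- as.matrix(out[-1])
  grand <- rowMeans(as.matrix(m))
  for (b in unique(batches$batch)) {
    idx <- which(batches$batch == b)
    expect_equal(rowMeans(om[, idx, drop = FALSE]), grand,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # per-gene grand mean preserved
  expect_equal(rowMeans(om), grand, tolerance = 1e-9, ignore_attr = TRUE)
  # within-batch ordering per gene unchanged
  expect_identical(apply(om[, 1:3], 1, order), apply(m[, 1:3], 1, order))
})

test_that("remove_batch_effect is identity for a single batch and checks labels", {
  m <- matrix(rnorm(12), nrow = 4, dimnames = list(NULL, paste0("s", 1:3)))
  expr <- make_expr(m)
  one <- tibble::tibble(sample_id = paste0("s", 1:3), batch = "b")
  expect_equal(as.matrix(remove_batch_effect(expr, one)[-1]),
               as.matrix(expr[-1]), ignore_attr = TRUE)
  expect_error(remove_batch_effect(expr, one[1:2, ]), "unlabelled")
})

test_that("batch centering matches limma's removeBatchEffect on offsets", {
  skip_if_not_installed("limma")
  set.seed(9)
  m <- matrix(rnorm(30 * 8, mean = 6), nrow = 30)
  colnames(m) <- paste0("s", 1:8)
  batch <- rep(c("A", "B"), each = 4)
  m[, batch == "B"] <- m[, batch == "B"] + 3
  ours <- as.matrix(remove_batch_effect(
    make_expr(m), tibble::tibble(sample_id = colnames(m), batch = batch))[-1])
  ref <- limma::removeBatchEffect(m, batch = batch)
  # both remove the same additive batch term, up to per-gene recentering
  expect_equal(ours - rowMeans(ours), ref - rowMeans(ref),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("harmonize_genes aliases, collapses duplicates and aligns order", {
  a <- as_expression(tibble::tibble(gene = c("TP53", "ERBB2"), s1 = c(1, 2)))
  b <- as_expression(tibble::tibble(gene = c("TP53", "HER2"), t1 = c(3, 4)))
  al <- tibble::tibble(source_symbol = "HER2", standard_symbol = "ERBB2")
  h <- harmonize_genes(a, b, al)
  expect_identical(h$a$gene, c("TP53", "ERBB2"))
  expect_identical(h$a$gene, h$b$gene)
  expect_equal(h$b$t1, c(3, 4))

  # duplicate after aliasing: highest-mean row retained
  b2 <- as_expression(tibble::tibble(gene = c("HER2", "ERBB2", "TP53"),
                                     t1 = c(5, 9, 1)))
  h2 <- harmonize_genes(a, b2, al)
  expect_equal(h2$b$t1[h2$b$gene == "ERBB2"], 9)

  # identity map: unchanged up to row ordering
  h3 <- harmonize_genes(a, b2[2:3, ])
  expect_identical(h3$a$gene, h3$b$gene)

  expect_error(
    harmonize_genes(a, as_expression(tibble::tibble(gene = "KRAS", u = 1))),
    "no genes in common")
})

test_that("expression validation catches malformed tables", {
  expect_error(as_expression(tibble::tibble(gene = c("a", "a"), s = 1:2)),
               "duplicated gene")
  expect_error(as_expression(tibble::tibble(gene = "a", s = "x")),
               "non-numeric")
  expect_error(as_expression(tibble::tibble(s = 1)), "first column")
})
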