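kb_fixture <- tibble::tibble(
  drug_id = c("lapatinib", "fluorouracil"),
  n_patients = c(31, 31),
  n_responders = c(8, 31)
)

test_that("compute_gamma returns KB rates and the 0.5 default", {
  expect_equal(compute_gamma(kb_fixture, "lapatinib"), 8 / 31)
  expect_equal(compute_gamma(kb_fixture, "fluorouracil"), 1)
  expect_equal(compute_gamma(kb_fixture, "novel"), 0.5)
  expect_equal(compute_gamma(kb_fixture, "novel", gamma_default = 0.3), 0.3)
  bad <- tibble::tibble(drug_id = "x", n_patients = 0, n_responders = 0)
  expect_error(compute_gamma(bad, "x"), "zero treated")
})

test_that("build_cell_list unions matched cells for KB drugs, panel otherwise", {
  matches <- tibble::tibble(
    patient_id = rep(c("p1", "p2"), each = 3),
    rank = rep(1:3, 2),
    cell_line = c("A", "B", "C", "B", "C", "D"),
    rho = rep(c(0.9, 0.8, 0.7), 2)
  )
  records <- tibble::tibble(patient_id = c("p1", "p2"),
                            drug_id = "lapatinib",
                            response = c("responder", "non_responder"))
  L <- build_cell_list(matches, kb_fixture, "lapatinib",
                       panel_cell_lines = LETTERS[1:10], records = records)
  expect_identical(L, c("A", "B", "C", "D"))
  # single patient: the match list itself
  L1 <- build_cell_list(matches[1:3, ], kb_fixture, "lapatinib",
                        LETTERS[1:10], records[1, ])
  expect_identical(L1, c("A", "B", "C"))
  # unknown drug: the whole panel
  expect_identical(
    build_cell_list(matches, kb_fixture, "unknown", LETTERS[1:10]),
    LETTERS[1:10])
  expect_error(
    build_cell_list(matches[0, ], kb_fixture, "lapatinib", LETTERS, records),
    "no matched cell lines")
})

test_that("percentile_point reproduces the grouped-percentile formula", {
  # ten identical values: P = 3 + (5 - 0)/10 = 3.5
  expect_equal(percentile_point(rep(3.2, 10), 0.5), 3.5)
  # gamma 0: lower limit of the first occupied bin
  expect_equal(percentile_point(c(7.2, 9.9), 0), 7)
  expect_equal(percentile_point(c(7.2, 9.9), 0, bin_width = 5), 5)
})

test_that("percentile_point equals the brute-force oracle on seeded data", {
  set.seed(99)
  for (i in 1:50) {
    vals <- runif(sample(5:200, 1), 0, 30)
    gamma <- runif(1)
    bw <- sample(c(0.5, 1, 2), 1)
    expect_equal(percentile_point(vals, gamma, bw),
                 oracle_percentile(vals, gamma, bw), tolerance = 1e-12)
  }
})

test_that("percentile_point is monotone in gamma and stays in occupied range", {
  set.seed(13)
  vals <- rexp(60, rate = 0.2)
  ps <- vapply(seq(0, 1, by = 0.05), percentile_point,
               numeric(1), auc_values = vals)
  expect_true(all(diff(ps) >= -1e-12))
  expect_true(all(ps >= floor(min(vals)) & ps <= ceiling(max(vals))))
})

test_that("compute_threshold applies the ceiling and validates data", {
  auc <- tibble::tibble(cell_line = paste0("c", 1:10),
                        d1 = rep(3.2, 10), d2 = rep(NA_real_, 10))
  thr <- compute_threshold(auc, "d1", auc$cell_line, gamma = 0.5)
  expect_equal(thr$p_gamma, 3.5)
  expect_equal(thr$theta, 4)
  # integer percentile point: theta equals it
  auc2 <- tibble::tibble(cell_line = paste0("c", 1:4), d1 = c(1.5, 2.5, 3.5, 4.5))
  thr2 <- compute_threshold(auc2, "d1", auc2$cell_line, gamma = 1)
  expect_equal(thr2$theta, ceiling(thr2$p_gamma))
  expect_true(thr2$theta - thr2$p_gamma >= 0 && thr2$theta - thr2$p_gamma < 1)
  expect_error(compute_threshold(auc, "d2", auc$cell_line, 0.5), "d2")
  expect_error(compute_threshold(auc, "nope", auc$cell_line, 0.5), "nope")
})

test_that("theta is an integer within one unit above p_gamma on random data", {
  set.seed(12)
  auc <- tibble::tibble(cell_line = paste0("c", 1:30), d = runif(30, 0, 25))
  for (g in c(0.1, 0.25, 0.5, 0.9, 1)) {
    thr <- compute_threshold(auc, "d", auc$cell_line, g)
    expect_identical(thr$theta, ceiling(thr$p_gamma))
    expect_true(thr$theta >= thr$p_gamma && thr$theta - thr$p_gamma < 1)
  }
})

test_that("compute_thresholds recomputes a planted synthetic threshold", {
  co <- noiseless_cohort()
  m <- match_cell_lines(co$patients, co$panel, alpha = 2)
  thr <- compute_thresholds(co$auc, co$kb, m, co$records)
  d <- co$kb$drug_id[1]
  L <- build_cell_list(m, co$kb, d, co$auc$cell_line, co$records)
  vals <- co$auc[[d]][match(L, co$auc$cell_line)]
  expect_equal(thr$p_gamma[thr$drug_id == d],
               oracle_percentile(vals[!is.na(vals)], compute_gamma(co$kb, d)),
               tolerance = 1e-12)
})
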