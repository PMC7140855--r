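match_one <- function(cells, pid = "p1") {
  tibble::tibble(patient_id = pid, rank = seq_along(cells),
                 cell_line = cells, rho = seq(0.9, by = -0.01,
                                              length.out = length(cells)))
}

test_that("average_auc drops missing screening entries", {
  auc <- tibble::tibble(cell_line = c("A", "B", "C", "D", "E"),
                        d1 = c(2, 4, 6, 8, NA),
                        d2 = c(1.7, NA, NA, NA, NA),
                        d3 = rep(NA_real_, 5))
  m <- match_one(c("A", "B", "C", "D", "E"))
  expect_equal(average_auc(auc, m, "d1"),
               tibble::tibble(drug_id = "d1", mean_auc = 5, freq = 4L))
  expect_equal(average_auc(auc, m, "d2")$mean_auc, 1.7)
  expect_equal(average_auc(auc, m, "d2")$freq, 1L)
  expect_equal(average_auc(auc, m, "d3")$freq, 0L)
})

test_that("recommend_drugs sorts ascending within category and uses strict <", {
  auc <- tibble::tibble(cell_line = c("A", "B"),
                        slow = c(7.3, 7.3), fast = c(2.1, 2.1),
                        edge = c(4, 4), gone = c(NA_real_, NA_real_))
  thr <- tibble::tibble(drug_id = c("slow", "fast", "edge", "gone"),
                        gamma = 0.5, p_gamma = c(8, 8, 4, 8),
                        theta = c(8, 8, 4, 8), n_cells = 2)
  ann <- tibble::tibble(drug_id = c("slow", "fast", "edge", "gone"),
                        category = "fda")
  rec <- recommend_drugs(match_one(c("A", "B")), auc, thr, ann)
  # the fully-missing drug is excluded
  expect_false("gone" %in% rec$drug_id)
  fda <- rec[rec$category == "fda", ]
  expect_identical(fda$drug_id, c("fast", "edge", "slow"))
  expect_identical(fda$rank, 1:3)
  # mean_auc == theta is non-responsive (strict threshold)
  expect_false(rec$predicted_responsive[rec$drug_id == "edge"])
  expect_true(rec$predicted_responsive[rec$drug_id == "fast"])
})

test_that("recommendations are stable under drug column permutation", {
  set.seed(2)
  auc <- tibble::tibble(cell_line = c("A", "B", "C"),
                        d1 = runif(3, 0, 10), d2 = runif(3, 0, 10),
                        d3 = runif(3, 0, 10))
  thr <- compute_thresholds(auc, kb = tibble::tibble(drug_id = character(),
                                                     n_patients = integer(),
                                                     n_responders = integer()))
  m <- match_one(c("A", "C"))
  r1 <- recommend_drugs(m, auc, thr)
  r2 <- recommend_drugs(m, auc[c("cell_line", "d3", "d1", "d2")],
                        thr[c(3, 1, 2), ])
  expect_equal(r1, r2)
})

test_that("drugs without annotation fall into 'other' with a warning", {
  auc <- tibble::tibble(cell_line = "A", d1 = 3, d2 = 5)
  thr <- tibble::tibble(drug_id = c("d1", "d2"), gamma = 0.5,
                        p_gamma = 4, theta = 4, n_cells = 1)
  ann <- tibble::tibble(drug_id = "d1", category = "clinical")
  expect_warning(rec <- recommend_drugs(match_one("A"), auc, thr, ann),
                 "without category")
  expect_identical(rec$category[rec$drug_id == "d2"], "other")
  # category blocks come out in the fixed order
  expect_identical(rec$category, c("clinical", "other"))
  expect_error(
    recommend_drugs(match_one("A"), auc, thr,
                    tibble::tibble(drug_id = "d1", category = "bogus")),
    "unknown drug category")
})

test_that("the planted sensitive drug ranks first in its category", {
  co <- noiseless_cohort()
  m <- match_cell_lines(co$patients, co$panel, alpha = 1)
  thr <- compute_thresholds(co$auc, co$kb, m, co$records)
  rec <- recommend_drugs(m, co$auc, thr, co$annotations)
  pat_cluster <- co$clusters$cluster[match(co$assignment$cell_line,
                                           co$clusters$cell_line)]
  for (i in seq_len(nrow(co$planted))) {
    d <- co$planted$drug_id[i]
    cat_d <- co$annotations$category[co$annotations$drug_id == d]
    pats <- co$assignment$patient_id[pat_cluster == co$planted$cluster[i]]
    for (p in pats) {
      block <- rec[rec$patient_id == p & rec$category == cat_d, ]
      expect_identical(block$drug_id[1], d)
      expect_true(block$predicted_responsive[1])
    }
  }
})
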