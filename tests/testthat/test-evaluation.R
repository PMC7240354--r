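test_that("rank-formula AUC equals the pairwise concordance oracle", {
  withr::with_seed(41, {
    for (r in 1:50) {
      n <- sample(5:40, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
      scores <- round(runif(n), sample(1:3, 1))  # rounding induces ties
      expect_equal(auc(scores, labels), oracle_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC handles perfect, inverted and tied scores", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "one class")
})

test_that("bootstrap CI is deterministic, ordered and brackets the point", {
  withr::with_seed(42, {
    scores <- runif(300)
    labels <- rbinom(300, 1, plogis(3 * scores - 1.5))
  })
  a <- bootstrap_ci(scores, labels, B = 400, seed = 7)
  b <- bootstrap_ci(scores, labels, B = 400, seed = 7)
  expect_identical(a, b)
  expect_lt(a$lo, a$hi)
  expect_gte(a$point, a$lo)
  expect_lte(a$point, a$hi)
  c2 <- bootstrap_ci(scores, labels, B = 400, seed = 8)
  expect_false(identical(a$lo, c2$lo))
})

test_that("per-drug AUC evaluates each drug on its known-outcome subset", {
  pd <- data.frame(
    patient_id = c("p1", "p2", "p3", "p4", "p1", "p2", "p3"),
    drug_name = c(rep("a", 4), rep("b", 3)),
    stable = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
  scores <- c(p1 = 0.9, p2 = 0.2, p3 = 0.8, p4 = 0.1)
  res <- per_drug_auc(scores, pd, c("a", "b"), B = 0)
  expect_equal(res$per_drug$auc[res$per_drug$drug_name == "a"], 1)
  # drug b: pos p2 (0.2) vs neg p1 (0.9), p3 (0.8) -> 0 concordant pairs
  expect_equal(res$per_drug$auc[res$per_drug$drug_name == "b"], 0)
  expect_equal(res$mean_auc, 0.5)
  # single-class drugs are excluded from the mean with a warning
  pd1 <- rbind(pd, data.frame(patient_id = "p1", drug_name = "c", stable = TRUE))
  expect_warning(res1 <- per_drug_auc(scores, pd1, c("a", "b", "c"), B = 0),
                 "excluded")
  expect_identical(res1$excluded, "c")
  expect_equal(res1$mean_auc, 0.5)
})

test_that("top-3 assessability categories follow the known outcomes", {
  pd <- data.frame(
    patient_id = c("p1", "p1", "p2", "p3"),
    drug_name = c("a", "b", "c", "d"),
    stable = c(FALSE, TRUE, FALSE, TRUE))
  drugs <- c("a", "b", "c", "d", "e")
  pm <- matrix(c(
    0.9, 0.8, 0.7, 0.1, 0.2,   # p1 top3 = a,b,c -> b stable
    0.1, 0.2, 0.9, 0.3, 0.8,   # p2 top3 = c,e,d -> c known nonstable
    0.5, 0.4, 0.3, 0.1, 0.2,   # p3 top3 = a,b,c -> d unseen: not assessable
    0.9, 0.9, 0.9, 0.9, 0.9),  # p4 no known outcome at all
    nrow = 4, byrow = TRUE, dimnames = list(paste0("p", 1:4), drugs))
  res <- top3_stability_accuracy(pm, pd, paste0("p", 1:4), drugs)
  got <- stats::setNames(res$categories$category, res$categories$patient_id)
  expect_identical(unname(got[c("p1", "p2", "p3", "p4")]),
                   c("assessable-stable", "assessable-nonstable",
                     "not-assessable", "not-assessable"))
  expect_equal(res$accuracy, 0.5)
  expect_equal(res$assessable_fraction, 0.5)
})

test_that("tied probabilities defer to the fallback ranking", {
  pd <- data.frame(patient_id = "p1", drug_name = "c", stable = TRUE)
  pm <- matrix(rep(0.5, 4), 1, dimnames = list("p1", c("a", "b", "c", "d")))
  # fallback prefers c: the all-tied row must surface c in its top 3
  res <- top3_stability_accuracy(pm, pd, "p1", c("c", "a", "b", "d"))
  expect_identical(res$categories$category, "assessable-stable")
  res2 <- top3_stability_accuracy(pm, pd, "p1", c("a", "b", "d", "c"))
  expect_identical(res2$categories$category, "not-assessable")
})

test_that("fixed-list and observed-practice comparators share the contract", {
  pd <- data.frame(patient_id = c("p1", "p2"), drug_name = c("a", "z"),
                   stable = c(TRUE, TRUE))
  fixed <- top3_stability_accuracy(NULL, pd, c("p1", "p2"),
                                   c("a", "b", "c", "z"))
  expect_equal(fixed$accuracy, 1)  # p1 assessable via a; p2 not (z ranked 4th)
  expect_equal(fixed$assessable_fraction, 0.5)
  pr <- practice_stability_accuracy(list(p1 = "b", p2 = "z"), pd,
                                    c("p1", "p2"))
  expect_equal(pr$assessable_fraction, 0.5)  # p1's b has no known outcome
  expect_equal(pr$accuracy, 1)
  prf <- practice_stability_accuracy(list(p1 = "b", p2 = "z"), pd,
                                     c("p1", "p2"), fill_from = c("a", "c"))
  expect_equal(prf$assessable_fraction, 1)  # p1 padded with a
})

test_that("most-common-stable ranking counts stable patients with ties lexicographic", {
  pd <- data.frame(
    patient_id = sprintf("p%d", 1:8),
    drug_name = c("b", "b", "a", "a", "c", "c", "c", "d"),
    stable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(most_common_stable_baseline(pd, k = 3), c("a", "b", "c"))
  expect_identical(most_common_stable_baseline(pd, k = 10), c("a", "b", "c", "d"))
})

test_that("quartile trial means match the hand-worked example", {
  scores <- stats::setNames(1:8 / 10, paste0("p", 1:8))
  trials <- stats::setNames(c(3L, 3L, 2L, 2L, 1L, 1L, 0L, 0L), paste0("p", 1:8))
  res <- quartile_medication_trials(scores, trials, B = 0)
  expect_equal(res$mean_trials, c(3, 2, 1, 0))
  expect_equal(res$n, rep(2L, 4))
})

test_that("boundary ties go to the lower quartile and NA trials drop out", {
  scores <- stats::setNames(c(0.1, 0.2, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7),
                            paste0("p", 1:8))
  trials <- stats::setNames(c(5L, 4L, 4L, 2L, NA, 2L, 1L, 0L), paste0("p", 1:8))
  res <- quartile_medication_trials(scores, trials, B = 0)
  # 25th percentile is 0.2: both 0.2 scores tie it and stay in quartile 1
  expect_equal(res$n[1], 3L)
  expect_equal(res$mean_trials[1], mean(c(5, 4, 4)))
  expect_equal(res$n[3], 1L)  # p5 (never-stable, NA trials) is excluded
  expect_equal(res$mean_trials[3], 2)
  # censored mode counts never-stable patients' observed initiations minus one
  tot <- stats::setNames(rep(3L, 8), paste0("p", 1:8))
  res2 <- quartile_medication_trials(scores, trials, B = 0,
                                     include_never = TRUE,
                                     total_initiations = tot)
  expect_equal(res2$n[3], 2L)
  expect_equal(res2$mean_trials[3], mean(c(2, 2)))
})

test_that("ppv and npv report NA, never zero, for undefined cells", {
  labels <- c(1, 1, 0, 1, 0, 0)
  scores <- c(0.9, 0.8, 0.6, 0.4, 0.3, 0.2)
  res <- ppv_npv(scores, labels, 0.5)
  expect_equal(res$ppv, 2 / 3)
  # the 0.4-scored patient is a stable miss below threshold: NPV is 2/3
  expect_equal(res$npv, 2 / 3)
  all_pos <- ppv_npv(scores, labels, 0.0)
  expect_true(is.na(all_pos$npv))
  expect_equal(all_pos$ppv, 0.5)
  all_neg <- ppv_npv(scores, labels, 1.1)
  expect_true(is.na(all_neg$ppv))
  expect_equal(all_neg$npv, 0.5)
})

test_that("bootstrap quartile CIs are ordered around the point estimate", {
  withr::with_seed(43, {
    scores <- stats::setNames(runif(200), sprintf("p%03d", 1:200))
    trials <- stats::setNames(rpois(200, 2 * (1 - scores)), names(scores))
  })
  res <- quartile_medication_trials(scores, trials, B = 300, seed = 5)
  expect_true(all(res$lo <= res$mean_trials + 1e-12))
  expect_true(all(res$hi >= res$mean_trials - 1e-12))
  expect_true(all(diff(res$mean_trials) <= 0))  # higher score, fewer trials
})
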