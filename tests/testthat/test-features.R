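feature_fixture <- function(n = 150, seed = 31) {
  cfg <- sim_config(n_patients = n, n_topics_true = 3, vocab_size = 60,
                    seed = seed)
  gen <- generate_cohort(cfg, generate_ground_truth(cfg))
  labs <- label_cohort(gen$cohort)
  idx <- stats::setNames(labs$general$index_date, labs$general$patient_id)
  sp <- split_cohort(labs$general$patient_id, seed = seed)
  list(gen = gen, idx = idx, sp = sp)
}

test_that("vocabulary counts distinct patients, not occurrences", {
  ev <- data.frame(patient_id = c("a", "a", "a", "b"),
                   date = c(1L, 2L, 3L, 1L),
                   code_type = "ICD", code = "X")
  rx <- data.frame(patient_id = c("a", "b"), date = 10L,
                   drug_name = "d", days_supply = 90L)
  dm <- data.frame(patient_id = c("a", "b"), sex = "F",
                   race_ethnicity = "White", birth_date = -9000L)
  co <- rx_cohort(ev, rx, dm)
  idx <- c(a = 10L, b = 10L)
  v <- build_vocabulary(co, c("a", "b"), idx, min_patients = 2)
  expect_identical(v$words, "ICD:X")  # 2 patients despite 4 occurrences
  v1 <- build_vocabulary(co, c("a", "b"), idx, min_patients = 3)
  expect_length(v1$words, 0)
})

test_that("vocabulary ordering is frequency-descending then lexicographic", {
  fx <- feature_fixture()
  v <- build_vocabulary(fx$gen$cohort, fx$sp$train, fx$idx, min_patients = 5)
  expect_true(all(diff(v$patient_freq) <= 0))
  ties <- split(v$words, v$patient_freq)
  expect_true(all(vapply(ties, function(w) !is.unsorted(w), logical(1))))
  expect_match(v$hash, "^[0-9a-f]+$")
})

test_that("count matrices respect the strict pre-index cutoff", {
  ev <- data.frame(patient_id = "a", date = c(5L, 9L, 10L, 11L),
                   code_type = "ICD", code = "X")
  rx <- data.frame(patient_id = "a", date = 10L, drug_name = "d",
                   days_supply = 90L)
  dm <- data.frame(patient_id = "a", sex = "F", race_ethnicity = "White",
                   birth_date = -9000L)
  co <- rx_cohort(ev, rx, dm)
  idx <- c(a = 10L)
  v <- build_vocabulary(co, "a", idx, min_patients = 1)
  X <- vectorize_history(co, "a", v, idx)
  # dates 5 and 9 count; the index-day event (10) and later (11) do not
  expect_equal(as.numeric(X["a", "ICD:X"]), 2)
})

test_that("prescriptions appear as RX tokens and the matrix is aligned", {
  fx <- feature_fixture()
  v <- build_vocabulary(fx$gen$cohort, fx$sp$train, fx$idx, min_patients = 1)
  # RX-type coded events survive as tokens; the antidepressant prescriptions
  # themselves never can, because the index is the first prescription and the
  # cutoff is strict
  expect_true(any(grepl("^RX:", v$words)))
  expect_false(any(grepl("^RX:drug_", v$words)))
  X <- vectorize_history(fx$gen$cohort, fx$sp$test, v, fx$idx)
  expect_identical(rownames(X), fx$sp$test)
  expect_identical(colnames(X), v$words)
  expect_s4_class(X, "dgCMatrix")
  expect_true(all(X@x >= 1))
})

test_that("demographics block one-hots categories and standardizes age", {
  fx <- feature_fixture()
  tf <- fit_demographics(fx$gen$cohort, fx$sp$train, fx$idx)
  D <- demographics_features(fx$gen$cohort, fx$sp$train, tf, fx$idx)
  expect_identical(rownames(D), fx$sp$train)
  expect_equal(mean(D[, "age_std"]), 0, tolerance = 1e-10)
  expect_equal(sd(D[, "age_std"]), 1, tolerance = 1e-10)
  sex_cols <- grep("^sex_", colnames(D))
  expect_true(all(rowSums(D[, sex_cols, drop = FALSE]) == 1))
})

test_that("unseen categories map to an all-zero one-hot block", {
  fx <- feature_fixture()
  tf <- fit_demographics(fx$gen$cohort, fx$sp$train, fx$idx)
  co <- fx$gen$cohort
  id <- fx$sp$test[1]
  co$demographics$race_ethnicity[co$demographics$patient_id == id] <- "Unreported"
  D <- demographics_features(co, id, tf, fx$idx)
  expect_equal(sum(D[, grep("^race_", colnames(D))]), 0)
  expect_equal(ncol(D), ncol(demographics_features(fx$gen$cohort, id, tf, fx$idx)))
})

test_that("features of early patients are invariant to later patients' data", {
  # leakage probe: perturbing test patients' post-index records or adding new
  # patients must not change training features or the vocabulary
  fx <- feature_fixture()
  v <- build_vocabulary(fx$gen$cohort, fx$sp$train, fx$idx, min_patients = 5)
  tf <- fit_demographics(fx$gen$cohort, fx$sp$train, fx$idx)
  X <- vectorize_history(fx$gen$cohort, fx$sp$train, v, fx$idx)

  co2 <- fx$gen$cohort
  sel <- co2$events$patient_id %in% fx$sp$test
  co2$events$code[sel] <- "Z999"  # rewrite all test patients' codes
  v2 <- build_vocabulary(co2, fx$sp$train, fx$idx, min_patients = 5)
  tf2 <- fit_demographics(co2, fx$sp$train, fx$idx)
  X2 <- vectorize_history(co2, fx$sp$train, v2, fx$idx)
  expect_identical(v2$hash, v$hash)
  expect_equal(X2, X)
  expect_equal(tf2, tf)
})

test_that("binarized and raw feature matrices agree on support", {
  fx <- feature_fixture()
  v <- build_vocabulary(fx$gen$cohort, fx$sp$train, fx$idx, min_patients = 5)
  tf <- fit_demographics(fx$gen$cohort, fx$sp$train, fx$idx)
  f <- featurize(fx$gen$cohort, fx$sp$train, v, tf, fx$idx)
  M <- feature_matrix(f)
  Mb <- feature_matrix(f, binarize = TRUE)
  cw <- seq_along(v$words)
  expect_true(all(Mb[, cw] %in% c(0, 1)))
  expect_identical(Mb[, cw] > 0, M[, cw] > 0)
  expect_identical(f$vocab_hash, v$hash)
})
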