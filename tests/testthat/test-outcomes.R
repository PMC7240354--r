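test_that("interval-union MPR equals the day-by-day counting oracle", {
  withr::with_seed(101, {
    for (r in 1:200) {
      n <- sample(1:8, 1)
      dates <- sort(sample(0:400, n))
      supplies <- sample(1:120, n, replace = TRUE)
      seg <- build_segments(rx_table(dates, supplies), max_gap = 10000L)[[1L]]
      expect_equal(medication_possession_ratio(seg),
                   oracle_mpr(dates, supplies), tolerance = 1e-12)
    }
  })
})

test_that("overlapping supplies are never double-counted", {
  seg <- build_segments(rx_table(c(0, 10, 20), 90))[[1L]]
  expect_equal(medication_possession_ratio(seg), 1)
  expect_equal(seg$duration, 110L)
})

test_that("each stability rule fails exactly at its documented boundary", {
  verdict <- function(dates, supply) {
    is_stable_segment(build_segments(rx_table(dates, supply))[[1L]])
  }
  # spacing: distinct dates must span >= 30 days
  expect_false(verdict(c(0, 29), 90)$stable)
  expect_identical(verdict(c(0, 29), 90)$failed_rules, "spacing")
  expect_true(verdict(c(0, 30), 90)$stable)
  # two-dates: one distinct date (even repeated) is insufficient
  expect_identical(verdict(0, 120)$failed_rules, "two-dates")
  expect_true("two-dates" %in% verdict(c(5, 5), 120)$failed_rules)
  # duration: coverage_end - start must reach 90 days
  expect_false(verdict(c(0, 30), c(30, 55))$stable)  # duration 85, mpr 1
  expect_identical(verdict(c(0, 30), c(30, 55))$failed_rules, "duration")
  expect_true(verdict(c(0, 30), c(30, 60))$stable)   # duration 90
  # mpr: possession must reach 80%
  expect_false(verdict(c(0, 80), 30)$stable)  # 60/110 covered
  expect_identical(verdict(c(0, 80), 30)$failed_rules, "mpr")
  expect_true(verdict(c(0, 45), 90)$stable)   # continuous possession
  # gap: adjacent dates at most 390 days apart within a segment
  segs <- build_segments(rx_table(c(0, 391), 90))
  expect_length(segs, 2L)  # the gap rule splits the run instead
  expect_true(all(!vapply(lapply(segs, is_stable_segment), `[[`,
                          logical(1), "stable")))
  expect_length(build_segments(rx_table(c(0, 390), 90)), 1L)
})

test_that("exact-threshold values satisfy the rules (>=, not >)", {
  seg <- build_segments(rx_table(c(0, 30, 60), 24))[[1L]]
  # duration 84 < 90 fails; with supply 30 duration is exactly 90 and passes
  expect_false(is_stable_segment(seg)$stable)
  seg2 <- build_segments(rx_table(c(0, 30, 60), 30))[[1L]]
  expect_equal(seg2$duration, 90L)
  expect_equal(seg2$mpr, 1)
  expect_true(is_stable_segment(seg2)$stable)
})

test_that("an MPR of exactly 80 percent passes and just below fails", {
  # duration 100, covered 80 -> exactly 0.80
  seg <- build_segments(rx_table(c(0, 60), c(40L, 40L)))[[1L]]
  expect_equal(seg$mpr, 0.80)
  expect_true(is_stable_segment(seg)$stable)
  # duration 100, covered 79 -> 0.79
  seg2 <- build_segments(rx_table(c(0, 61), c(40L, 39L)))[[1L]]
  expect_equal(seg2$mpr, 0.79)
  expect_identical(is_stable_segment(seg2)$failed_rules, "mpr")
})

test_that("segments split per drug and at >390-day gaps", {
  rx <- rbind(rx_table(c(0, 100, 600), 90, "a"),
              rx_table(c(50, 120), 90, "b"))
  segs <- build_segments(rx)
  drugs <- vapply(segs, `[[`, character(1), "drug_name")
  starts <- vapply(segs, `[[`, integer(1), "start")
  expect_identical(drugs[order(starts)], c("a", "b", "a"))
  expect_identical(sort(starts), c(0L, 50L, 600L))
})

test_that("break dates terminate ongoing segments when requested", {
  rx <- rx_table(c(0, 40, 80, 120), 30, "a")
  expect_length(build_segments(rx), 1L)
  segs <- build_segments(rx, break_dates = 80L)
  expect_length(segs, 2L)
  expect_identical(vapply(segs, `[[`, integer(1), "start"), c(0L, 80L))
})

test_that("general label distinguishes index-, later- and never-stable", {
  stable_rx <- function(drug, t0) rx_table(t0 + c(0, 45, 90), 90, drug)
  broken_rx <- function(drug, t0) rx_table(t0 + c(0, 20), 90, drug)  # spacing

  lab <- label_general_stability(stable_rx("a", 0))
  expect_identical(lab$category, "index-stable")
  expect_identical(lab$additional_trials, 0L)

  lab <- label_general_stability(rbind(broken_rx("a", 0), stable_rx("b", 150)))
  expect_identical(lab$category, "later-stable")
  expect_identical(lab$additional_trials, 1L)
  expect_identical(lab$per_drug, c(a = FALSE, b = TRUE))

  lab <- label_general_stability(rbind(broken_rx("a", 0), broken_rx("b", 150)))
  expect_identical(lab$category, "never-stable")
  expect_true(is.na(lab$additional_trials))

  expect_null(label_general_stability(rx_table(0, 90)[0, , drop = FALSE]))
})

test_that("additional trials count initiations up to the first stable start", {
  rx <- rbind(rx_table(c(0, 20), 90, "a"),        # fails spacing
              rx_table(c(150, 170), 90, "b"),     # fails spacing
              rx_table(c(300, 345, 390), 90, "c"),# stable
              rx_table(c(700, 745), 90, "d"))     # after stability: not a trial
  lab <- label_general_stability(rx)
  expect_identical(lab$category, "later-stable")
  expect_identical(lab$additional_trials, 2L)
})

test_that("drug-specific label is NA only for drugs never prescribed", {
  rx <- rbind(rx_table(c(0, 45, 90), 90, "a"), rx_table(c(400, 420), 90, "b"))
  expect_true(label_drug_specific(rx, "a"))
  expect_false(label_drug_specific(rx, "b"))
  expect_true(is.na(label_drug_specific(rx, "c")))
})

test_that("cohort labeling matches per-patient labeling", {
  withr::with_seed(7, {
    cfg <- sim_config(n_patients = 60, vocab_size = 50, n_topics_true = 3,
                      seed = 7)
    gen <- generate_cohort(cfg, generate_ground_truth(cfg))
  })
  labs <- label_cohort(gen$cohort)
  rx <- gen$cohort$prescriptions
  for (id in sample(labs$general$patient_id, 10)) {
    one <- label_general_stability(rx[rx$patient_id == id, , drop = FALSE])
    row <- labs$general[labs$general$patient_id == id, ]
    expect_identical(row$category, one$category)
    expect_identical(row$index_date, one$index_date)
    expect_identical(row$additional_trials, one$additional_trials)
  }
})

test_that("target drugs require enough known outcomes and sort stably", {
  pd <- data.frame(
    patient_id = sprintf("P%02d", 1:9),
    drug_name = c(rep("b", 3), rep("a", 3), rep("c", 2), "d"),
    stable = TRUE)
  expect_identical(select_target_drugs(pd, min_patients = 3), c("a", "b"))
  expect_identical(select_target_drugs(pd, min_patients = 2), c("a", "b", "c"))
  expect_identical(select_target_drugs(pd[0, ], 1), character(0))
})
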